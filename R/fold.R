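# Equilibrium secondary-structure prediction: partition function, base-pair
# probabilities, helices, dominant and alternative structures.

.vf_pk_modes <- c(none = 0L, junction1 = 1L, any = 2L)

#' Fold an RNA sequence: partition function and base-pair probabilities
#'
#' Computes the equilibrium partition function Q over the helix-based
#' secondary-structure ensemble (relative to the open chain), the base-pair
#' probability matrix P_ij, helix probabilities, and the dominant (pairs
#' with P_ij > 0.5) and alternative structures. Intra-loop mismatch
#' variants of every hairpin and internal loop are summed as distinct
#' ensemble members. Pseudoknot modes add bare H-type two-helix structures:
#' `"junction1"` restricts the inter-helix junction to <= 1 nt, `"any"`
#' allows any junction length (and is limited to shorter sequences).
#'
#' @param seq RNA sequence (string, [rna_sequence()], or FASTA text via
#'   [read_rna()]).
#' @param temperature temperature in degrees Celsius (default 37).
#' @param params `"turner04"`, `"mfold23"`, or an [energy_params()] object.
#' @param pseudoknot `"none"`, `"junction1"`, or `"any"`.
#' @param entropies loop-entropy table (defaults to the shipped table).
#' @param level_tolerance probability window within which helices are
#'   grouped into the same alternative structure.
#' @param min_helix_prob smallest helix probability considered when
#'   grouping alternatives.
#' @param max_length,max_length_any sequence-length limits (the `"any"`
#'   pseudoknot mode enumerates a much larger geometry set).
#' @param multiloop_branch_penalty per-branch multiloop penalty (kcal/mol).
#' @return an object of class `vfold_fold`.
#' @examples
#' f <- fold_rna("GGGAGCAAAAGCUCCC")
#' f$Q
#' f$helices
#' @export
fold_rna <- function(seq, temperature = 37, params = "turner04",
                     pseudoknot = c("none", "junction1", "any"),
                     entropies = loop_entropy_table(),
                     level_tolerance = 0.15, min_helix_prob = 0.05,
                     max_length = 140, max_length_any = 60,
                     multiloop_branch_penalty = 0.1) {
  pseudoknot <- match.arg(pseudoknot)
  seq <- rna_sequence(seq, max_length = max_length)
  n <- attr(seq, "n")
  if (pseudoknot == "any" && n > max_length_any)
    abort(sprintf("pseudoknot mode 'any' is limited to %d nt (sequence has %d); use 'junction1' or 'none'",
                  max_length_any, n),
          class = "vfold_feasibility_error")
  eng <- .vf_engine(seq, temperature, params, entropies,
                    c_b = multiloop_branch_penalty)
  res <- vf_fold_cpp(eng$s, eng$RT, eng$SG,
                     as.numeric(eng$emmH), as.numeric(eng$emmI),
                     eng$mm_ok,
                     eng$S_hp, eng$S_int, eng$a_int, eng$c_int,
                     eng$S_hpmm, eng$S_intmm, eng$mmcap,
                     eng$S_ml, eng$c_b,
                     eng$S_pk, eng$S_junc,
                     .vf_pk_modes[[pseudoknot]],
                     eng$min_hairpin, eng$max_internal,
                     TRUE)
  .vf_fold_result(seq, temperature, eng$params$dialect, pseudoknot,
                  res$Q, res$Qn, res$Qpk, res$bpp,
                  level_tolerance, min_helix_prob, method = "dp")
}

.vf_fold_result <- function(seq, temperature, dialect, pseudoknot,
                            Q, Qn, Qpk, bpp, level_tolerance, min_helix_prob,
                            method) {
  n <- attr(seq, "n")
  dimnames(bpp) <- list(seq_len(n), seq_len(n))
  out <- list(seq = seq, n = n, temperature = temperature,
              dialect = dialect, pseudoknot = pseudoknot,
              Q = Q, lnQ = log(Q), Qn = Qn, Qpk = Qpk,
              bpp = bpp, method = method)
  out$helices <- helix_probabilities(bpp)
  ds <- dominant_structures(out, level_tolerance = level_tolerance,
                            min_prob = min_helix_prob)
  out$dominant <- ds$dominant
  out$alternatives <- ds$alternatives
  class(out) <- "vfold_fold"
  out
}

#' @export
print.vfold_fold <- function(x, ...) {
  cat(sprintf("<vfold_fold> %d nt at %.1f C (%s, pseudoknot: %s)\n",
              x$n, x$temperature, x$dialect, x$pseudoknot))
  cat(sprintf("  Q = %.6g (lnQ = %.4f)\n", x$Q, x$lnQ))
  cat(sprintf("  dominant structure: %s (probability %.3f, %d pairs)\n",
              pairs_to_dotbracket(x$dominant$pairs, x$n),
              x$dominant$probability, nrow(x$dominant$pairs)))
  if (length(x$alternatives))
    cat(sprintf("  %d alternative structure(s); strongest at level %.3f\n",
                length(x$alternatives), x$alternatives[[1]]$probability))
  invisible(x)
}

#' Helix probabilities from a base-pair probability matrix
#'
#' Maximal diagonal runs of pairs with P_ij above a floor are reported as
#' helices with probability equal to the mean P_ij over the run; runs of a
#' single pair are not reported (the model has no lonely pairs).
#'
#' @param x a `vfold_fold` object or an N x N probability matrix.
#' @param min_prob floor below which a pair is not part of any reported
#'   helix.
#' @return tibble with columns `i`, `j` (outer pair), `length`, `prob`.
#' @export
helix_probabilities <- function(x, min_prob = 1e-4) {
  bpp <- if (inherits(x, "vfold_fold")) x$bpp else x
  n <- nrow(bpp)
  on <- bpp > min_prob
  on[lower.tri(on, diag = TRUE)] <- FALSE
  res <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (!on[i, j]) next
    if (i > 1 && j < n && on[i - 1, j + 1]) next  # not a run start
    h <- 1L
    p <- bpp[i, j]
    while (i + h < j - h && on[i + h, j - h]) {
      p <- p + bpp[i + h, j - h]
      h <- h + 1L
    }
    if (h >= 2)
      res[[length(res) + 1]] <- tibble(i = i, j = j, length = h, prob = p / h)
  }
  out <- dplyr::bind_rows(res)
  if (!nrow(out)) return(tibble(i = integer(), j = integer(),
                                length = integer(), prob = numeric()))
  dplyr::arrange(out, dplyr::desc(.data$prob), .data$i)
}

.vf_helix_pairs <- function(h) {
  do.call(rbind, lapply(seq_len(nrow(h)), function(k)
    cbind(h$i[k] + 0:(h$length[k] - 1), h$j[k] - 0:(h$length[k] - 1))))
}

#' Dominant and alternative structures
#'
#' The dominant structure is the set of base pairs with P_ij > 0.5 (strict).
#' Alternative structures are maximal sets of mutually compatible helices
#' whose probabilities agree within `level_tolerance` (helices of the same
#' structure form at the same probability level), reported with the level's
#' mean probability; helices below `min_prob` are ignored.
#'
#' @param x a `vfold_fold` object.
#' @param level_tolerance probability window defining one level.
#' @param min_prob smallest helix probability considered.
#' @return list with `dominant` (list: `pairs`, `probability`) and
#'   `alternatives` (list of the same shape).
#' @export
dominant_structures <- function(x, level_tolerance = 0.15, min_prob = 0.05) {
  bpp <- x$bpp
  n <- nrow(bpp)
  idx <- which(bpp > 0.5 & upper.tri(bpp), arr.ind = TRUE)
  dom_pairs <- .vf_pairs_mat(idx, n)
  dom_prob <- if (nrow(dom_pairs))
    mean(bpp[dom_pairs]) else NA_real_
  hel <- helix_probabilities(bpp, min_prob = min_prob)
  # helices already fully inside the dominant pair set are not alternatives
  if (nrow(hel) && nrow(dom_pairs)) {
    domkey <- paste(dom_pairs[, 1], dom_pairs[, 2])
    in_dom <- vapply(seq_len(nrow(hel)), function(k) {
      hp <- .vf_helix_pairs(hel[k, ])
      all(paste(hp[, 1], hp[, 2]) %in% domkey)
    }, TRUE)
    hel <- hel[!in_dom, ]
  }
  alts <- list()
  while (nrow(hel)) {
    lev <- hel$prob[1]
    take <- abs(hel$prob - lev) <= level_tolerance
    grp <- hel[take, ]
    # keep the group mutually compatible (no shared indices, no crossing)
    sel <- integer(0)
    for (k in seq_len(nrow(grp))) {
      ok <- TRUE
      for (m in sel) {
        a <- grp[k, ]; b <- grp[m, ]
        ia <- c(a$i + 0:(a$length - 1), a$j - 0:(a$length - 1))
        ib <- c(b$i + 0:(b$length - 1), b$j - 0:(b$length - 1))
        if (length(intersect(ia, ib)) || .vf_cross(a, b)) { ok <- FALSE; break }
      }
      if (ok) sel <- c(sel, k)
    }
    grp <- grp[sel, ]
    alts[[length(alts) + 1]] <- list(
      pairs = .vf_pairs_mat(.vf_helix_pairs(grp), n),
      probability = mean(grp$prob),
      helices = grp)
    hel <- hel[!take, ]
  }
  list(dominant = list(pairs = dom_pairs, probability = dom_prob),
       alternatives = alts)
}

#' Free energy of a given secondary structure
#'
#' dG of one structure relative to the open chain: the sum of helix stack
#' free energies and loop free energies (hairpin, internal/bulge,
#' multiloop, or pseudoknot loops for a bare H-type pseudoknot). With
#' `mismatches = "ensemble"` (default) every loop contributes the Boltzmann
#' sum over its intra-loop single-mismatch variants, and the returned value
#' is the ensemble free energy -RT ln W of that structure class; with
#' `"none"` only the plain loops are scored.
#'
#' @inheritParams fold_rna
#' @param structure pairs (matrix/data frame) or dot-bracket string.
#' @param mismatches `"ensemble"` or `"none"`.
#' @return free energy in kcal/mol (0 for the open chain; `Inf` for a
#'   structure outside the model's ensemble).
#' @export
structure_free_energy <- function(seq, structure, temperature = 37,
                                  params = "turner04",
                                  entropies = loop_entropy_table(),
                                  mismatches = c("ensemble", "none"),
                                  multiloop_branch_penalty = 0.1) {
  mismatches <- match.arg(mismatches)
  eng <- .vf_engine(seq, temperature, params, entropies,
                    c_b = multiloop_branch_penalty)
  val <- validate_structure(seq, structure)
  w <- .vf_structure_weight(eng, val, use_mismatches = mismatches == "ensemble")
  -eng$RT * log(w)
}

# Boltzmann weight of one validated structure (relative to the open chain)
.vf_structure_weight <- function(eng, val, use_mismatches = TRUE) {
  hel <- val$helices
  if (!nrow(hel)) return(1)
  if (val$pseudoknotted) {
    if (nrow(hel) != 2)
      abort("only bare H-type pseudoknots (exactly two crossing helices) are scored",
            class = "vfold_invalid_structure")
    A <- hel[1, ]; B <- hel[2, ]
    if (B$i < A$i) { tmp <- A; A <- B; B <- tmp }
    return(.vf_pk_weight(eng, A$i, A$j, A$length, B$i, B$j, B$length))
  }
  W <- 1
  # parent helix of each helix (nearest enclosing)
  parent <- rep(0L, nrow(hel))
  for (a in seq_len(nrow(hel))) {
    best <- 0L
    for (b in seq_len(nrow(hel))) {
      if (a == b) next
      pb <- hel$i[b] + hel$length[b] - 1L; qb <- hel$j[b] - hel$length[b] + 1L
      if (pb < hel$i[a] && hel$j[a] < qb) {
        if (best == 0L || hel$i[b] > hel$i[best]) best <- b
      }
    }
    parent[a] <- best
  }
  for (a in seq_len(nrow(hel))) {
    i <- hel$i[a]; j <- hel$j[a]; h <- hel$length[a]
    W <- W * .vf_helix_stack_weight(eng, i, j, h)
    p <- i + h - 1L; q <- j - h + 1L
    kids <- which(parent == a)
    if (length(kids) == 0) {
      W <- W * (if (use_mismatches) .vf_wh_r(eng, p, q) else
        exp(eng$S_hp[q - p]))
    } else if (length(kids) == 1) {
      ip <- hel$i[kids]; jp <- hel$j[kids]
      L1 <- ip - p - 1L; L2 <- q - jp - 1L
      if (L1 + L2 > eng$max_internal) return(0)
      W <- W * (if (use_mismatches) .vf_wint_r(eng, p, q, ip, jp) else {
        S <- .vf_s_int_fast(eng, L1, L2)
        if (is.finite(S)) exp(S) else 0
      })
    } else {
      spans <- hel$j[kids] - hel$i[kids] + 1L
      u <- (q - p - 1L) - sum(spans)
      W <- W * exp(eng$S_ml[u + 1]) *
        exp(-eng$c_b / eng$RT)^(length(kids) + 1)
    }
  }
  W
}

.vf_pk_weight <- function(eng, ai, aj, ah, bi, bj, bh) {
  a1e <- ai + ah - 1L; a2s <- aj - ah + 1L
  b1e <- bi + bh - 1L; b2s <- bj - bh + 1L
  L1 <- bi - a1e - 1L
  j2 <- a2s - b1e - 1L
  L3 <- b2s - aj - 1L
  if (L1 < 1 || j2 < 0 || L3 < 1)
    abort("helices do not form an H-type pseudoknot geometry",
          class = "vfold_invalid_structure")
  hmax <- ncol(eng$S_pk) + 1L
  S <- eng$S_pk[L1 + 1, min(bh, hmax) - 1] +
    eng$S_junc[j2 + 1] +
    eng$S_pk[L3 + 1, min(ah, hmax) - 1]
  if (!is.finite(S)) return(0)
  .vf_helix_stack_weight(eng, ai, aj, ah) *
    .vf_helix_stack_weight(eng, bi, bj, bh) * exp(S)
}

#' Enumerate intra-loop mismatch variants of a loop
#'
#' Lists the mismatch-free loop plus every admissible single-mismatch
#' placement (hairpin loops: any two loop nucleotides >= 3 nt apart;
#' internal loops: one nucleotide from each strand), with the entropy,
#' mismatch-stack term and Boltzmann weight of each variant. The mismatch
#' alphabet is every non-canonical base combination except A-A.
#'
#' @inheritParams fold_rna
#' @param loop a list: `list(type = "hairpin", closing = c(i, j))` or
#'   `list(type = "internal", closing = c(i, j), inner = c(ip, jp))`
#'   (`inner` is the outer pair of the helix across the loop).
#' @return a tibble, one row per variant (`u`, `v` are `NA` for the plain
#'   loop).
#' @export
enumerate_mismatch_variants <- function(seq, loop, temperature = 37,
                                        params = "turner04",
                                        entropies = loop_entropy_table()) {
  eng <- .vf_engine(seq, temperature, params, entropies)
  rows <- list()
  push <- function(u, v, S, stackG) {
    rows[[length(rows) + 1]] <<- tibble(
      u = u, v = v, dS = S, stack_dG = stackG,
      weight = exp(S) * exp(-stackG / eng$RT))
  }
  if (loop$type == "hairpin") {
    p <- loop$closing[1]; q <- loop$closing[2]
    L <- q - p - 1
    if (L < 3) abort("hairpin loop below the 3-nt minimum",
                     class = "vfold_invalid_loop")
    push(NA_integer_, NA_integer_, eng$S_hp[L + 1], 0)
    if (L >= 5) {
      c1 <- eng$mmcap + 1L
      for (u in 1:(L - 4)) for (v in (u + 4):L) {
        if (!eng$mm_ok[eng$s[p + u] + 1, eng$s[p + v] + 1]) next
        S <- if (L <= eng$mmcap) eng$S_hpmm[(L * c1 + u) * c1 + v + 1]
        else eng$S_hp[v - u] + .vf_s_int_fast(eng, u - 1, L - v)
        if (!is.finite(S)) next
        g <- if (u == 1 && v == L)
          eng$emmH[.vf_pt_at(eng, p, q), eng$s[p + 1] + 1, eng$s[q - 1] + 1]
        else 0
        push(u, v, S, g)
      }
    }
  } else if (loop$type == "internal") {
    p <- loop$closing[1]; q <- loop$closing[2]
    ip <- loop$inner[1]; jp <- loop$inner[2]
    L1 <- ip - p - 1; L2 <- q - jp - 1
    push(NA_integer_, NA_integer_, .vf_s_int_fast(eng, L1, L2), 0)
    if (L1 >= 1 && L2 >= 1) {
      c1 <- eng$mmcap + 1L
      for (u in 1:L1) for (v in 1:L2) {
        if (!eng$mm_ok[eng$s[p + u] + 1, eng$s[jp + v] + 1]) next
        S <- if (L1 + L2 <= eng$mmcap)
          eng$S_intmm[((L1 * c1 + L2) * c1 + u) * c1 + v + 1]
        else .vf_s_int_fast(eng, u - 1, L2 - v) + .vf_s_int_fast(eng, L1 - u, v - 1)
        if (!is.finite(S)) next
        g <- 0
        if (u == 1 && v == L2)
          g <- g + eng$emmI[.vf_pt_at(eng, p, q), eng$s[p + 1] + 1, eng$s[q - 1] + 1]
        if (u == L1 && v == 1)
          g <- g + eng$emmI[.vf_pt_at(eng, jp, ip), eng$s[jp + 1] + 1, eng$s[ip - 1] + 1]
        push(u, v, S, g)
      }
    }
  } else {
    abort("loop$type must be 'hairpin' or 'internal'", class = "vfold_invalid_loop")
  }
  dplyr::bind_rows(rows)
}
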