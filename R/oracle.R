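# Exhaustive structure enumeration: the independent reference for the
# dynamic-programming engine at small N.

#' Fold by exhaustive enumeration (test oracle)
#'
#' Generates every admissible secondary structure explicitly — all sets of
#' mutually compatible, non-mergeable helix placements (nested ensemble)
#' plus, in pseudoknot modes, every bare H-type two-helix geometry — scores
#' each with [structure_free_energy()]'s weight model, and sums Boltzmann
#' weights directly. Same contracts as [fold_rna()]; limited to short
#' sequences (the ensemble is enumerated one structure at a time).
#'
#' @inheritParams fold_rna
#' @param max_n refuse sequences longer than this (combinatorial explosion).
#' @param max_structures safety cap on the number of enumerated structures.
#' @return a `vfold_fold` object with an extra element `n_structures` (the
#'   number of enumerated nested structures, including the open chain) and
#'   `structures` (list of pair matrices with their weights).
#' @export
exhaustive_fold <- function(seq, temperature = 37, params = "turner04",
                            pseudoknot = c("none", "junction1", "any"),
                            entropies = loop_entropy_table(),
                            max_n = 25, max_structures = 500000,
                            multiloop_branch_penalty = 0.1) {
  pseudoknot <- match.arg(pseudoknot)
  seq <- rna_sequence(seq)
  n <- attr(seq, "n")
  if (n > max_n)
    abort(sprintf("exhaustive enumeration refused for n = %d > %d", n, max_n),
          class = "vfold_feasibility_error")
  eng <- .vf_engine(seq, temperature, params, entropies,
                    c_b = multiloop_branch_penalty)
  ch <- eng$chars

  # nested helix placements: (i, j, h) with all pairs valid, inner gap >= 3
  pl <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j - i < 6) next
    if (.vf_pair_type(ch[i], ch[j]) == 0) next
    h <- 1L
    repeat {
      ii <- i + h; jj <- j - h
      if (jj - ii - 1 < 3 || .vf_pair_type(ch[ii], ch[jj]) == 0) break
      h <- h + 1L
      if (h >= 2)
        pl[[length(pl) + 1]] <- list(i = i, j = j, h = h,
                                     idx = c(i:(i + h - 1), (j - h + 1):j))
    }
  }
  np <- length(pl)

  compatible <- function(a, b) {
    if (length(intersect(a$idx, b$idx))) return(FALSE)
    # non-crossing
    if ((a$i < b$i && b$i < a$j && a$j < b$j) ||
        (b$i < a$i && a$i < b$j && b$j < a$j)) return(FALSE)
    # non-mergeable (adjacent continuation would be the same pair set as a
    # single longer placement)
    if (b$i == a$i + a$h && b$j == a$j - a$h) return(FALSE)
    if (a$i == b$i + b$h && a$j == b$j - b$h) return(FALSE)
    TRUE
  }
  comp <- matrix(TRUE, max(np, 1), max(np, 1))
  if (np > 1)
    for (a in 1:(np - 1)) for (b in (a + 1):np) {
      comp[a, b] <- comp[b, a] <- compatible(pl[[a]], pl[[b]])
    }

  Q <- 0
  bppnum <- matrix(0, n, n)
  structures <- list()
  nstruct <- 0L
  emit <- function(sel) {
    pairs <- if (length(sel))
      do.call(rbind, lapply(pl[sel], function(p)
        cbind(p$i + 0:(p$h - 1), p$j - 0:(p$h - 1))))
    else matrix(integer(0), 0, 2)
    val <- list(pairs = .vf_pairs_mat(pairs, n),
                helices = .vf_helix_runs(.vf_pairs_mat(pairs, n)),
                pseudoknotted = FALSE)
    w <- .vf_structure_weight(eng, val)
    Q <<- Q + w
    nstruct <<- nstruct + 1L
    if (nrow(val$pairs))
      for (r in seq_len(nrow(val$pairs)))
        bppnum[val$pairs[r, 1], val$pairs[r, 2]] <<-
          bppnum[val$pairs[r, 1], val$pairs[r, 2]] + w
    structures[[nstruct]] <<- list(pairs = val$pairs, weight = w)
  }
  recurse <- function(sel, from) {
    if (nstruct >= max_structures)
      abort("structure ensemble larger than max_structures",
            class = "vfold_feasibility_error")
    emit(sel)
    if (from > np) return(invisible(NULL))
    for (k in from:np) {
      if (all(comp[sel, k])) recurse(c(sel, k), k + 1L)
    }
    invisible(NULL)
  }
  if (np > 0) recurse(integer(0), 1L) else emit(integer(0))

  # bare H-type pseudoknots
  Qpk <- 0
  if (pseudoknot != "none") {
    # placements without the hairpin-gap requirement
    pk <- list()
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (j - i < 3) next
      if (.vf_pair_type(ch[i], ch[j]) == 0) next
      h <- 1L
      repeat {
        ii <- i + h; jj <- j - h
        if (jj - ii < 1 || .vf_pair_type(ch[ii], ch[jj]) == 0) break
        h <- h + 1L
        if (h >= 2) pk[[length(pk) + 1]] <- list(i = i, j = j, h = h)
      }
    }
    for (A in pk) for (B in pk) {
      L1 <- B$i - (A$i + A$h - 1) - 1
      j2 <- (A$j - A$h + 1) - (B$i + B$h - 1) - 1
      L3 <- (B$j - B$h + 1) - A$j - 1
      if (L1 < 1 || j2 < 0 || L3 < 1) next
      if (pseudoknot == "junction1" && j2 > 1) next
      w <- .vf_pk_weight(eng, A$i, A$j, A$h, B$i, B$j, B$h)
      if (w <= 0) next
      Qpk <- Qpk + w
      for (t in 0:(A$h - 1))
        bppnum[A$i + t, A$j - t] <- bppnum[A$i + t, A$j - t] + w
      for (t in 0:(B$h - 1))
        bppnum[B$i + t, B$j - t] <- bppnum[B$i + t, B$j - t] + w
      nstruct <- nstruct + 1L
    }
  }

  Qn <- Q
  Qtot <- Qn + Qpk
  bpp <- (bppnum + t(bppnum)) / Qtot
  out <- .vf_fold_result(seq, temperature, eng$params$dialect, pseudoknot,
                         Qtot, Qn, Qpk, bpp,
                         level_tolerance = 0.15, min_helix_prob = 0.05,
                         method = "exhaustive")
  out$n_structures <- length(structures)
  out$structures <- structures
  out
}
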