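# Preparation of the numeric tables the folding engine consumes, and exact
# R mirrors of the per-loop Boltzmann weights (used by the structure-level
# energy evaluator and the exhaustive oracle).

.vf_engine <- function(seq, temperature, params, entropies,
                       min_hairpin = 3L, max_internal = 30L,
                       c_b = 0.1, mmcap = NULL) {
  seq <- rna_sequence(seq, allow_long = TRUE)
  params <- .vf_as_params(params)
  tk <- .vf_kelvin(temperature)
  n <- attr(seq, "n")
  s <- .vf_encode(seq)
  ent <- entropies
  mmcap <- mmcap %||% ent$meta$max_total
  fits <- ent$fits
  a_hp <- fits$hairpin["a"]; c_hp <- fits$hairpin["c"]
  a_int <- unname(fits$internal["a"]); c_int <- unname(fits$internal["c"])

  e <- ent$entries
  # hairpin entropies 0..n (index L+1)
  S_hp <- rep(-Inf, n + 1)
  for (L in 3:max(3, n)) {
    if (L > n) break
    hit <- e$entropy[e$loop_type == "hairpin" & e$size1 == L]
    S_hp[L + 1] <- if (length(hit) == 1) hit else
      unname(a_hp - c_hp * log(L))
  }
  # internal entropies 0..30 x 0..30
  S_int <- matrix(NA_real_, 31, 31)
  ei <- e[e$loop_type == "internal", ]
  for (a in 0:30) for (b in 0:30) {
    if (a + b == 0) { S_int[a + 1, b + 1] <- 0; next }
    hit <- ei$entropy[ei$size1 == a & ei$size2 == b]
    S_int[a + 1, b + 1] <- if (length(hit) == 1) hit else
      a_int - c_int * log(a + b)
  }
  # mismatch-constrained tables (flat, C-style [L][u][v] / [L1][L2][u][v])
  c1 <- mmcap + 1L
  S_hpmm <- rep(-Inf, c1^3)
  eh <- e[e$loop_type == "hairpin_mm", ]
  if (nrow(eh)) {
    idx <- (eh$size1 * c1 + eh$pos1) * c1 + eh$pos2 + 1L
    S_hpmm[idx] <- eh$entropy
  }
  S_intmm <- rep(-Inf, c1^4)
  em <- e[e$loop_type == "internal_mm", ]
  if (nrow(em)) {
    idx <- ((em$size1 * c1 + em$size2) * c1 + em$pos1) * c1 + em$pos2 + 1L
    S_intmm[idx] <- em$entropy
  }
  # multiloop entropy of total unpaired length (hairpin-fit form, clamped)
  u <- 0:n
  S_ml <- pmin(0, unname(a_hp - c_hp * log(pmax(u, 1))))
  # pseudoknot-spanning loops: rows L = 0..n, cols h = 2..hmax
  hmax <- ent$meta$pk_max_helix
  ep <- e[e$loop_type == "pk", ]
  S_pk <- matrix(-Inf, n + 1, hmax - 1)
  for (h in 2:hmax) {
    f <- fits$pk[[as.character(h)]]
    for (L in 1:n) {
      hit <- ep$entropy[ep$size1 == L & ep$size2 == h]
      S_pk[L + 1, h - 1] <- if (length(hit) == 1) hit else if (!is.null(f))
        unname(f["a"] - f["c"] * log(L)) else -Inf
    }
  }
  S_junc <- c(0, vapply(seq_len(n), function(j) {
    if (j <= 30) S_int[j + 1, 1] else a_int - c_int * log(j)
  }, 0))

  # temperature-dependent stack / mismatch-stack energies (kcal/mol)
  SG <- .vf_stack_matrix_T(params, tk)
  mmT <- function(tab) {
    g <- tab$dH - tk * tab$dS
    nf <- !is.finite(g)
    if (any(nf)) {
      .vf_once(paste0("mmfall_", params$dialect), function()
        warn("mismatch stack entries without published values contribute 0 kcal/mol"))
      g[nf] <- 0
    }
    g
  }
  list(seq = seq, n = n, s = s, chars = .vf_seq_chars(seq),
       tk = tk, RT = .vf_gas_constant * tk,
       params = params, entropies = ent,
       SG = SG, emmH = mmT(params$mm_hairpin), emmI = mmT(params$mm_interior),
       mm_ok = .vf_mm_ok_matrix(),
       S_hp = S_hp, S_int = S_int, a_int = a_int, c_int = c_int,
       S_hpmm = S_hpmm, S_intmm = S_intmm, mmcap = mmcap,
       S_ml = S_ml, c_b = c_b, S_pk = S_pk, S_junc = S_junc,
       min_hairpin = as.integer(min_hairpin),
       max_internal = as.integer(max_internal))
}

# ---- R mirrors of the engine's weight assembly ---------------------------

.vf_pt_at <- function(eng, i, j) {
  .vf_pair_type(eng$chars[i], eng$chars[j])
}

.vf_s_int_fast <- function(eng, a, b) {
  if (a + b == 0) return(0)
  if (a <= 30 && b <= 30) return(eng$S_int[a + 1, b + 1])
  eng$a_int - eng$c_int * log(a + b)
}

# hairpin loop weight closed by (p, q), mismatch variants included
.vf_wh_r <- function(eng, p, q) {
  L <- q - p - 1
  if (L < eng$min_hairpin) return(0)
  w <- exp(eng$S_hp[L + 1])
  if (L >= 5) {
    c1 <- eng$mmcap + 1L
    for (u in 1:(L - 4)) for (v in (u + 4):L) {
      if (!eng$mm_ok[eng$s[p + u] + 1, eng$s[p + v] + 1]) next
      S <- if (L <= eng$mmcap)
        eng$S_hpmm[(L * c1 + u) * c1 + v + 1]
      else
        eng$S_hp[v - u] + .vf_s_int_fast(eng, u - 1, L - v)
      if (!is.finite(S)) next
      fac <- exp(S)
      if (u == 1 && v == L) {
        pt <- .vf_pt_at(eng, p, q)
        fac <- fac * exp(-eng$emmH[pt, eng$s[p + 1] + 1, eng$s[q - 1] + 1] / eng$RT)
      }
      w <- w + fac
    }
  }
  w
}

# internal/bulge loop weight between (p,q) and inner helix pair (pp,qq)
.vf_wint_r <- function(eng, p, q, pp, qq) {
  L1 <- pp - p - 1; L2 <- q - qq - 1
  base <- .vf_s_int_fast(eng, L1, L2)
  w <- if (is.finite(base)) exp(base) else 0
  if (L1 >= 1 && L2 >= 1) {
    c1 <- eng$mmcap + 1L
    small <- (L1 + L2) <= eng$mmcap
    for (u in 1:L1) for (v in 1:L2) {
      if (!eng$mm_ok[eng$s[p + u] + 1, eng$s[qq + v] + 1]) next
      S <- if (small)
        eng$S_intmm[((L1 * c1 + L2) * c1 + u) * c1 + v + 1]
      else
        .vf_s_int_fast(eng, u - 1, L2 - v) + .vf_s_int_fast(eng, L1 - u, v - 1)
      if (!is.finite(S)) next
      fac <- exp(S)
      if (u == 1 && v == L2) {
        pt <- .vf_pt_at(eng, p, q)
        fac <- fac * exp(-eng$emmI[pt, eng$s[p + 1] + 1, eng$s[q - 1] + 1] / eng$RT)
      }
      if (u == L1 && v == 1) {
        pt2 <- .vf_pt_at(eng, qq, pp)
        fac <- fac * exp(-eng$emmI[pt2, eng$s[qq + 1] + 1, eng$s[pp - 1] + 1] / eng$RT)
      }
      w <- w + fac
    }
  }
  w
}

# stack weight product along a helix placement (i, j, h)
.vf_helix_stack_weight <- function(eng, i, j, h) {
  w <- 1
  for (t in 1:(h - 1)) {
    po <- .vf_pt_at(eng, i + t - 1, j - t + 1)
    pi <- .vf_pt_at(eng, i + t, j - t)
    w <- w * exp(-eng$SG[po, pi] / eng$RT)
  }
  w
}
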