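# Folding thermodynamics: Q(T) on a temperature grid, heat capacity C(T),
# melting-transition peaks.

#' Partition function over a temperature grid
#'
#' Evaluates ln Q at every grid temperature with the same engine as
#' [fold_rna()] (base-pair probabilities are skipped for speed).
#'
#' @inheritParams fold_rna
#' @param t_min,t_max,t_step temperature grid in degrees Celsius
#'   (default 0-100 in 0.5 steps, i.e. 201 points).
#' @return tibble with columns `temperature` and `lnQ`.
#' @export
partition_over_temperature <- function(seq, t_min = 0, t_max = 100,
                                       t_step = 0.5,
                                       params = "turner04",
                                       pseudoknot = c("none", "junction1", "any"),
                                       entropies = loop_entropy_table(),
                                       multiloop_branch_penalty = 0.1) {
  pseudoknot <- match.arg(pseudoknot)
  if (!(t_min < t_max) || t_step <= 0)
    abort("need t_min < t_max and t_step > 0", class = "vfold_grid_error")
  seq <- rna_sequence(seq)
  grid <- seq(t_min, t_max, by = t_step)
  lnQ <- vapply(grid, function(tc) {
    eng <- .vf_engine(seq, tc, params, entropies,
                      c_b = multiloop_branch_penalty)
    res <- vf_fold_cpp(eng$s, eng$RT, eng$SG,
                       as.numeric(eng$emmH), as.numeric(eng$emmI), eng$mm_ok,
                       eng$S_hp, eng$S_int, eng$a_int, eng$c_int,
                       eng$S_hpmm, eng$S_intmm, eng$mmcap,
                       eng$S_ml, eng$c_b, eng$S_pk, eng$S_junc,
                       .vf_pk_modes[[pseudoknot]],
                       eng$min_hairpin, eng$max_internal, FALSE)
    res$lnQ
  }, 0)
  tibble(temperature = grid, lnQ = lnQ)
}

#' Heat capacity from ln Q on a uniform grid
#'
#' C(T) = d/dT \[ R T_K^2 d lnQ / dT \] by central finite differences:
#' C_i = R (T_K^2 u'' + 2 T_K u') with u = lnQ. Defined on the grid minus
#' one point at each boundary; excess heat capacity relative to the open
#' chain, per mole of strand, in kcal/(mol K).
#'
#' @param curve tibble with `temperature` (uniform grid, degrees C) and
#'   `lnQ` columns (at least 5 points).
#' @return the input tibble with a `C` column (`NA` at the two boundary
#'   points).
#' @export
heat_capacity <- function(curve) {
  tc <- curve$temperature
  u <- curve$lnQ
  m <- length(tc)
  if (m < 5) abort("need at least 5 grid points", class = "vfold_grid_error")
  dt <- diff(tc)
  if (any(abs(dt - dt[1]) > 1e-9))
    abort("temperature grid must be uniform", class = "vfold_grid_error")
  h <- dt[1]
  tk <- tc + .vf_T0
  C <- rep(NA_real_, m)
  i <- 2:(m - 1)
  d1 <- (u[i + 1] - u[i - 1]) / (2 * h)
  d2 <- (u[i + 1] - 2 * u[i] + u[i - 1]) / h^2
  C[i] <- .vf_gas_constant * (tk[i]^2 * d2 + 2 * tk[i] * d1)
  out <- curve
  out$C <- C
  out
}

#' Detect melting-transition peaks in a heat-capacity curve
#'
#' Strict local maxima of C(T) with prominence at least `min_prominence`
#' (default 5% of the maximum C), sorted by temperature. Prominence is the
#' height of the peak above the higher of the two bracketing minima that
#' separate it from any higher point.
#'
#' @param curve tibble with `temperature` and `C` (from [heat_capacity()]).
#' @param min_prominence absolute prominence threshold; default
#'   `0.05 * max(C)`.
#' @return tibble with `t_peak` and `C_peak`.
#' @export
find_melting_peaks <- function(curve, min_prominence = NULL) {
  ok <- is.finite(curve$C)
  tc <- curve$temperature[ok]
  C <- curve$C[ok]
  m <- length(C)
  if (m < 3) return(tibble(t_peak = numeric(), C_peak = numeric()))
  if (is.null(min_prominence)) min_prominence <- 0.05 * max(C)
  peaks <- which(vapply(2:(m - 1), function(i)
    C[i] > C[i - 1] && C[i] > C[i + 1], TRUE)) + 1L
  keep <- vapply(peaks, function(i) {
    # walk outward until a higher point or the boundary; prominence is the
    # drop to the highest of the two valley minima
    left <- C[seq_len(i - 1)]
    right <- C[(i + 1):m]
    higher_l <- which(left > C[i])
    base_l <- if (length(higher_l)) min(left[(max(higher_l)):(i - 1)]) else min(left)
    higher_r <- which(right > C[i])
    base_r <- if (length(higher_r)) min(right[seq_len(min(higher_r))]) else min(right)
    (C[i] - max(base_l, base_r)) >= min_prominence
  }, TRUE)
  tibble(t_peak = tc[peaks[keep]], C_peak = C[peaks[keep]])
}

#' Heat-capacity melting curve of a sequence
#'
#' Runs [partition_over_temperature()], [heat_capacity()] and
#' [find_melting_peaks()] in one call.
#'
#' @inheritParams partition_over_temperature
#' @param min_prominence passed to [find_melting_peaks()].
#' @return an object of class `vfold_melt`: the curve tibble
#'   (`temperature`, `lnQ`, `C`), detected `peaks`, and the run metadata.
#' @examples
#' \donttest{
#' m <- melting_curve("GGGAGCAAAAGCUCCC", t_step = 2)
#' m$peaks
#' }
#' @export
melting_curve <- function(seq, t_min = 0, t_max = 100, t_step = 0.5,
                          params = "turner04",
                          pseudoknot = c("none", "junction1", "any"),
                          entropies = loop_entropy_table(),
                          min_prominence = NULL,
                          multiloop_branch_penalty = 0.1) {
  pseudoknot <- match.arg(pseudoknot)
  seq <- rna_sequence(seq)
  curve <- partition_over_temperature(seq, t_min, t_max, t_step, params,
                                      pseudoknot, entropies,
                                      multiloop_branch_penalty)
  curve <- heat_capacity(curve)
  peaks <- find_melting_peaks(curve, min_prominence)
  out <- list(seq = seq, curve = curve, peaks = peaks,
              t_step = t_step,
              dialect = .vf_as_params(params)$dialect,
              pseudoknot = pseudoknot)
  class(out) <- "vfold_melt"
  out
}

#' @export
print.vfold_melt <- function(x, ...) {
  cat(sprintf("<vfold_melt> %d nt, %.4g-%.4g C (step %.2g), %s\n",
              attr(x$seq, "n"), min(x$curve$temperature),
              max(x$curve$temperature), x$t_step, x$dialect))
  if (nrow(x$peaks)) {
    cat("  melting transitions:\n")
    for (r in seq_len(nrow(x$peaks)))
      cat(sprintf("    T = %.1f C (C = %.3g kcal/(mol K))\n",
                  x$peaks$t_peak[r], x$peaks$C_peak[r]))
  } else cat("  no transitions detected\n")
  invisible(x)
}
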