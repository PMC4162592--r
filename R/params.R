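# Nearest-neighbor thermodynamic parameter sets (two dialects).

.vf_pair_codes <- c("CG", "GC", "GU", "UG", "AU", "UA")

# pair type code for bases a, b (characters); 0 if not canonical
.vf_pair_type <- function(a, b) {
  m <- match(paste0(a, b), .vf_pair_codes, nomatch = 0L)
  m
}

.vf_rev_pair <- function(p) {
  paste0(substr(p, 2, 2), substr(p, 1, 1))
}

#' Nearest-neighbor energy parameter set
#'
#' Returns the embedded stack and terminal-mismatch thermodynamic tables for
#' one of the two supported dialects:
#'
#' * `"turner04"` — the Turner-lab 2004 compilation (Watson-Crick stacks of
#'   Xia et al. 1998 plus the 2004 wobble/mismatch revision), transcribed
#'   from the standard redistributed parameter files.
#' * `"mfold23"` — the older mfold-era rules: Freier et al. (1986)
#'   Watson-Crick stacks (exact literature transcription) with approximate
#'   wobble extensions of that era, and terminal mismatches from the 1999
#'   compilation. The wobble and wobble-enthalpy entries of this dialect are
#'   representative rather than an exact transcription (the original mfold
#'   2.x energy files are not redistributable); they are chosen so that the
#'   37 degC values sit in the historically used range.
#'
#' Entropies are derived from the stored (dH, dG37) pairs as
#' dS = (dH - dG37) / 310.15, which makes the dG37 self-consistency exact by
#' construction.
#'
#' @param dialect `"turner04"` or `"mfold23"`.
#' @return an object of class `vfold_params`: stack and mismatch tables
#'   (kcal/mol), gas constant, dialect name.
#' @examples
#' p <- energy_params("turner04")
#' stack_free_energy("GC", "GC", temperature = 37, params = p)
#' @export
energy_params <- function(dialect = c("turner04", "mfold23")) {
  dialect <- match.arg(dialect)
  dG <- .vf_stack_dG37[[dialect]]
  dH <- .vf_stack_dH[[dialect]]
  mk <- function(g, h) list(dG37 = g, dH = h, dS = (h - g) / 310.15)
  out <- list(
    dialect = dialect,
    stack = mk(dG, dH),
    mm_hairpin = mk(.vf_mm_hairpin_dG37[[dialect]], .vf_mm_hairpin_dH[[dialect]]),
    mm_interior = mk(.vf_mm_interior_dG37[[dialect]], .vf_mm_interior_dH[[dialect]]),
    gas_constant = .vf_gas_constant
  )
  class(out) <- "vfold_params"
  out
}

.vf_as_params <- function(params) {
  if (inherits(params, "vfold_params")) return(params)
  if (is.character(params) && length(params) == 1L) return(energy_params(params))
  abort("params must be a dialect name or an energy_params() object",
        class = "vfold_parameter_error")
}

#' @export
print.vfold_params <- function(x, ...) {
  cat("<vfold_params> dialect:", x$dialect, "\n")
  cat("  stack dG37 range:",
      sprintf("%.2f .. %.2f kcal/mol\n", min(x$stack$dG37), max(x$stack$dG37)))
  invisible(x)
}

.vf_check_pair <- function(p) {
  if (!p %in% .vf_pair_codes)
    abort(sprintf("'%s' is not an allowed base pair (%s)",
                  p, paste(.vf_pair_codes, collapse = ", ")),
          class = "vfold_parameter_missing")
  p
}

# temperature-dependent stack matrix SG[outer, inner] (unreversed inner)
.vf_stack_matrix_T <- function(params, tk) {
  g <- params$stack$dH - tk * params$stack$dS
  # columns of the stored matrix are reversed inner pairs; re-index so that
  # SG[outer, inner] is direct
  rev_idx <- match(vapply(.vf_pair_codes, .vf_rev_pair, ""), .vf_pair_codes)
  g[, rev_idx, drop = FALSE]
}

#' Stack free energy at temperature
#'
#' Free energy dG(T) = dH - T_kelvin * dS of stacking `inner` (the pair at
#' i+1, j-1) on `outer` (the pair at i, j), both read 5'->3' on the top
#' strand. The lookup is invariant under strand rotation of the key.
#'
#' @param outer,inner two-character pair strings, e.g. `"GC"`.
#' @param temperature temperature in degrees Celsius.
#' @param params dialect name or [energy_params()] object.
#' @return free energy in kcal/mol.
#' @export
stack_free_energy <- function(outer, inner, temperature = 37,
                              params = energy_params()) {
  params <- .vf_as_params(params)
  tk <- .vf_kelvin(temperature)
  .vf_check_pair(outer); .vf_check_pair(inner)
  dH <- params$stack$dH[outer, .vf_rev_pair(inner)]
  dS <- params$stack$dS[outer, .vf_rev_pair(inner)]
  unname(dH - tk * dS)
}

#' Terminal/intra-loop mismatch stack free energy
#'
#' dG(T) for a mismatch pair (x, y) stacked on a closing canonical pair, in
#' hairpin or internal-loop context. Where the dialect publishes no finite
#' value the contribution falls back to 0 kcal/mol with a one-time warning.
#'
#' @param closing two-character canonical closing pair (5' base first).
#' @param x,y the mismatching bases directly inside the closing pair
#'   (x = 3' of the closing 5' base, y = 5' of the closing 3' base).
#' @param context `"hairpin"` or `"interior"`.
#' @inheritParams stack_free_energy
#' @return free energy in kcal/mol.
#' @export
mismatch_stack_free_energy <- function(closing, x, y,
                                       context = c("hairpin", "interior"),
                                       temperature = 37,
                                       params = energy_params()) {
  context <- match.arg(context)
  params <- .vf_as_params(params)
  tk <- .vf_kelvin(temperature)
  .vf_check_pair(closing)
  tab <- if (context == "hairpin") params$mm_hairpin else params$mm_interior
  dH <- tab$dH[closing, x, y]
  dS <- tab$dS[closing, x, y]
  v <- dH - tk * dS
  if (!is.finite(v)) {
    .vf_once(paste0("mmfall_", params$dialect), function()
      warn("mismatch stack entries without published values contribute 0 kcal/mol"))
    v <- 0
  }
  unname(v)
}

# mismatch alphabet: all non-canonical pairs except A.A
.vf_mm_ok_matrix <- function() {
  m <- matrix(1L, 4, 4, dimnames = list(.vf_bases_chr, .vf_bases_chr))
  for (a in .vf_bases_chr) for (b in .vf_bases_chr)
    if (.vf_pair_type(a, b) > 0) m[a, b] <- 0L
  m["A", "A"] <- 0L
  m
}

#' Loop free energy
#'
#' dG_loop(T) = -T_kelvin * R * dS_loop(sizes) plus the free energies of any
#' closing/mismatch stacks. Loop entropies come from the lattice-enumerated
#' table (units of R), extrapolated where the requested size is beyond the
#' enumeration cap.
#'
#' @param loop_type `"hairpin"`, `"internal"`, `"bulge"`, or `"pk_loop"`.
#' @param sizes loop sizes: hairpin — the unpaired length; internal — the
#'   two strand lengths; bulge — the bulged length; pk_loop — loop length
#'   and spanned helix length.
#' @param closing_stacks optional list of stack terms to add; each element
#'   either `c(outer, inner)` (canonical stack) or
#'   `list(closing =, x =, y =, context =)` (mismatch stack).
#' @inheritParams stack_free_energy
#' @param entropies a [loop_entropy_table()] object.
#' @return free energy in kcal/mol (`Inf` for an unformable loop).
#' @export
loop_free_energy <- function(loop_type = c("hairpin", "internal", "bulge", "pk_loop"),
                             sizes, closing_stacks = list(),
                             temperature = 37, params = energy_params(),
                             entropies = loop_entropy_table()) {
  loop_type <- match.arg(loop_type)
  params <- .vf_as_params(params)
  tk <- .vf_kelvin(temperature)
  sizes <- as.integer(sizes)
  if (loop_type == "hairpin") {
    if (length(sizes) != 1L || sizes[1] < 3)
      abort("hairpin loops need a single size >= 3 unpaired nt",
            class = "vfold_invalid_loop")
  } else if (loop_type == "internal") {
    if (length(sizes) != 2L || any(sizes < 1))
      abort("internal loops need two sizes >= 1", class = "vfold_invalid_loop")
  } else if (loop_type == "bulge") {
    if (length(sizes) != 1L || sizes[1] < 1)
      abort("bulge loops need a single size >= 1", class = "vfold_invalid_loop")
    sizes <- c(sizes, 0L)
    loop_type <- "internal"
  } else {
    if (length(sizes) != 2L || sizes[1] < 1 || sizes[2] < 2)
      abort("pk loops need (loop length >= 1, spanned helix length >= 2)",
            class = "vfold_invalid_loop")
  }
  S <- extrapolate_entropy(entropies, loop_type, sizes)$entropy
  g <- -tk * params$gas_constant * S
  for (st in closing_stacks) {
    if (is.character(st) && length(st) == 2L) {
      g <- g + stack_free_energy(st[1], st[2], temperature, params)
    } else if (is.list(st)) {
      g <- g + mismatch_stack_free_energy(st$closing, st$x, st$y,
                                          context = st$context %||% "hairpin",
                                          temperature, params)
    } else {
      abort("unrecognized closing stack specification",
            class = "vfold_parameter_error")
    }
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export the active parameter tables as tab-separated text
#'
#' Writes the stack dH/dS/dG37 table of a dialect for audit.
#'
#' @param params dialect name or [energy_params()] object.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
export_params <- function(params, path) {
  params <- .vf_as_params(params)
  rows <- expand.grid(outer = .vf_pair_codes, inner_rev = .vf_pair_codes,
                      stringsAsFactors = FALSE)
  df <- data.frame(
    outer = rows$outer,
    inner = vapply(rows$inner_rev, .vf_rev_pair, ""),
    dH = mapply(function(a, b) params$stack$dH[a, b], rows$outer, rows$inner_rev),
    dS = mapply(function(a, b) params$stack$dS[a, b], rows$outer, rows$inner_rev),
    dG37 = mapply(function(a, b) params$stack$dG37[a, b], rows$outer, rows$inner_rev)
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
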