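# Readers and writers for the tool's text formats. All writers use fixed
# decimal formatting (probabilities to 4 decimals, energies to 2) and
# stable ordering, so identical inputs give byte-identical files.

#' Read an RNA sequence from text or a FASTA file
#'
#' Accepts a plain sequence string, a path to a plain-text sequence file,
#' or a path to a single-record FASTA file. T is converted to U and case is
#' folded (see [rna_sequence()]).
#'
#' @param x sequence string or file path.
#' @param max_length,allow_long passed to [rna_sequence()].
#' @return an [rna_sequence()].
#' @export
read_rna <- function(x, max_length = 140, allow_long = FALSE) {
  if (length(x) == 1L && file.exists(x)) {
    first <- readLines(x, n = 1)
    if (startsWith(first, ">")) {
      set <- Biostrings::readBStringSet(x)
      if (length(set) != 1L)
        abort("FASTA file must contain exactly one record",
              class = "vfold_parse_error")
      return(rna_sequence(as.character(set[[1]]), max_length, allow_long))
    }
    return(rna_sequence(paste(readLines(x), collapse = ""),
                        max_length, allow_long))
  }
  rna_sequence(x, max_length, allow_long)
}

#' Write / read base-pair probabilities
#'
#' Whitespace-separated text `i j P_ij` (1-based indices, probabilities to
#' 4 decimals, upper triangle, entries above a floor, ordered by i then j).
#'
#' @param x a `vfold_fold` object or probability matrix.
#' @param path file path.
#' @param min_prob entries below this are not written.
#' @return the path (writer, invisibly) / a tibble `i, j, prob` (reader).
#' @export
write_bpp <- function(x, path, min_prob = 1e-4) {
  bpp <- if (inherits(x, "vfold_fold")) x$bpp else x
  idx <- which(upper.tri(bpp) & bpp >= min_prob, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  lines <- sprintf("%d %d %.4f", idx[, 1], idx[, 2], bpp[idx])
  writeLines(c("# i j P_ij", lines), path)
  invisible(path)
}

#' @rdname write_bpp
#' @export
read_bpp <- function(path) {
  df <- read.delim(path, sep = "", comment.char = "#", header = FALSE,
                   col.names = c("i", "j", "prob"))
  as_tibble(df)
}

#' Write / read helix probabilities
#'
#' Text columns `i j length P` for every predicted helix (outer pair,
#' length, probability to 4 decimals), sorted by decreasing probability.
#'
#' @param x a `vfold_fold` object or a helix tibble.
#' @inheritParams write_bpp
#' @export
write_helices <- function(x, path) {
  hel <- if (inherits(x, "vfold_fold")) x$helices else x
  lines <- sprintf("%d %d %d %.4f", hel$i, hel$j, hel$length, hel$prob)
  writeLines(c("# i j length P", lines), path)
  invisible(path)
}

#' @rdname write_helices
#' @export
read_helices <- function(path) {
  df <- read.delim(path, sep = "", comment.char = "#", header = FALSE,
                   col.names = c("i", "j", "length", "prob"))
  as_tibble(df)
}

#' Write predicted structures (dot-bracket and CT)
#'
#' Writes the dominant and alternative structures of a fold as dot-bracket
#' lines (with probabilities) and, optionally, the dominant structure as a
#' CT file.
#'
#' @param fold a `vfold_fold` object.
#' @param path output path for the dot-bracket text.
#' @param ct_path optional CT output path for the dominant structure.
#' @export
write_structure <- function(fold, path, ct_path = NULL) {
  lines <- c(sprintf("# %s", as.character(fold$seq)),
             sprintf("%s %.4f dominant",
                     pairs_to_dotbracket(fold$dominant$pairs, fold$n),
                     if (is.na(fold$dominant$probability)) 0 else
                       fold$dominant$probability))
  for (alt in fold$alternatives)
    lines <- c(lines, sprintf("%s %.4f alternative",
                              pairs_to_dotbracket(alt$pairs, fold$n),
                              alt$probability))
  writeLines(lines, path)
  if (!is.null(ct_path))
    write_ct(fold$seq, fold$dominant$pairs, ct_path)
  invisible(path)
}

#' Write / read a melting curve
#'
#' Two-column text `T_celsius C` (and a companion `T_celsius lnQ` file),
#' energies to 6 significant digits.
#'
#' @param melt a `vfold_melt` object or curve tibble.
#' @param path output path for the C(T) file.
#' @param lnq_path optional companion ln Q file.
#' @export
write_melting <- function(melt, path, lnq_path = NULL) {
  curve <- if (inherits(melt, "vfold_melt")) melt$curve else melt
  ok <- is.finite(curve$C)
  writeLines(c("# T_celsius C",
               sprintf("%.4f %.6g", curve$temperature[ok], curve$C[ok])), path)
  if (!is.null(lnq_path))
    writeLines(c("# T_celsius lnQ",
                 sprintf("%.4f %.6g", curve$temperature, curve$lnQ)),
               lnq_path)
  invisible(path)
}

#' @rdname write_melting
#' @export
read_melting <- function(path) {
  df <- read.delim(path, sep = "", comment.char = "#", header = FALSE,
                   col.names = c("temperature", "C"))
  as_tibble(df)
}

#' Read a YAML configuration file of defaults
#'
#' One key per line (`temperature`, `params`, `pseudoknot`, `t_min`,
#' `t_max`, `t_step`); unknown keys are rejected.
#'
#' @param path file path.
#' @return a named list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("temperature", "params", "pseudoknot", "t_min", "t_max", "t_step")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    abort(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")),
          class = "vfold_parse_error")
  cfg
}
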