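# RNA sequence validation and encoding.

.vf_bases_chr <- c("A", "C", "G", "U")

#' Validate an RNA sequence
#'
#' Normalizes and validates a nucleotide string: uppercases, converts T to U
#' (with a note), and checks the alphabet. Sequences longer than
#' `max_length` (default 140 nt, the scale the folding engine is designed
#' for) are rejected unless `allow_long = TRUE`, in which case a warning is
#' emitted.
#'
#' @param x a character scalar over A/C/G/U (case-insensitive; T accepted
#'   and converted).
#' @param max_length maximum accepted length in nt.
#' @param allow_long allow sequences beyond `max_length` (with a warning).
#' @return the normalized sequence string, with attribute `n` (its length).
#' @examples
#' rna_sequence("gcgaaagc")
#' rna_sequence("ACGT")   # T -> U with a note
#' @export
rna_sequence <- function(x, max_length = 140, allow_long = FALSE) {
  if (inherits(x, "vfold_seq")) return(x)
  if (!is.character(x) || length(x) != 1L)
    abort("sequence must be a single character string", class = "vfold_parse_error")
  s <- toupper(gsub("[[:space:]]", "", x))
  if (grepl("T", s, fixed = TRUE)) {
    message("DNA alphabet detected: converting T to U")
    s <- gsub("T", "U", s, fixed = TRUE)
  }
  bad <- regexpr("[^ACGU]", s)
  if (bad > 0)
    abort(sprintf("non-nucleotide character '%s' at position %d",
                  substr(s, bad, bad), bad),
          class = "vfold_parse_error")
  n <- nchar(s)
  if (n < 1) abort("empty sequence", class = "vfold_parse_error")
  if (n > max_length) {
    if (!allow_long)
      abort(sprintf("sequence length %d exceeds the %d-nt limit (set allow_long = TRUE to override)",
                    n, max_length),
            class = "vfold_length_error")
    warn(sprintf("sequence length %d exceeds the %d-nt limit; expect long run times",
                 n, max_length))
  }
  structure(s, n = n, class = c("vfold_seq", "character"))
}

# integer encoding A=0 C=1 G=2 U=3 (matches the C++ engine)
.vf_encode <- function(seq) {
  match(strsplit(unclass(seq), "")[[1]], .vf_bases_chr) - 1L
}

.vf_seq_chars <- function(seq) strsplit(unclass(seq), "")[[1]]
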