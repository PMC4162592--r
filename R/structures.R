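# Secondary-structure representation: pair lists, dot-bracket, CT.

# normalize a structure to a 2-column matrix of pairs with i < j
.vf_pairs_mat <- function(x, n = NULL) {
  if (is.character(x) && length(x) == 1L) x <- parse_dotbracket(x)
  if (is.data.frame(x)) x <- as.matrix(x[, 1:2])
  if (is.null(x) || length(x) == 0) return(matrix(integer(0), 0, 2))
  x <- matrix(as.integer(x), ncol = 2)
  sw <- x[, 1] > x[, 2]
  x[sw, ] <- x[sw, c(2, 1)]
  x <- x[order(x[, 1]), , drop = FALSE]
  if (anyDuplicated(c(x)))
    abort("an index appears in more than one pair", class = "vfold_invalid_structure")
  if (!is.null(n) && nrow(x) && (min(x) < 1 || max(x) > n))
    abort("pair index outside the sequence", class = "vfold_invalid_structure")
  x
}

.vf_partner <- function(pairs, n) {
  pr <- integer(n)
  if (nrow(pairs)) {
    pr[pairs[, 1]] <- pairs[, 2]
    pr[pairs[, 2]] <- pairs[, 1]
  }
  pr
}

# maximal helices: runs of consecutive pairs (i,j),(i+1,j-1),...
.vf_helix_runs <- function(pairs) {
  if (!nrow(pairs)) return(tibble(i = integer(), j = integer(), length = integer()))
  key <- paste(pairs[, 1], pairs[, 2])
  prev <- paste(pairs[, 1] - 1L, pairs[, 2] + 1L)
  is_start <- !(prev %in% key)
  starts <- which(is_start)
  res <- lapply(starts, function(s) {
    i <- pairs[s, 1]; j <- pairs[s, 2]; h <- 1L
    while (paste(i + h, j - h) %in% key) h <- h + 1L
    tibble(i = i, j = j, length = h)
  })
  dplyr::bind_rows(res)
}

.vf_cross <- function(h1, h2) {
  # do two helices (outer pairs) cross?
  (h1$i < h2$i && h2$i <= h1$j && h1$j < h2$j) ||
    (h2$i < h1$i && h1$i <= h2$j && h2$j < h1$j)
}

#' Validate a secondary structure for a sequence
#'
#' Checks the structural invariants of the model: every pair is an allowed
#' type (Watson-Crick or wobble) at its positions, no index pairs twice,
#' hairpin loops span at least 3 unpaired nt, and every pair belongs to a
#' helix of at least 2 consecutive pairs. Crossing pairs are allowed and mark the
#' structure pseudoknotted.
#'
#' @param seq sequence (string or [rna_sequence()]).
#' @param structure pairs as a 2-column matrix/data frame or a dot-bracket
#'   string.
#' @return list with `pairs`, `helices` (tibble), `pseudoknotted`.
#' @export
validate_structure <- function(seq, structure) {
  seq <- rna_sequence(seq, allow_long = TRUE)
  n <- attr(seq, "n")
  ch <- .vf_seq_chars(seq)
  pairs <- .vf_pairs_mat(structure, n)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (.vf_pair_type(ch[i], ch[j]) == 0)
      abort(sprintf("pair %s%d-%s%d is not an allowed pair type",
                    ch[i], i, ch[j], j),
            class = "vfold_invalid_structure")
  }
  hel <- .vf_helix_runs(pairs)
  if (nrow(hel) && any(hel$length < 2))
    abort("every pair must belong to a helix of >= 2 consecutive pairs",
          class = "vfold_invalid_structure")
  pr <- .vf_partner(pairs, n)
  # hairpin minimum: innermost pairs
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (j - i - 1 >= 0 && j > i + 1) {
      inside <- pr[(i + 1):(j - 1)]
      if (all(inside == 0) && (j - i - 1) < 3)
        abort(sprintf("hairpin closed by (%d,%d) spans fewer than 3 unpaired nt", i, j),
              class = "vfold_invalid_structure")
    } else if (j == i + 1) {
      abort(sprintf("pair (%d,%d) leaves no room for a loop", i, j),
            class = "vfold_invalid_structure")
    }
  }
  pk <- FALSE
  if (nrow(hel) > 1) {
    for (a in 1:(nrow(hel) - 1)) for (b in (a + 1):nrow(hel))
      if (.vf_cross(hel[a, ], hel[b, ])) pk <- TRUE
  }
  list(pairs = pairs, helices = hel, pseudoknotted = pk)
}

#' Parse and render dot-bracket strings
#'
#' `parse_dotbracket()` accepts the layers `()`, `[]` and `{}` (pseudoknot
#' layers) and returns a pair matrix; `pairs_to_dotbracket()` renders a pair
#' set, assigning crossing helices to successive bracket layers.
#'
#' @param x a dot-bracket string.
#' @return `parse_dotbracket`: 2-column integer matrix of pairs.
#' @export
parse_dotbracket <- function(x) {
  ch <- strsplit(x, "")[[1]]
  open <- c("(" = 1, "[" = 2, "{" = 3)
  close <- c(")" = 1, "]" = 2, "}" = 3)
  stacks <- list(integer(0), integer(0), integer(0))
  out <- list()
  for (k in seq_along(ch)) {
    c0 <- ch[k]
    if (c0 %in% names(open)) {
      l <- open[[c0]]
      stacks[[l]] <- c(stacks[[l]], k)
    } else if (c0 %in% names(close)) {
      l <- close[[c0]]
      if (!length(stacks[[l]]))
        abort(sprintf("unbalanced '%s' at position %d", c0, k),
              class = "vfold_parse_error")
      i <- stacks[[l]][length(stacks[[l]])]
      stacks[[l]] <- stacks[[l]][-length(stacks[[l]])]
      out[[length(out) + 1]] <- c(i, k)
    } else if (c0 != "." && c0 != "-") {
      abort(sprintf("unexpected character '%s' at position %d in dot-bracket", c0, k),
            class = "vfold_parse_error")
    }
  }
  if (any(lengths(stacks) > 0))
    abort("unbalanced brackets in dot-bracket string", class = "vfold_parse_error")
  .vf_pairs_mat(do.call(rbind, c(out, list(matrix(integer(0), 0, 2)))))
}

#' @rdname parse_dotbracket
#' @param pairs pair matrix (2 columns) or data frame.
#' @param n sequence length.
#' @export
pairs_to_dotbracket <- function(pairs, n) {
  pairs <- .vf_pairs_mat(pairs, n)
  hel <- .vf_helix_runs(pairs)
  out <- rep(".", n)
  if (!nrow(hel)) return(paste(out, collapse = ""))
  sym_open <- c("(", "[", "{")
  sym_close <- c(")", "]", "}")
  layer <- integer(nrow(hel))
  for (a in seq_len(nrow(hel))) {
    used <- c()
    for (b in seq_len(a - 1)) {
      if (.vf_cross(hel[a, ], hel[b, ])) used <- c(used, layer[b])
    }
    l <- 1L
    while (l %in% used) l <- l + 1L
    if (l > 3) abort("more than three pseudoknot layers are not renderable",
                     class = "vfold_invalid_structure")
    layer[a] <- l
  }
  for (a in seq_len(nrow(hel))) {
    for (t in 0:(hel$length[a] - 1)) {
      out[hel$i[a] + t] <- sym_open[layer[a]]
      out[hel$j[a] - t] <- sym_close[layer[a]]
    }
  }
  paste(out, collapse = "")
}

#' Read and write CT (connectivity table) files
#'
#' The standard 6-column CT format: index, base, i-1, i+1, partner (0 if
#' unpaired), index.
#'
#' @param path file path.
#' @return `read_ct`: list with `seq` and `pairs`; `write_ct`: the path,
#'   invisibly.
#' @export
read_ct <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) abort("empty CT file", class = "vfold_parse_error")
  hdr <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  n <- suppressWarnings(as.integer(hdr[1]))
  if (is.na(n)) abort("CT header must start with the sequence length",
                      class = "vfold_parse_error")
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n) abort("CT file shorter than its header claims",
                              class = "vfold_parse_error")
  fields <- strsplit(trimws(body[seq_len(n)]), "[[:space:]]+")
  base <- vapply(fields, `[`, "", 2)
  partner <- as.integer(vapply(fields, `[`, "", 5))
  seq <- rna_sequence(paste(base, collapse = ""), allow_long = TRUE)
  keep <- partner > seq_len(n)
  pairs <- cbind(seq_len(n)[keep], partner[keep])
  list(seq = seq, pairs = .vf_pairs_mat(pairs, n))
}

#' @rdname read_ct
#' @param seq sequence.
#' @param pairs pair matrix.
#' @param title optional CT title string.
#' @export
write_ct <- function(seq, pairs, path, title = "vfold") {
  seq <- rna_sequence(seq, allow_long = TRUE)
  n <- attr(seq, "n")
  ch <- .vf_seq_chars(seq)
  pr <- .vf_partner(.vf_pairs_mat(pairs, n), n)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d %s", n, title), con)
  for (i in seq_len(n)) {
    writeLines(sprintf("%5d %s %5d %5d %5d %5d",
                       i, ch[i], i - 1L, if (i < n) i + 1L else 0L, pr[i], i),
               con)
  }
  invisible(path)
}
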