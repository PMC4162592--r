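# Deterministic sequence fixtures: designed hairpins, bistable two-helix
# sequences, toy H-type pseudoknots, seeded random sequences.

.vf_revcomp <- function(x) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

#' Generate a test/demo fixture sequence
#'
#' Deterministic sequence generators with an annotated intended structure:
#'
#' * `"hairpin"` — a GC-rich stem-loop: stem of `stem` bp, loop of `loop`
#'   A's.
#' * `"bistable"` — a sequence with two mutually exclusive pairings for its
#'   5' strand. With `balanced = FALSE` (default, 39 nt): the dominant
#'   structure is a weak all-AU hairpin (low melting temperature) in tandem
#'   with a strong GC hairpin (high melting temperature), and the
#'   alternative pairs the same 5' strand with a 3' decoy instead — the two
#'   helix sets cannot coexist and the melting curve shows one peak per
#'   helix stability. With `balanced = TRUE` (14 nt) the ensemble is
#'   exactly open chain + two competing 2-bp GC helices with identical
#'   stack and loop terms, so their ensemble weights are exactly equal.
#' * `"pseudoknot"` — a toy H-type pseudoknot `P1 L1 P2 J P1' L3 P2'` with
#'   two crossing stems of `stem` bp.
#' * `"random"` — seeded uniform A/C/G/U sequence of length `length`.
#'
#' Identical arguments always give identical sequences.
#'
#' @param kind fixture kind.
#' @param stem,loop,junction,length size parameters (nt / bp).
#' @param balanced for `"bistable"`: equal-stability symmetric version.
#' @param seed integer seed (`"random"` only).
#' @return list with `seq` (an [rna_sequence()]) and `structure` (annotated
#'   intended pairs; for `"bistable"` the two competing helices are in
#'   `structure` and `structure_alt`).
#' @examples
#' make_fixture("hairpin", stem = 3, loop = 4)$seq
#' @export
make_fixture <- function(kind = c("hairpin", "bistable", "pseudoknot", "random"),
                         stem = 3, loop = 4, junction = 1, length = 20,
                         balanced = FALSE, seed = 1) {
  kind <- match.arg(kind)
  stem <- as.integer(stem); loop <- as.integer(loop)
  if (kind == "hairpin") {
    if (stem < 2 || loop < 3)
      abort("hairpin fixtures need stem >= 2 and loop >= 3",
            class = "vfold_generation_error")
    s1 <- paste(rep(c("G", "C", "G"), length.out = stem), collapse = "")
    seqs <- paste0(s1, strrep("A", loop), .vf_revcomp(s1))
    n <- nchar(seqs)
    pairs <- cbind(1:stem, n:(n - stem + 1))
    list(seq = rna_sequence(seqs), structure = .vf_pairs_mat(pairs, n))
  } else if (kind == "bistable") {
    if (balanced) {
      # X a X' a X with X = GG: the ensemble is exactly {open chain, helix
      # A, helix B}; the two helices have identical stack and loop terms
      # (the stack table is symmetric under strand rotation), so their
      # ensemble weights are identical
      x <- "GG"
      seqs <- paste0(x, "AAAA", .vf_revcomp(x), "AAAA", x)
      n <- nchar(seqs)
      a <- nchar(x)
      helixA <- cbind(1:a, (2 * a + 4):(a + 5))
      helixB <- cbind((a + 5):(2 * a + 4), n:(n - a + 1))
      return(list(seq = rna_sequence(seqs),
                  structure = .vf_pairs_mat(helixA, n),
                  structure_alt = .vf_pairs_mat(helixB, n)))
    }
    # unequal-stability design (42 nt):
    #   w  Lw  w'  j  g  Lg  g'  t
    # dominant: weak all-AU hairpin w:w' (low melting) in tandem with the
    # stronger GC-core hairpin g:g' (high melting); alternative: w pairs
    # the 3' decoy t = revcomp(w) instead, at the cost of a large bulged
    # loop around g:g' -- mutually exclusive with w:w' because both need
    # strand w
    w <- "AAUAUAA"; lw <- "CCCA"; j <- "C"
    g <- "AGGCG"; lg <- "UUCGUC"
    seqs <- paste0(w, lw, .vf_revcomp(w), j, g, lg, .vf_revcomp(g),
                   .vf_revcomp(w))
    n <- nchar(seqs)
    helix_w <- cbind(1:7, 18:12)
    helix_g <- cbind(20:24, 35:31)
    helix_alt <- cbind(1:7, 42:36)
    list(seq = rna_sequence(seqs),
         structure = .vf_pairs_mat(rbind(helix_w, helix_g), n),
         structure_alt = .vf_pairs_mat(helix_alt, n))
  } else if (kind == "pseudoknot") {
    if (stem < 2 || loop < 1)
      abort("pseudoknot fixtures need stem >= 2 and loop >= 1",
            class = "vfold_generation_error")
    p1 <- paste(rep(c("G", "C"), length.out = stem), collapse = "")
    p2 <- paste(rep(c("C", "A", "G"), length.out = stem), collapse = "")
    seqs <- paste0(p1, strrep("A", loop), p2, strrep("A", junction),
                   .vf_revcomp(p1), strrep("A", loop), .vf_revcomp(p2))
    n <- nchar(seqs)
    s1 <- stem; l1 <- loop; j <- junction
    h1 <- cbind(1:s1, (s1 + l1 + s1 + j + s1):(s1 + l1 + s1 + j + 1))
    h2_start <- s1 + l1 + 1
    h2 <- cbind(h2_start:(h2_start + s1 - 1), n:(n - s1 + 1))
    list(seq = rna_sequence(seqs),
         structure = .vf_pairs_mat(rbind(h1, h2), n))
  } else {
    if (length < 1) abort("length must be >= 1", class = "vfold_generation_error")
    rng <- .vf_lcg(seed, length)
    seqs <- paste(c("A", "C", "G", "U")[rng %% 4L + 1L], collapse = "")
    list(seq = rna_sequence(seqs), structure = matrix(integer(0), 0, 2),
         seed = seed)
  }
}

# small deterministic linear congruential generator so fixtures do not
# disturb (or depend on) the global RNG state
.vf_lcg <- function(seed, n) {
  x <- as.integer(seed) %% 2147483647L
  if (x <= 0) x <- x + 2147483646L
  out <- integer(n)
  for (i in seq_len(n)) {
    x <- as.integer((as.double(x) * 16807) %% 2147483647)
    out[i] <- x
  }
  out
}
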