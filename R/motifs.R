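# Motif decomposition of a 2D structure and template-eligibility report
# (the front end of motif-template-based 3D assembly).

#' Decompose a secondary structure into motifs
#'
#' Splits a sequence + structure into the motif vocabulary used by
#' template-based 3D assembly: helices, hairpin loops, internal/bulge
#' loops, N-way junctions, pseudoknots, and open motifs (5'/3' single-strand
#' tails and single strands connecting helices that share no closing pair,
#' including zero-length tandem-helix links). Every nucleotide belongs to
#' at least one motif.
#'
#' @inheritParams validate_structure
#' @return tibble with columns `kind`, `strands` (list of `c(start, end)`
#'   intervals, 1-based inclusive; empty intervals have end < start),
#'   `closing_pairs` (list), `branch_count`.
#' @examples
#' decompose_structure("GGGAAAACCC", "(((....)))")
#' @export
decompose_structure <- function(seq, structure) {
  seq <- rna_sequence(seq, allow_long = TRUE)
  n <- attr(seq, "n")
  val <- validate_structure(seq, structure)
  hel <- val$helices
  rows <- list()
  add <- function(kind, strands, closing, branches = NA_integer_) {
    rows[[length(rows) + 1]] <<- tibble(
      kind = kind, strands = list(strands), closing_pairs = list(closing),
      branch_count = branches)
  }
  if (!nrow(hel)) {
    add("OPEN_MOTIF", list(c(1L, n)), list())
    return(dplyr::bind_rows(rows))
  }
  for (k in seq_len(nrow(hel))) {
    i <- hel$i[k]; j <- hel$j[k]; h <- hel$length[k]
    add("HELIX", list(c(i, i + h - 1L), c(j - h + 1L, j)),
        list(c(i, j), c(i + h - 1L, j - h + 1L)))
  }
  # pseudoknot clusters: transitive closure of crossing helices
  nh <- nrow(hel)
  crossing <- matrix(FALSE, nh, nh)
  if (nh > 1)
    for (a in 1:(nh - 1)) for (b in (a + 1):nh)
      crossing[a, b] <- crossing[b, a] <- .vf_cross(hel[a, ], hel[b, ])
  cluster <- integer(nh)
  cl <- 0L
  for (a in seq_len(nh)) {
    if (cluster[a] > 0 || !any(crossing[a, ])) next
    cl <- cl + 1L
    todo <- a
    while (length(todo)) {
      x <- todo[1]; todo <- todo[-1]
      if (cluster[x] == cl) next
      cluster[x] <- cl
      todo <- c(todo, which(crossing[x, ] & cluster == 0L))
    }
  }
  pk_members <- which(cluster > 0)

  # nesting: parent helix of each non-pk helix; pk clusters are treated as
  # single blocks occupying their full span
  pr <- .vf_partner(val$pairs, n)
  inner_p <- hel$i + hel$length - 1L
  inner_q <- hel$j - hel$length + 1L
  parent <- rep(0L, nh)
  for (a in seq_len(nh)) {
    for (b in seq_len(nh)) {
      if (a == b) next
      if (inner_p[b] < hel$i[a] && hel$j[a] < inner_q[b]) {
        if (parent[a] == 0L || hel$i[b] > hel$i[parent[a]]) parent[a] <- b
      }
    }
  }
  for (cl_id in unique(cluster[cluster > 0])) {
    members <- which(cluster == cl_id)
    span <- c(min(hel$i[members]), max(hel$j[members]))
    strands <- list()
    # loop strands between consecutive helix segments inside the cluster
    segs <- sort(unlist(lapply(members, function(k)
      c(hel$i[k], hel$i[k] + hel$length[k] - 1L,
        hel$j[k] - hel$length[k] + 1L, hel$j[k]))))
    seg_mat <- matrix(segs, ncol = 2, byrow = TRUE)
    if (nrow(seg_mat) > 1)
      for (r in 1:(nrow(seg_mat) - 1)) {
        a <- seg_mat[r, 2] + 1L; b <- seg_mat[r + 1, 1] - 1L
        strands[[length(strands) + 1]] <- c(a, b)
      }
    add("PSEUDOKNOT", strands,
        lapply(members, function(k) c(hel$i[k], hel$j[k])),
        branches = length(members))
  }

  # loops closed by the inner pair of each non-pk helix
  for (a in seq_len(nh)) {
    if (a %in% pk_members) next
    p <- inner_p[a]; q <- inner_q[a]
    kids <- which(parent == a & cluster == 0L)
    kid_cl <- unique(cluster[which(parent == a & cluster > 0L)])
    nb <- length(kids) + length(kid_cl)
    if (nb == 0) {
      add("HAIRPIN_LOOP", list(c(p + 1L, q - 1L)), list(c(p, q)))
    } else if (nb == 1 && length(kids) == 1) {
      b <- kids
      L1 <- hel$i[b] - p - 1L; L2 <- q - hel$j[b] - 1L
      kind <- if (L1 > 0 && L2 > 0) "INTERNAL_LOOP" else "BULGE"
      add(kind, list(c(p + 1L, hel$i[b] - 1L), c(hel$j[b] + 1L, q - 1L)),
          list(c(p, q), c(hel$i[b], hel$j[b])))
    } else {
      # junction: strands between consecutive branch blocks
      blocks <- lapply(kids, function(b) c(hel$i[b], hel$j[b]))
      for (cc in kid_cl) {
        mem <- which(cluster == cc)
        blocks[[length(blocks) + 1]] <- c(min(hel$i[mem]), max(hel$j[mem]))
      }
      blocks <- blocks[order(vapply(blocks, `[`, 0L, 1))]
      strands <- list()
      cur <- p
      for (blk in blocks) {
        strands[[length(strands) + 1]] <- c(cur + 1L, blk[1] - 1L)
        cur <- blk[2]
      }
      strands[[length(strands) + 1]] <- c(cur + 1L, q - 1L)
      add("NWAY_JUNCTION", strands, c(list(c(p, q)), blocks),
          branches = nb + 1L)
    }
  }

  # exterior: tails and single strands between top-level blocks
  top <- which(parent == 0L & cluster == 0L)
  top_blocks <- lapply(top, function(k) c(hel$i[k], hel$j[k]))
  for (cl_id in unique(cluster[cluster > 0])) {
    mem <- which(cluster == cl_id)
    blk <- c(min(hel$i[mem]), max(hel$j[mem]))
    enclosed <- any(vapply(seq_len(nh), function(b)
      !(b %in% mem) && inner_p[b] < blk[1] && blk[2] < inner_q[b], TRUE))
    if (!enclosed) top_blocks[[length(top_blocks) + 1]] <- blk
  }
  top_blocks <- top_blocks[order(vapply(top_blocks, `[`, 0L, 1))]
  if (length(top_blocks)) {
    first <- top_blocks[[1]][1]
    if (first > 1) add("OPEN_MOTIF", list(c(1L, first - 1L)), list())
    if (length(top_blocks) > 1)
      for (b in 1:(length(top_blocks) - 1)) {
        a <- top_blocks[[b]][2] + 1L
        z <- top_blocks[[b + 1]][1] - 1L
        add("OPEN_MOTIF", list(c(a, z)), list())  # may be empty (tandem)
      }
    last <- top_blocks[[length(top_blocks)]][2]
    if (last < n) add("OPEN_MOTIF", list(c(last + 1L, n)), list())
  }
  dplyr::bind_rows(rows)
}

#' Template eligibility of a motif decomposition
#'
#' Motif-template 3D assembly supports helices, hairpin loops,
#' internal/bulge loops, N-way junctions with 2 < N < 8, and (H-type)
#' pseudoknots. Open motifs — single-strand tails and helix-connecting
#' single strands without a shared closing pair — have no templates, and
#' junctions with 8 or more branches are unsupported.
#'
#' @param motifs a [decompose_structure()] result.
#' @return list with `motifs` (the input plus a `supported` column),
#'   `overall_supported`, and `recommendations` (character vector, e.g. to
#'   trim single-strand tails).
#' @export
motif_eligibility <- function(motifs) {
  supported <- vapply(seq_len(nrow(motifs)), function(k) {
    kind <- motifs$kind[k]
    if (kind == "OPEN_MOTIF") return(FALSE)
    if (kind == "NWAY_JUNCTION") {
      b <- motifs$branch_count[k]
      return(b >= 3 && b < 8)
    }
    TRUE
  }, TRUE)
  motifs$supported <- supported
  rec <- character(0)
  if (any(motifs$kind == "OPEN_MOTIF"))
    rec <- c(rec, "remove single-strand tails / open linkers before template-based 3D assembly")
  if (any(motifs$kind == "NWAY_JUNCTION" & !supported))
    rec <- c(rec, "junctions with 8 or more branches have no templates")
  list(motifs = motifs, overall_supported = all(supported),
       recommendations = rec)
}
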