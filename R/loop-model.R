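# Conformational loop entropies by virtual-bond lattice enumeration.
#
# The backbone is represented by two virtual bonds per nucleotide on the
# diamond (tetrahedral) lattice; closing a loop constrains the chain ends to
# a canonical two-vertex template (one lattice bond), and the loop entropy
# is ln(omega_closed / omega_open) in units of R.

# ---- geometry: map a loop specification onto a lattice walk ---------------

# zigzag helix path used as the spanning template for pseudoknot loops
.vf_helix_path <- function(h) {
  v <- matrix(0L, nrow = h + 1, ncol = 3)
  for (k in seq_len(h)) {
    v[k + 1, ] <- if (k %% 2 == 1) v[k, ] + c(1L, 1L, 1L) else v[k, ] - c(1L, -1L, -1L)
  }
  v
}

.vf_loop_geometry <- function(loop_type, sizes, mismatch_positions = NULL) {
  no_mm <- matrix(integer(0), 0, 4)
  mmrows <- function(aidx, bidx) cbind(aidx[1], aidx[2], bidx[1], bidx[2])
  if (loop_type == "hairpin") {
    L <- sizes[1]
    n <- 2L * L + 1L
    mm <- no_mm
    if (!is.null(mismatch_positions)) {
      for (r in seq_len(nrow(mismatch_positions))) {
        u <- mismatch_positions[r, 1]; v <- mismatch_positions[r, 2]
        if (u < 1 || v > L || u >= v)
          abort("mismatch positions must lie inside the loop",
                class = "vfold_invalid_loop")
        mm <- rbind(mm, mmrows(c(2L * u - 1L, 2L * u), c(2L * v - 1L, 2L * v)))
      }
    }
    list(nsteps = n, closed = TRUE, target = c(1L, 1L, 1L),
         blocked = matrix(integer(0), 0, 3), mm = mm, fixed = integer(0))
  } else if (loop_type == "internal") {
    L1 <- sizes[1]; L2 <- sizes[2]
    n <- 2L * (L1 + L2) + 3L
    mm <- no_mm
    if (!is.null(mismatch_positions)) {
      off <- 2L * L1 + 2L
      for (r in seq_len(nrow(mismatch_positions))) {
        u <- mismatch_positions[r, 1]; v <- mismatch_positions[r, 2]
        if (u < 1 || u > L1 || v < 1 || v > L2)
          abort("cross-strand mismatch positions must lie on the two strands",
                class = "vfold_invalid_loop")
        mm <- rbind(mm, mmrows(c(2L * u - 1L, 2L * u),
                               c(off + 2L * v - 1L, off + 2L * v)))
      }
    }
    # far helix = its terminal bond (step 2*L1+2 of the cycle); leaving its
    # direction free keeps 1-nt bulges formable (the smallest lattice cycle
    # is a hexagon, which cannot hold two antiparallel opposite bonds)
    list(nsteps = n, closed = TRUE, target = c(1L, 1L, 1L),
         blocked = matrix(integer(0), 0, 3), mm = mm,
         fixed = integer(0))
  } else if (loop_type == "pk") {
    L <- sizes[1]; h <- sizes[2]
    path <- .vf_helix_path(h)
    n <- 2L * L + 1L + (h %% 2 == 0)
    blocked <- if (h >= 2) path[2:h, , drop = FALSE] else matrix(integer(0), 0, 3)
    list(nsteps = as.integer(n), closed = TRUE, target = path[h + 1, ],
         blocked = blocked, mm = no_mm, fixed = integer(0))
  } else {
    abort(sprintf("unknown loop type '%s'", loop_type),
          class = "vfold_invalid_loop")
  }
}

.vf_saw_count <- function(geom, engine = c("production", "oracle"),
                          open = FALSE) {
  engine <- match.arg(engine)
  fn <- if (engine == "production") vf_saw_count_cpp else vf_saw_count_oracle_cpp
  if (open) {
    key <- paste0("open_", engine, "_", geom$nsteps)
    hit <- .vf_cache[[key]]
    if (!is.null(hit)) return(hit)
    v <- fn(geom$nsteps, FALSE, c(0L, 0L, 0L),
            matrix(integer(0), 0, 3), matrix(integer(0), 0, 4), integer(0))
    .vf_cache[[key]] <- v
    v
  } else {
    fn(geom$nsteps, TRUE, as.integer(geom$target),
       matrix(as.integer(geom$blocked), ncol = 3),
       matrix(as.integer(geom$mm), ncol = 4),
       as.integer(geom$fixed))
  }
}

#' Enumerate loop conformations on the virtual-bond lattice
#'
#' Exact counts of self-avoiding virtual-bond chains satisfying a loop's
#' closure constraint (`omega_closed`) and of unconstrained chains of the
#' same length (`omega_open`). Two bonds per nucleotide on the diamond
#' lattice; the closing helix fixes the chain ends one lattice bond apart;
#' internal loops additionally carry a direction-fixed far-helix bond and
#' pseudoknot loops span a blocked zigzag helix path.
#'
#' @param loop_type `"hairpin"`, `"internal"` (bulges are internal loops
#'   with one zero strand), or `"pk"`.
#' @param sizes hairpin: unpaired length; internal: the two strand lengths
#'   (either may be 0); pk: `c(loop_length, helix_length)`.
#' @param max_size_cap enumeration cap on the total unpaired length
#'   (exponential cost beyond it; use [extrapolate_entropy()] instead).
#' @param mismatch_positions optional 2-column matrix of intra-loop mismatch
#'   constraints (hairpin: both offsets in the loop; internal: strand-1 and
#'   strand-2 offsets), enforced as adjacency constraints.
#' @param engine `"production"` (pruned iterative enumerator) or `"oracle"`
#'   (independent brute-force recursion, used for cross-checks).
#' @return list with `loop_type`, `sizes`, `omega_closed`, `omega_open`.
#' @examples
#' enumerate_loop("hairpin", 3)
#' @export
enumerate_loop <- function(loop_type, sizes, max_size_cap = 8,
                           mismatch_positions = NULL,
                           engine = c("production", "oracle")) {
  engine <- match.arg(engine)
  sizes <- as.integer(sizes)
  total <- if (loop_type == "pk") sizes[1] else sum(sizes)
  if (total == 0 && loop_type != "pk") {
    # degenerate closure: the empty chain
    return(list(loop_type = loop_type, sizes = sizes,
                omega_closed = 1, omega_open = 1))
  }
  if (total > max_size_cap)
    abort(sprintf("loop size %d beyond the enumeration cap %d; use extrapolate_entropy()",
                  total, max_size_cap),
          class = "vfold_enumeration_cap")
  geom <- .vf_loop_geometry(loop_type, sizes, mismatch_positions)
  list(loop_type = loop_type, sizes = sizes,
       omega_closed = .vf_saw_count(geom, engine),
       omega_open = .vf_saw_count(geom, engine, open = TRUE))
}

#' Loop entropy from conformation counts
#'
#' dS_loop = ln(omega_closed / omega_open), in units of R (always <= 0).
#' A count of zero closed conformations signals an unformable loop and
#' yields `-Inf` (callers treat the loop as dG = +Inf).
#'
#' @param count a [enumerate_loop()] result.
#' @return dS_loop in units of R.
#' @export
loop_entropy <- function(count) {
  if (count$omega_open <= 0)
    abort("omega_open must be positive", class = "vfold_invalid_loop")
  if (count$omega_closed == 0) return(-Inf)
  log(count$omega_closed / count$omega_open)
}

#' Entropy of a mismatch-constrained loop
#'
#' Entropy of a loop whose geometry is additionally constrained by
#' intra-loop mismatches (each mismatch pins two loop nucleotides one
#' lattice bond apart). Never larger than the unconstrained loop entropy.
#' Beyond the enumeration cap the sum-of-sub-loops approximation is used
#' (the mismatch splits the loop; excluded volume between the sub-loops is
#' then neglected) with a one-time warning.
#'
#' @inheritParams enumerate_loop
#' @param entropies table used for the beyond-cap approximation.
#' @return dS_loop in units of R (`-Inf` if unformable).
#' @export
mismatch_loop_entropy <- function(loop_type, sizes, mismatch_positions,
                                  max_size_cap = 8,
                                  entropies = loop_entropy_table(),
                                  engine = "production") {
  sizes <- as.integer(sizes)
  if (is.null(mismatch_positions) || nrow(as.matrix(mismatch_positions)) == 0)
    return(loop_entropy(enumerate_loop(loop_type, sizes, max_size_cap,
                                       engine = engine)))
  mm <- as.matrix(mismatch_positions)
  total <- sum(sizes)
  if (total <= max_size_cap) {
    cnt <- enumerate_loop(loop_type, sizes, max_size_cap, mm, engine = engine)
    if (cnt$omega_closed == 0) return(-Inf)
    return(log(cnt$omega_closed / cnt$omega_open))
  }
  .vf_once("mm_subloop_approx", function()
    warn("mismatch-constrained loop beyond the enumeration cap: using the sum-of-independent-sub-loops approximation"))
  if (nrow(mm) != 1)
    abort("sub-loop approximation supports a single mismatch",
          class = "vfold_invalid_loop")
  u <- mm[1, 1]; v <- mm[1, 2]
  if (loop_type == "hairpin") {
    L <- sizes[1]
    extrapolate_entropy(entropies, "hairpin", v - u - 1)$entropy +
      .vf_s_int_any(entropies, u - 1, L - v)
  } else {
    L1 <- sizes[1]; L2 <- sizes[2]
    .vf_s_int_any(entropies, u - 1, L2 - v) +
      .vf_s_int_any(entropies, L1 - u, v - 1)
  }
}
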