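# Embedded nearest-neighbor thermodynamic tables (kcal/mol).
#
# turner04: Watson-Crick + wobble stacks and terminal mismatches of the
#   Turner-lab 2004 compilation (Xia et al. 1998 WC stacks, Mathews et al.
#   2004 revision), as redistributed in the standard parameter files.
# mfold23: the older mfold-era rules -- Freier et al. (1986) Watson-Crick
#   stacks with early wobble extensions (the wobble and enthalpy entries of
#   that era are approximate; only the WC stack table is an exact literature
#   transcription), terminal mismatches from the 1999 compilation.
#
# Matrix convention: STACK[p_out, p_in_rev] is the free energy of stacking
# inner pair (i+1, j-1) under outer pair (i, j), indexed by the outer pair
# (read 5'->3' on the top strand) and the *reversed* inner pair.  This makes
# the matrix symmetric, which encodes the strand-rotation symmetry of the
# nearest-neighbor model.
# Mismatch arrays: MM[pair, x, y] for closing pair (i,j) with first unpaired
# nucleotides x = seq[i+1], y = seq[j-1].

.vf_pairs <- c("CG", "GC", "GU", "UG", "AU", "UA")
.vf_bases <- c("A", "C", "G", "U")

.vf_stack_dG37 <- list(
  turner04 = matrix(c(-2.40, -3.30, -2.10, -1.40, -2.10, -2.10, -3.30, -3.40, -2.50, -1.50, -2.20, -2.40, -2.10, -2.50, 1.30, -0.50, -1.40, -1.30, -1.40, -1.50, -0.50, 0.30, -0.60, -1.00, -2.10, -2.20, -1.40, -0.60, -1.10, -0.90, -2.10, -2.40, -1.30, -1.00, -0.90, -1.30), nrow = 6, byrow = TRUE, dimnames = list(.vf_pairs, .vf_pairs)),
  mfold23 = matrix(c(-2.00, -2.90, -1.50, -1.50, -1.70, -1.80, -2.90, -3.40, -1.90, -1.30, -2.10, -2.30, -1.50, -1.90, 0.50, 0.50, -0.70, -0.70, -1.50, -1.30, 0.50, 0.50, -0.50, -0.50, -1.70, -2.10, -0.70, -0.50, -0.90, -0.90, -1.80, -2.30, -0.70, -0.50, -0.90, -1.10), nrow = 6, byrow = TRUE, dimnames = list(.vf_pairs, .vf_pairs))
)

.vf_stack_dH <- list(
  turner04 = matrix(c(-10.60, -13.40, -12.10, -5.60, -10.50, -10.40, -13.40, -14.90, -12.60, -8.30, -11.40, -12.40, -12.10, -12.60, -14.60, -13.50, -8.80, -12.80, -5.60, -8.30, -13.50, -9.30, -3.20, -7.00, -10.50, -11.40, -8.80, -3.20, -9.40, -6.80, -10.40, -12.40, -12.80, -7.00, -6.80, -7.70), nrow = 6, byrow = TRUE, dimnames = list(.vf_pairs, .vf_pairs)),
  mfold23 = matrix(c(-11.90, -12.20, -9.30, -9.30, -7.60, -10.50, -12.20, -14.20, -10.80, -8.60, -10.20, -13.30, -9.30, -10.80, -2.00, -2.00, -5.00, -5.00, -9.30, -8.60, -2.00, -2.00, -4.10, -4.10, -7.60, -10.20, -5.00, -4.10, -5.70, -6.60, -10.50, -13.30, -5.00, -4.10, -6.60, -8.10), nrow = 6, byrow = TRUE, dimnames = list(.vf_pairs, .vf_pairs))
)

.vf_mm_hairpin_dG37 <- list(
  turner04 = array(c(-1.50, -1.10, 0.20, -0.50, -0.30, -0.50, -1.00, -1.10, -0.10, -0.20, -0.10, -0.20, -2.30, -2.50, -1.00, -0.90, -1.20, -1.50, -1.00, -1.10, -0.10, -0.20, -0.10, -0.20, -1.50, -1.50, -0.50, -0.30, -0.50, -0.30, -1.10, -0.70, -0.20, -0.10, -0.20, -0.10, -1.50, -1.50, -0.50, -0.30, -0.50, -0.30, -1.40, -1.00, -0.30, -0.10, -0.30, -0.10, -1.40, -1.30, -0.30, -0.60, -0.30, -0.50, -1.00, -1.10, -0.10, -0.20, -0.10, -0.20, -2.40, -2.20, -1.10, -1.10, -1.10, -1.50, -1.00, -1.10, -0.10, -0.20, -0.10, -0.20, -1.50, -1.50, -0.50, -0.30, -0.50, -0.30, -0.80, -0.50, -0.20, 0.00, -0.20, 0.00, -1.50, -1.50, -0.50, -0.30, -0.50, -0.30, -2.10, -1.60, -1.00, -0.90, -1.20, -0.90), dim = c(6, 4, 4), dimnames = list(.vf_pairs, .vf_bases, .vf_bases)),
  mfold23 = array(c(-1.50, -1.10, 0.20, -0.50, -0.30, -0.50, -1.00, -1.10, -0.10, -0.20, -0.10, -0.20, -2.20, -2.40, -0.90, -0.80, -1.10, -1.40, -1.70, -1.90, -0.30, -0.60, -0.30, -0.30, -1.50, -1.50, -0.50, -0.30, -0.50, -0.30, -0.90, -0.70, -0.20, -0.10, -0.20, -0.10, -2.00, -2.90, -1.10, -1.20, -1.20, -1.20, -1.40, -1.00, -0.30, -0.10, -0.30, -0.10, -1.40, -1.30, -0.30, -0.60, -0.30, -0.60, -2.90, -2.40, -1.50, -1.70, -1.50, -1.20, -1.60, -1.40, -0.30, -0.30, -0.20, -0.70, -1.80, -2.20, -0.40, -0.60, -0.60, -0.50, -1.80, -2.10, -0.30, -0.50, -0.30, -0.50, -0.80, -0.50, -0.20, 0.00, -0.20, 0.00, -1.10, -1.20, 0.00, -0.70, 0.20, -0.20, -2.00, -1.50, -1.10, -0.80, -1.10, -0.80), dim = c(6, 4, 4), dimnames = list(.vf_pairs, .vf_bases, .vf_bases))
)

.vf_mm_hairpin_dH <- list(
  turner04 = array(c(-9.10, -5.20, 0.30, -1.10, -0.20, -0.30, -5.70, -7.20, 1.40, -0.60, 1.40, -0.60, -14.00, -12.90, -2.70, 1.00, -5.20, -5.90, -5.70, -7.20, 1.40, -0.60, 1.40, -0.60, -5.60, -4.00, 5.70, -2.60, 5.70, -2.60, -3.40, 0.50, 9.70, -1.40, 9.70, -1.40, 5.60, -4.00, 5.70, -2.60, 5.70, -2.60, -5.30, -0.30, 8.30, 2.30, 8.30, 2.30, -5.60, -5.60, 0.20, -5.20, 0.20, -5.20, -5.70, -7.20, 1.40, -0.60, 1.40, -0.60, -9.20, -6.20, 0.20, 2.20, 0.20, -5.20, -5.70, -7.20, 1.40, -0.60, 1.40, -0.60, -5.60, -4.00, 5.70, -2.60, 5.70, -2.60, -2.70, -4.20, 3.40, 1.90, 3.40, 1.90, -5.60, -4.00, 5.70, -2.60, 5.70, -2.60, -14.40, -10.80, -0.50, -0.70, -3.80, -0.70), dim = c(6, 4, 4), dimnames = list(.vf_pairs, .vf_bases, .vf_bases)),
  mfold23 = array(c(-10.30, -5.20, -4.30, -7.20, -4.30, -4.00, -5.20, -7.20, -2.60, -4.80, -2.60, -4.30, -9.40, -7.10, -3.40, -6.60, -3.40, -3.80, -8.10, -5.00, -3.30, -5.50, -3.30, -2.80, -9.50, -8.80, -6.00, -7.90, -6.00, -6.30, -4.50, -3.10, -2.40, -4.80, -2.40, -5.10, -9.40, -7.40, -6.90, -8.10, -6.90, -6.80, -7.40, -5.00, -3.30, -4.40, -3.30, -1.40, -10.30, -5.60, -6.00, -9.60, -6.00, -8.90, -5.20, -3.10, -2.40, -3.60, -2.40, -2.00, -9.40, -6.20, -6.90, -9.20, -6.90, -8.90, -8.10, -5.00, -3.30, -5.50, -3.30, -2.80, -10.30, -8.80, -6.00, -8.10, -6.00, -5.90, -6.70, -3.90, -2.40, -4.80, -2.40, -1.80, -9.40, -7.40, -6.90, -8.10, -6.90, -6.80, -8.60, -5.70, -3.30, -3.60, -3.30, -1.40), dim = c(6, 4, 4), dimnames = list(.vf_pairs, .vf_bases, .vf_bases))
)

.vf_mm_interior_dG37 <- list(
  turner04 = array(c(0.00, 0.00, 0.70, 0.70, 0.70, 0.70, 0.00, 0.00, 0.70, 0.70, 0.70, 0.70, -1.00, -1.00, -0.30, -0.30, -0.30, -0.30, 0.00, 0.00, 0.70, 0.70, 0.70, 0.70, 0.00, 0.00, 0.70, 0.70, 0.70, 0.70, 0.00, 0.00, 0.70, 0.70, 0.70, 0.70, 0.00, 0.00, 0.70, 0.70, 0.70, 0.70, 0.00, 0.00, 0.70, 0.70, 0.70, 0.70, -0.80, -0.80, -0.10, -0.10, -0.10, -0.10, 0.00, 0.00, 0.70, 0.70, 0.70, 0.70, -1.00, -1.00, -0.30, -0.30, -0.30, -0.30, 0.00, 0.00, 0.70, 0.70, 0.70, 0.70, 0.00, 0.00, 0.70, 0.70, 0.70, 0.70, 0.00, 0.00, 0.70, 0.70, 0.70, 0.70, 0.00, 0.00, 0.70, 0.70, 0.70, 0.70, -0.60, -0.60, 0.10, 0.10, 0.10, 0.10), dim = c(6, 4, 4), dimnames = list(.vf_pairs, .vf_bases, .vf_bases)),
  mfold23 = array(c(0.00, 0.00, 0.70, 0.70, 0.70, 0.70, 0.00, 0.00, 0.70, 0.70, 0.70, 0.70, -1.10, -1.10, -0.40, -0.40, -0.40, -0.40, 0.00, 0.00, 0.70, 0.70, 0.70, 0.70, 0.00, 0.00, 0.70, 0.70, 0.70, 0.70, 0.00, 0.00, 0.70, 0.70, 0.70, 0.70, 0.00, 0.00, 0.70, 0.70, 0.70, 0.70, 0.00, 0.00, 0.70, 0.70, 0.70, 0.70, -1.10, -1.10, -0.40, -0.40, -0.40, -0.40, 0.00, 0.00, 0.70, 0.70, 0.70, 0.70, 0.00, 0.00, 0.70, 0.70, 0.70, 0.70, 0.00, 0.00, 0.70, 0.70, 0.70, 0.70, 0.00, 0.00, 0.70, 0.70, 0.70, 0.70, 0.00, 0.00, 0.70, 0.70, 0.70, 0.70, 0.00, 0.00, 0.70, 0.70, 0.70, 0.70, -0.70, -0.70, 0.00, 0.00, 0.00, 0.00), dim = c(6, 4, 4), dimnames = list(.vf_pairs, .vf_bases, .vf_bases))
)

.vf_mm_interior_dH <- list(
  turner04 = array(c(0.00, 0.00, 5.00, 5.00, 5.00, 5.00, 0.00, 0.00, 5.00, 5.00, 5.00, 5.00, -7.60, -7.60, -2.60, -2.60, -2.60, -2.60, 0.00, 0.00, 5.00, 5.00, 5.00, 5.00, 0.00, 0.00, 5.00, 5.00, 5.00, 5.00, 0.00, 0.00, 5.00, 5.00, 5.00, 5.00, 0.00, 0.00, 5.00, 5.00, 5.00, 5.00, 0.00, 0.00, 5.00, 5.00, 5.00, 5.00, -3.40, -3.40, 1.70, 1.70, 1.70, 1.70, 0.00, 0.00, 5.00, 5.00, 5.00, 5.00, 2.80, 2.80, 7.90, 7.90, 7.90, 7.90, 0.00, 0.00, 5.00, 5.00, 5.00, 5.00, 0.00, 0.00, 5.00, 5.00, 5.00, 5.00, 0.00, 0.00, 5.00, 5.00, 5.00, 5.00, 0.00, 0.00, 5.00, 5.00, 5.00, 5.00, -5.80, -5.80, -0.80, -0.80, -0.80, -0.80), dim = c(6, 4, 4), dimnames = list(.vf_pairs, .vf_bases, .vf_bases)),
  mfold23 = array(c(-10.30, -5.20, -4.30, -7.20, -4.30, -4.00, -5.20, -7.20, -2.60, -4.80, -2.60, -4.30, -9.40, -7.10, -3.40, -6.60, -3.40, -3.80, -8.10, -5.00, -3.30, -5.50, -3.30, -2.80, -9.50, -8.80, -6.00, -7.90, -6.00, -6.30, -4.50, -3.10, -2.40, -4.80, -2.40, -5.10, -9.40, -7.40, -6.90, -8.10, -6.90, -6.80, -7.40, -5.00, -3.30, -4.40, -3.30, -1.40, -10.30, -5.60, -6.00, -9.60, -6.00, -8.90, -5.20, -3.10, -2.40, -3.60, -2.40, -2.00, -9.40, -6.20, -6.90, -9.20, -6.90, -8.90, -8.10, -5.00, -3.30, -5.50, -3.30, -2.80, -10.30, -8.80, -6.00, -8.10, -6.00, -5.90, -6.70, -3.90, -2.40, -4.80, -2.40, -1.80, -9.40, -7.40, -6.90, -8.10, -6.90, -6.80, -8.60, -5.70, -3.30, -3.60, -3.30, -1.40), dim = c(6, 4, 4), dimnames = list(.vf_pairs, .vf_bases, .vf_bases))
)
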