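---
title: "Statistical-mechanical RNA folding with lattice-enumerated loop entropies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical-mechanical RNA folding with lattice-enumerated loop entropies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vfold)
```

## The model

`vfold` predicts RNA secondary structure and folding thermodynamics for a
single sequence by computing the equilibrium partition function

$$Q \;=\; \sum_{s \in \mathcal{S}} e^{-\Delta G(s)/RT},$$

relative to the open chain ($\Delta G = 0$, weight 1), over an ensemble
$\mathcal{S}$ of helix-based secondary structures. The free energy of a
structure is assembled from two ingredients:

* **stack enthalpies and entropies** for adjacent base pairs, taken from
  published nearest-neighbor compilations, evaluated at temperature $T$ as
  $\Delta G = \Delta H - T\Delta S$ (with $\Delta H$, $\Delta S$ treated as
  temperature independent);
* **conformational loop entropies** $\Delta S_{\mathrm{loop}}$ computed by
  exhaustive enumeration of coarse-grained virtual-bond chains on a
  diamond lattice: a loop of a given type and size contributes
  $\ln(\Omega_{\mathrm{closed}}/\Omega_{\mathrm{open}})$ in units of the
  gas constant, the log-ratio of self-avoiding chain conformations that
  satisfy the loop's closure constraint to unconstrained chains of the
  same length.

Base-pair probabilities $P_{ij}$ are equilibrium averages over the same
ensemble; the most probable ("dominant") structure is read off as the set
of pairs with $P_{ij} > 0.5$, and alternative structures are groups of
mutually compatible helices forming at the same probability level.
Temperature scans of $\ln Q$ yield the excess heat capacity

$$C(T) \;=\; \frac{\partial}{\partial T}\!\left[RT_K^2\,
  \frac{\partial \ln Q}{\partial T}\right],$$

whose peaks mark melting transitions.

## The structure ensemble

The ensemble is defined precisely, because an exhaustive enumerator
(`exhaustive_fold()`) must generate exactly the same set of structures that
the dynamic program (`fold_rna()`) sums over:

* allowed pairs are AU, UA, CG, GC, GU, UG;
* every pair belongs to a helix of at least 2 consecutive pairs (a purely
  stack-based energy assigns no stability to a lone pair);
* hairpin loops span at least 3 unpaired nucleotides;
* internal/bulge loops are capped at 30 unpaired nucleotides total (the
  standard practice in nearest-neighbor folding engines);
* multiloops (N-way junctions) of any size are allowed;
* the exterior strand carries no penalty;
* in the pseudoknot modes, additionally every *bare H-type pseudoknot*:
  two crossing helices with all three connecting loops unpaired and all
  other nucleotides unpaired. `"junction1"` restricts the inter-helix
  junction to at most 1 nt; `"any"` allows any junction length.

The restriction of pseudoknotted structures to bare two-helix geometries
is a deliberate simplification: the pseudoknotted part of the partition
function is computed by explicit enumeration over H-type two-helix
geometries, so structures combining a pseudoknot with additional nested
helices are outside the ensemble. Consequently pseudoknot probabilities
are conservative for sequences where a pseudoknot would coexist with
stable flanking hairpins. Recursive and multi-pseudoknots are excluded
altogether. The three modes nest as ensembles, so
$Q_{\mathrm{any}} \ge Q_{\mathrm{junction1}} \ge Q_{\mathrm{none}}$ holds
on every input.

The nested part of $Q$ and the $P_{ij}$ matrix are computed by an
inside–outside dynamic program over this grammar. Because the multiloop
entropy depends on the *total* unpaired length of the junction (see
below), multiloop states carry that length as an explicit dimension; the
computational cost is $O(N^4)$ time and $O(N^3)$ memory, about two
seconds at the 140-nt sequence limit. The exhaustive oracle enumerates
compatible sets of helix placements directly and scores each structure
with the independent, R-level energy evaluator
(`structure_free_energy()`); the test suite requires the two routes to
agree to a relative $10^{-9}$ on $Q$ and every $P_{ij}$ across random
sequences, all three pseudoknot modes, and both parameter dialects.

## Energy parameters

Two selectable stack-parameter dialects are embedded as code constants:

* **turner04** — the Turner-lab 2004 compilation (1998 Watson–Crick
  stacks, 2004 wobble and terminal-mismatch revision), transcribed from
  the standard redistributed parameter files;
* **mfold23** — the older mfold-era rules: the 1986 Watson–Crick stack
  table (exact literature transcription) with wobble extensions of that
  era. The wobble and wobble-enthalpy entries of this dialect are
  representative values, not an exact transcription — the original mfold
  2.x energy files are not redistributable — and are documented as such;
  terminal mismatches are taken from the 1999 compilation.

Tables store $(\Delta H, \Delta G_{37})$ pairs; $\Delta S$ is derived as
$(\Delta H - \Delta G_{37})/310.15$, which is how the published
compilations define it, so the 37 °C reconstruction is exact by
construction. The gas constant is $R = 1.987\times10^{-3}$ kcal/(mol·K)
and temperatures convert with $+273.15$ exactly. Dangling ends and
coaxial stacking are not modeled. Mismatch stacks without a published
finite value contribute 0 kcal/mol with a one-time warning.

## Loop entropies on the diamond lattice

The backbone is represented by **two virtual bonds per nucleotide** on the
diamond (tetrahedral, coordination 4) lattice. A hairpin loop of $L$
nucleotides is a self-avoiding walk of $2L+1$ steps whose ends are pinned
one lattice bond apart (the closing helix's terminal bond). An internal
loop with strand lengths $(L_1, L_2)$ is a single closed cycle through
both helix terminal bonds. A pseudoknot-spanning loop of length $L$
bridging a helix of $h$ base pairs runs from one end of a zigzag helix
path to the other while avoiding the helix vertices.

Two numerical choices deserve comment:

* **The far-helix bond is orientation-free.** An earlier closure template
  fixed the far bond anti-parallel to the closing bond; on the diamond
  lattice the smallest cycle is a hexagon, whose opposite bonds cannot
  both satisfy that constraint, making 1-nt bulges (and with them 1-nt
  pseudoknot junctions) unformable. With the free orientation the
  1-nt bulge is a hexagonal cycle and all loop sizes are formable. A
  consequence is that internal-loop entropies depend only on the total
  unpaired length $L_1 + L_2$, not on the split.
* **The enumeration cap is 8 unpaired nt total** (configurable). With two
  bonds per nucleotide this is already a 17–19-step self-avoiding-walk
  enumeration ($\sim 10^9$ chains); each additional nucleotide multiplies
  the cost by roughly $2.9^2$, so a larger default cap is not a
  desk-scale computation. Beyond the cap, entropies follow a
  Jacobson–Stockmayer-form fit $\Delta S(L) = a - c\ln L$ to the
  enumerated sizes (hairpins: the non-increasing tail from the
  entropy-maximal size; internal loops: the total length; pseudoknot
  loops: per spanned helix length). The fitted hairpin exponent is
  $c \approx 1.77$, in the expected range for closed lattice chains.

The shipped table (`inst/extdata/loop_entropies.tsv`) was generated by the
package's own enumerator (`build_entropy_tables()`), is bit-reproducible,
and records counts, entropies and provenance (`enumerated` /
`extrapolated`) per entry. The test suite regenerates part of it and
compares every enumerated count against a second, independently written
brute-force enumerator.

Multiloops are scored with the extrapolated hairpin form applied to the
total unpaired length of the junction, clamped to be non-positive, plus a
penalty of 0.1 kcal/mol per branch. This is an acknowledged
approximation: the junction-closure geometry is not enumerated.
Similarly, the pseudoknot junction strand is scored with the bulge-type
entropy of its length. Where a pseudoknot spans a helix longer than the
tabulated 6 bp, the 6-bp column is used with a one-time warning.

## Intra-loop mismatches

Every hairpin and internal loop contributes a Boltzmann sum over its
sequence-admissible single-mismatch variants, which makes the loop free
energy sequence dependent, not just size dependent. A mismatch is any
non-canonical base combination except A·A (the one combination without a
plausible pairing geometry; this also keeps poly-A loops variant-free).
Placements:

* hairpin loops: any two loop nucleotides at least 3 nt apart (the
  mismatch closes a sub-loop subject to the same steric minimum);
* internal loops: one nucleotide from each strand (an in-strand mismatch
  would create a branched, junction-like geometry outside the single-loop
  closure templates and is treated as geometrically inadmissible).

The constrained entropy is enumerated exactly (the mismatch is an
adjacency constraint on the lattice walk) up to the cap; beyond it, the
mismatch splits the loop into two sub-loops whose entropies are summed —
this neglects the excluded volume between the sub-loops and is flagged
once per session. A mismatch adjacent to a closing pair additionally
contributes the dialect's terminal-mismatch stack. Mismatch variants are
enumerated identically in the dynamic program and in the oracle, so the
ensembles match member for member.

## Melting curves

`partition_over_temperature()` re-evaluates $\ln Q$ on a uniform grid
(default 0–100 °C in 0.5 °C steps, 201 points). `heat_capacity()` applies
central differences, $C_i = R(T_K^2 u'' + 2T_K u')$ with $u = \ln Q$,
defined on the grid minus one point per boundary; no boundary
extrapolation is attempted. $C$ is the excess heat capacity relative to
the open chain, per mole of strand, with no baseline ($\Delta C_p = 0$)
correction. `find_melting_peaks()` reports strict local maxima with
prominence at least 5 % of the maximum. On a synthetic two-state system
with $\Delta H = -40$ kcal/mol and $\Delta S = -0.12$ kcal/(mol·K), the
detected peak sits within one grid step of the closed-form
$T_m = \Delta H / \Delta S$ and the transition integral recovers
$|\Delta H|$ within 5 %.

## Fixtures: what they emulate and what they do not

The generator (`make_fixture()`) produces the study systems:

* `hairpin` — a GC-rich stem-loop with a known structure;
* `bistable` (default, 42 nt) — a sequence with two mutually exclusive
  pairings for its 5′ strand. The design was chosen once, with the
  engine, to realize the intended physics: the dominant structure
  (probability ≈ 0.87 at 37 °C) is a weak all-AU hairpin in tandem with a
  stronger GC-core hairpin, the single alternative (≈ 0.14) re-pairs the
  AU strand with a 3′ decoy at the cost of a large bulged loop, and the
  melting curve shows exactly two peaks — the AU helix near 64 °C, the
  GC-core helix near 95 °C — each within a few degrees of the helix's
  independent two-state $\Delta H/\Delta S$ temperature. Getting two
  *resolved* peaks requires the strong helix to carry enough enthalpy
  (A·U flanks around the GC core) while a larger loop keeps its melting
  temperature inside the grid;
* `bistable, balanced` (14 nt) — an ensemble of exactly {open chain, two
  2-bp GC helices with identical stack and loop terms}; the two helix
  probabilities are *exactly* equal, which the tests use as a symmetry
  check. Larger balanced designs are not exactly symmetric in this
  model: published terminal-mismatch tables are orientation dependent and
  nearest-neighbor stacks are not invariant under sequence reversal, so
  shifted sub-registers break mirror symmetry at the $10^{-3}$ level;
* `pseudoknot` — a toy H-type geometry with two crossing stems;
* `random` — seeded uniform sequences from a self-contained linear
  congruential generator (fixtures neither disturb nor depend on R's
  global RNG).

Passing tests on these fixtures demonstrate internal consistency of the
model, its thermodynamics, and its implementation — not agreement with
experimental structures of natural RNAs, which have non-canonical
tertiary interactions, modified nucleotides and ionic-strength
dependences outside this model.

## Numerical choices and degenerate inputs

* No randomness anywhere in the engine; iteration order is fixed by
  index, so all results are bit-reproducible.
* Partition-function weights are accumulated in double precision without
  rescaling; within the 140-nt limit and the −10…150 °C temperature
  range the weights stay far below overflow.
* Unformable loops (zero closed conformations) carry $-\infty$ entropy
  and simply drop out of the ensemble; unpairable sequences return
  $Q = 1$ with an all-zero probability matrix.
* The dominant-structure threshold is strictly $P_{ij} > 0.5$; ties at
  exactly 0.5 are excluded. The alternative-structure level tolerance
  defaults to 0.15, and helices below probability 0.05 are not grouped
  into alternatives.
* Sequence lengths beyond 140 nt require an explicit override; the
  `"any"` pseudoknot mode is limited to 60 nt by default (the two-helix
  geometry enumeration grows steeply with junction freedom).

## Problem sizes used by the checks

The test suite compares the engine against exhaustive enumeration on 200+
random sequences of 8–18 nt (the scale at which explicit enumeration is
exact and fast), validates lattice counts for all loop types up to 8
unpaired nt against the independent enumerator, and exercises the
bistable fixture at 42 nt over the full 201-point melting grid. The
acceptance script reruns the same computations from scratch.

## Known limitations

* Pseudoknots are bare H-type two-helix structures; no coexisting nested
  helices, no recursive pseudoknots, no kissing-hairpin motifs.
* Multiloop and pseudoknot-junction entropies are approximations (see
  above), not enumerated closures.
* No dangling ends, coaxial stacking, ion dependence, or heat-capacity
  ($\Delta C_p$) corrections; enthalpies and entropies are temperature
  independent.
* The `mfold23` wobble sub-table is representative rather than an exact
  historical transcription.
* The motif decomposer does not infer coaxially stacked tandem helices (a
  3D property); zero-length junction strands are kept as junctions of
  that size, and open motifs are a conservative catch-all for tails and
  unlinked tandem helices.
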