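Package: vfold
Title: RNA Secondary Structure, Pseudoknot and Melting-Curve Prediction
    with Lattice-Enumerated Loop Entropies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical-mechanical prediction of RNA secondary structure
    and folding thermodynamics for single sequences. Computes the
    equilibrium partition function over helix-based secondary structures
    (optionally including H-type pseudoknots), base-pair and helix
    probabilities, and dominant/alternative structures, using
    nearest-neighbor stack energies from two selectable parameter dialects
    together with conformational loop entropies obtained by exhaustive
    enumeration of coarse-grained virtual-bond chains on a diamond lattice.
    Sequence-dependent intra-loop mismatches are enumerated as distinct
    ensemble members. Temperature scans of the partition function yield
    heat-capacity melting curves with transition-peak detection, and a
    motif decomposer classifies a given structure into helices, loops,
    junctions and pseudoknots and reports template eligibility for
    motif-based 3D assembly.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
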