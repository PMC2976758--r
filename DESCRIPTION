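Package: famforge
Title: Iterative Profile HMM Refinement for Protein Superfamily Subdivision
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Carves large, divergent protein superfamilies into stable family
    models by iterative profile hidden Markov model (HMM) refinement. Starting
    from greedy identity clusters of extracted two-domain regions, each family
    model is rebuilt and re-searched against the database until its seed set
    stabilises, guarded by a divergence cap with progressive curation of the
    initial seeds. Leave-one-out (jackknife) inclusion control with three
    spuriousness strategies classifies models as stable and reliable, seed-set
    overlaps between models are resolved by subset set-aside, threshold
    raising or merging, and per-model gathering/trusted/noise score cutoffs
    are recorded for classification of new sequences. Includes a minimal
    glocal (global-in-model, local-in-sequence) Viterbi profile-HMM engine, a
    synthetic two-domain superfamily generator with planted ground truth,
    family characterisation statistics (column conservation, conserved net
    charge, domain conservation ratios, kingdom distributions), and readers
    and writers for FASTA, aligned FASTA, Stockholm and a documented ASCII
    profile model format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
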