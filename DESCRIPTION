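Package: primeropt
Title: Multi-Objective Optimization of 16S rRNA Primer-Set-Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and assessment of broad-spectrum PCR primers for the
    bacterial 16S ribosomal RNA gene. Candidate solutions are
    primer-set-pairs (a set of forward plus a set of reverse non-degenerate
    primers, the natural expansion of a degenerate primer pair) scored on
    three competing objectives against a reference collection of 16S
    sequences: a ten-term fuzzy efficiency score (melting temperature, GC
    content, 3'-end stability, homopolymers, self- and cross-dimers,
    hairpins, melting-temperature range and amplicon-length spread),
    coverage under a seed-anchored mismatch matching rule, and
    matching-bias (the coefficient of variation of the number of primer
    combinations matching each covered sequence). The Pareto front of the
    three objectives is approximated by restart-driven best-improvement
    local search over random scalarizations with weights drawn uniformly
    from the unit simplex. Includes a synthetic 16S-like reference-set
    generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
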