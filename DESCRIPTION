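Package: seroprofiler
Title: Serum Autoantibody Profiling on Protein Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of high-throughput serum autoantibody
    screens on full-length protein microarrays (GenePix-style spot data).
    Implements spot-level preprocessing (background subtraction, replicate
    CV filtering, negative-control filtration, polyspecific-sample
    detection, cyclic loess normalization, empirical-Bayes batch
    correction), covariate-adjusted moderated differential testing,
    correlation of antibody levels with clinical scores, cross-reactivity
    adjudication by global sequence alignment, and gene-set
    overrepresentation. Includes a truth-known synthetic study generator
    for validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    sva,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
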