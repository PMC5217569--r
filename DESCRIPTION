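Package: bsartifact
Title: Simulation and Diagnosis of Base-Calling Artifacts in Bisulfite Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates whole-genome bisulfite sequencing (WGBS) libraries with
    PBAT and MethylC-seq read chemistry and controllable base-caller artifacts
    (minority-base G undercall with quality penalty, density-dependent R2
    quality collapse), and quantifies their effect on methylation estimates:
    a desk-scale three-letter bisulfite aligner, per-cytosine methylation
    extraction, depth-weighted CpG and non-CpG methylation levels stratified
    by mate, per-cycle base composition and quality-score diagnostics
    including the steep-drop statistic at G, windowed methylation statistics
    with run-vs-run regression and CpG-density classes, spike-in mixture
    calibration, and sliding-window calling of partially methylated domains.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    withr,
    Biostrings,
    Rcpp,
    stats,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
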