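Package: submir
Title: Time-Course Small RNA Analysis of Submergence-Responsive microRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for time-course small RNA sequencing studies
    of plants under contrasting hydrological regimes. Cleans and collapses
    small RNA reads, annotates non-coding RNA classes, identifies known
    microRNAs against a mature reference with bounded mismatches and gaps,
    calls novel microRNAs from hairpin structure criteria on a transcriptome,
    normalises expression to reads per million, classifies per-library
    occupancy and submergence-responsive expression dynamics across an
    eleven-library wet/dry time course, scores microRNA target sites with
    plant complementarity penalties, pairs microRNAs with inversely
    co-expressed targets, and summarises qPCR and 5' RACE validation data.
    Ships a synthetic data generator with planted ground truth for
    end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
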