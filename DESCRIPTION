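Package: popflow
Title: Gene-Flow, Selection and Demographic Inference from Population Genomic Windows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Windowed population-genomic analyses for detecting gene flow and
    selection among diverged populations, built around a wild / domesticated /
    sister-lineage study design with an outgroup. Provides sliding-window
    nucleotide diversity, Tajima's D, dxy and FST; the ABBA/BABA D statistic
    and the f3 three-population test with weighted block-jackknife standard
    errors; an fd window scan with introgressed-region calling and dxy/FST
    verification; a joint theta-pi-ratio / Z(FST) selective-sweep scan with
    gene annotation; an event-driven multi-locus coalescent simulator for
    three-population-plus-outgroup demographies; and approximate Bayesian
    computation model choice (rejection and GLM) over competing gene-flow
    models after PLS-DA reduction of summary statistics. A synthetic-data
    generator plants known introgressed tracts and sweeps so every stage of
    the pipeline can be validated against truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    GenomicRanges,
    jsonlite,
    mixOmics,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
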