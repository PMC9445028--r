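Package: qtronset
Title: Quasi-Tandem-Repeat Genotyping and Ascertainment-Corrected Onset
    Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calls perfect and imperfect (quasi) tandem hexanucleotide
    repeats from short-read sequencing data localized to a declared locus,
    using a match-matrix realignment algorithm with a length-discounted
    gap penalty, and tests association of repeat length with residual age
    at motor onset in Huntington's disease cohorts. Includes a "regression
    with selection" maximum-likelihood framework that corrects effect-size
    estimates for extreme-phenotype ascertainment, a minimum-distance
    fitter for the sigmoid selection function, nested-model comparison of
    repeat statistics, and simulators for reads over repeat haplotypes and
    for selected cohorts.
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
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    Rsamtools,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
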