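Package: nrlkit
Title: Nucleosome Repeat Length Estimation and Nucleosome Repositioning
    Analysis from MNase-Derived Fragment Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing nucleosome organisation from paired-end
    MNase-seq, MNase-assisted ChIP-seq or cell-free DNA fragment maps
    supplied as BED intervals. Implements fragment-size fractionation,
    nucleosome repeat length (NRL) estimation from dyad-distance
    phaseograms by peak detection and linear regression, paired-condition
    NRL comparison, discrete nucleosome classification between two
    conditions (stable, common, shifted, gained, lost) using
    fraction-of-overlap interval matching, aggregate occupancy and DNA
    methylation profiles around genomic features, and interval enrichment
    against length-preserving random placement with an exact test. A
    synthetic-data generator emulating phased nucleosome arrays with
    condition-specific spacing provides ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    methods,
    tools,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    BiocGenerics,
    Biostrings,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
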