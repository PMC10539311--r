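Package: chartographer
Title: Statistical Analysis of RNA-DNA Proximity-Ligation Contact Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing chromatin-associated RNA (caRNA) contact
    maps from RNA-DNA proximity-ligation assays such as ChAR-seq.
    Implements delocalization scoring of caRNAs with a beta-binomial
    regression null and empirical-Bayes shrinkage, a multinomial
    generative model of RNA-DNA contacts with a distance-decay kernel and
    DNA-locus bias, interactome-space differential testing with a
    negative-binomial engine, priority-rule classification of unannotated
    transcribed loci, and caRNA-gene network construction with bootstrap
    edge-sign enrichment. Includes a synthetic-data generator with planted
    ground truth so that every stage of the analysis can be validated
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    stats,
    utils,
    methods,
    tibble,
    dplyr,
    rlang,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    tidyr,
    DESeq2,
    glmmTMB,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
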