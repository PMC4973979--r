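Package: tfbsburden
Title: Somatic Mutation Burden and Disruption at Transcription Factor Binding Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide analysis of somatic mutation burden at transcription
    factor binding sites (TFBSs). Scans a reference genome with position weight
    matrices under exact dynamic-programming p-value calibration, classifies
    motif matches into putatively functional sites (constitutive open
    chromatin) and position-matched control sites, intersects somatic
    substitutions and germline polymorphisms with the site catalog, and
    quantifies burden (four-way contingency tests, double ratios, per-position
    profile shape tests), binding disruption (relative PWM scores with
    Price-Bonett ratio-of-medians confidence intervals), 96-channel
    trinucleotide mutational spectra with Manhattan-distance clustering,
    transcriptional strand asymmetry, chromatin loop-anchor and
    chromatin-state context, and a site-level logistic mutation model. A
    synthetic-data generator with planted effects supports ground-truth
    recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
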