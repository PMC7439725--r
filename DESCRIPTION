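Package: mpradiverge
Title: Cis and Trans Regulatory Divergence from Massively Parallel Reporter Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for massively parallel reporter assay (MPRA)
    experiments run on orthologous regulatory element pairs in two cellular
    environments. Quantifies per-sequence transcriptional activity from
    barcode-level RNA/DNA counts, tests cis (sequence-driven), trans
    (environment-driven) and native activity differences with null
    differential controls and empirical-FDR calibration, classifies
    compensatory versus directional cis-trans pairs, links transcription
    factor motifs to activity and to cis/trans effects through nested linear
    models, scores enhancer redundancy inside topologically associating
    domains with Otsu thresholding of expression correlations, and calls
    transcription start site conservation from CAGE coverage. Includes a
    synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
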