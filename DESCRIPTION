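Package: dysbiosr
Title: Longitudinal Microbiome Dysbiosis Analysis for DSS-Colitis Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable analysis pipeline for longitudinal gut-microbiome
    dysbiosis studies of the DSS-colitis type. Provides community profiling
    of taxon/OTU/function count tables (rarefaction, relative abundance,
    rank aggregation, richness and Pielou evenness), Bray-Curtis
    dissimilarity and principal component analysis by eigendecomposition of
    a correlation matrix, qPCR standard-curve quantification with a fixed
    reallocation randomization test for expression ratios, a flagellin
    transcript-to-gene expression index, SEED-style functional category
    aggregation with curated gene panels, and thresholded Pearson
    correlation networks joining host markers, OTUs and function categories
    for biomarker discovery. Includes a synthetic-data generator that
    emulates a DSS-colitis time course with known ground truth for
    calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
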