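Package: imagetx
Title: Imaging Transcriptomics of Regional Gray-Matter Alterations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links case-control maps of regional gray-matter volume (GMV)
    alteration to regional gene expression. Provides covariate-adjusted
    per-region linear models with Benjamini-Hochberg correction, first-component
    partial least squares (PLS1) association with permutation tests of explained
    variance and bootstrap z-scored gene weights, a permutation enrichment-ratio
    statistic over gene lists and cortical cell-type classes, hemisphere-aware
    spherical spin-test spatial nulls for parcellated brain maps, receptor-map
    correlation, and scaled-robust-sigmoid expression normalization. A synthetic
    data module generates parcellation atlases, subject cohorts with planted
    atrophy, spatially autocorrelated expression with planted gene alignment,
    gene sets, and receptor maps, so the full analysis is testable end to end
    without subject-level imaging or donor expression data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    mixOmics,
    optparse
Config/testthat/edition: 3
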