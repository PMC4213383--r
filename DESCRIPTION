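Package: quinomics
Title: Differential Multiomics of a Bacterial Carbon-Source Shift
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for differential multiomics analysis of a
    bacterial carbon-source shift experiment (six vs four biological
    replicates, duplicate LC/MS injections): curation of untargeted LC/MS
    feature tables (blank subtraction, adduct/isotope/dimer annotation and
    redundancy collapsing), replicate quality control by relative standard
    deviation, fold-ratio estimation with Fieller confidence intervals and
    threshold classification of metabolites, accurate-mass identification
    with MSI confidence levels, adenylate energy charge from calibrated
    AMP/ADP/ATP quantification, Pareto-scaled principal component analysis,
    and threshold-based classification of RNA-seq gene counts with a
    median-of-ratios normalization. A synthetic-data generator reproduces
    the statistical structure of the study design so every stage is
    testable without raw instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
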