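Package: episig
Title: Compact DNA Methylation Episignature Classifiers with Mosaic
    Adjudication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds compact blood DNA-methylation episignature classifiers
    for Mendelian disorders of the epigenetic machinery. Differentially
    methylated CpG sites are found by covariate-adjusted epigenome-wide
    association analysis on M-values, compressed by a bootstrap-ensemble
    minimum-redundancy-maximum-relevance (mRMR) selection, and used to
    train a linear support vector machine with Platt probability scores.
    Stepwise re-training recruits moderate-effect and mosaic carriers into
    the case set, and suspected mosaics are adjudicated against loess-
    smoothed quantile bands of in-silico synthesized mosaic mixtures.
    Includes a synthetic EPIC-like cohort generator for end-to-end testing,
    a mean normalized methylation deviation severity statistic with
    survival-model association to age at onset, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    graphics,
    jsonlite,
    stats,
    survival,
    tools,
    utils
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
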