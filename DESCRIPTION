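Package: qpcrlmm
Title: Mixed-Effects Delta-Delta-Ct Analysis of Factorial QPCR Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of quantitative PCR cycle-threshold (Ct) data from
    factorial knockout/hormone studies with a linear mixed-effects model
    (fixed gene, genotype and hormone factors with all interactions, a
    Gaussian random intercept per animal) fitted by profiled REML/ML.
    Provides likelihood-ratio chi-square tests of fixed-effect terms with
    Benjamini-Hochberg adjustment, delta-delta-Ct interaction contrasts with
    fold-change point estimates, 95% confidence intervals and direction
    calls, and a four-class regulation classifier (hormone-only,
    genotype-only, both without interaction, both with interaction).
    Companion modules implement a discovery-stage expression screen
    (quantile normalization, group-wise t-tests, fold-change/FDR filters)
    and a chromogenic in situ hybridization densitometry pipeline (red
    channel inversion, rolling-ball style background subtraction, Otsu
    thresholding, watershed separation of touching nuclei, per-object
    absorbance density), plus seeded synthetic-data generators for Ct
    tables, expression matrices and stained-section images with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    limma,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
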