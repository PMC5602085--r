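Package: glaucoSF
Title: Structure-Function Analysis for Early Glaucoma with the
    Two-Global-Flash Multifocal ERG
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for multimodal structure-function analysis of early
    glaucoma in the central retina. Implements maximal-length m-sequence
    stimulation and the two-global-flash multifocal electroretinogram
    (2F-mfERG) protocol, first-order kernel extraction by cross-correlation,
    epoch root-mean-square (RMS) amplitudes for the direct component (DC,
    15-45 ms) and the two induced components (IC1 45-75 ms, IC2 75-105 ms)
    averaged over the central 7 (10 degrees) and 19 (15 degrees) hexagons;
    spatially matched standard automated perimetry summaries (linear mean
    sensitivity and mean defect over the central 10 and 15 degrees, with
    ganglion-cell displacement correction) and optical coherence tomography
    summaries (ETDRS 1+3 mm macular thickness, ganglion cell-inner
    plexiform layer elliptical annulus); covariate-adjusted group statistics
    (ANOVA with Bonferroni post hoc, linear mixed-effects structure-function
    regressions, Benjamini-Hochberg FDR, logistic-regression-based ROC with
    Mann-Whitney AUC and DeLong comparisons); a per-eye multimodal
    abnormality classifier with cross-tabulated modality agreement; and a
    seeded synthetic cohort generator so the whole pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    lme4,
    lmerTest,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
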