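Package: EnviroOmics
Title: Multi-Omic Analytics for Enviromimetic-Treated Forebrain Organoid Screens
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reusable analysis chain for chemically defined environmental-
    exposure ("enviromimetic") screens in human forebrain organoids: targeted
    LC/MS metabolite quantification from centroided mzML runs (ppm and
    retention-time windowed peak-height extraction), blank-based detection
    thresholds with threshold imputation and group-versus-vehicle differential
    statistics, isobaric-label proteome QC (quantile normalization,
    coefficient-of-variation and correlation reports) with one-way ANOVA and
    Dunnett-style post-hoc testing, and flow-cytometry analytics (Dean-Jett-Fox
    style DNA-content deconvolution and two-channel apoptosis/DNA-damage
    quadrant gating with fold-change tests). A synthetic-data module generates
    every pipeline input with known ground truth so each stage is verifiable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    mzR,
    limma,
    multcomp,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
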