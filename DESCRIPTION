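Package: fociLET
Title: Linking LET, gammaH2AX Focus Volume and Clonogenic Cell Killing for
    Carbon-Ion Beams
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative inference chain relating the linear energy transfer
    (LET) of carbon-ion beams, the volume of gammaH2AX foci (a microscopy
    proxy for clustered DNA double-strand breaks) and clonogenic cell
    killing. Provides Gaussian fits to per-nucleus maximum focus-volume
    histograms with linear-in-LET laws for the fitted mean and standard
    deviation, a quadratic law for the fraction of unhit cells, hit-fraction
    normalization of clonogenic killing, dose-averaged LET computation for
    spread-out Bragg peak (SOBP) beams composed from ridge-filter weighted
    monoenergetic depth profiles, and a lethal-volume threshold concordance
    sweep. A synthetic-data generator emulates the statistical structure of
    the microscopy, occupancy and clonogenic measurements so that every
    stage of the pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, minpack.lm, pracma, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
biocViews: Software, StatisticalMethod, Radiotherapy
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'concordance.R'
    'defaults.R'
    'foci-model.R'
    'fociLET-package.R'
    'io.R'
    'let-mixing.R'
    'pipeline.R'
    'survival.R'
    'synthetic-data.R'
    'unhit-model.R'
    'utils.R'
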