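Package: tgcalcium
Title: Ex Vivo Calcium Imaging Analysis for Neonatal Trigeminal Ganglion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for spontaneous activity recorded by ex vivo
    calcium imaging of neonatal trigeminal ganglion explants expressing
    GCaMP6s. Provides bleach and rigid motion correction, activity-based
    soma (ROI) detection, sliding-window dF/F0 computation, PeakCaller-style
    calcium-transient detection and parametrization, all-pairs Pearson
    correlation with inter-ROI distance analysis, watershed nuclei counting,
    soma-diameter classification (small/medium/large), population summaries
    (percent active, subtype active-fraction estimation, group comparisons),
    temporal color-coded activity maps, and a ground-truthed synthetic-movie
    generator so every stage is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    png,
    EBImage,
    signal,
    minpack.lm,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
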