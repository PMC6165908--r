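Package: csdsi
Title: Compressed-Sensing Diffusion Spectrum Imaging Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and analysis of q-space sampling schemes for diffusion
    MRI, centred on compressed-sensing diffusion spectrum imaging (CS-DSI).
    Provides the truncated-sphere Cartesian q-space grid, undersampled CS-DSI
    and staggered multi-shell (HARDI) scheme generators, an iterative
    shrinkage-thresholding (ISTA) solver that recovers the diffusion propagator
    from undersampled q-space measurements, propagator-derived orientation
    distribution functions and scalar metrics (MSD, RTOP), diffusion tensor and
    constrained diffusion kurtosis model fitting with protocol-specific b-value
    subset selection, post hoc shell assignment of Cartesian-grid b-values, a
    multi-tensor phantom simulator with Rician noise, and the quantitative
    comparison and test-retest reliability statistics (NMSE, angular
    cross-correlation, peak angle metrics, ICC, wsCV) needed to compare
    acquisition protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    pracma,
    RNifti
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
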