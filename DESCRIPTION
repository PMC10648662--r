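Package: accelGRF
Title: Comparing Accelerometer-Based Estimators of Vertical Ground Reaction
    Force in Running
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to benchmark single-accelerometer methods for estimating
    vertical ground reaction force (vGRF) features during running. Provides a
    synthetic running-gait generator with closed-form latent force features, an
    inertial measurement unit (IMU) processing chain (calibration, quiet-period
    bias removal, saturation fusion, zero-phase Butterworth filtering, Madgwick
    orientation estimation and gravity removal, segment and tilt-corrected
    coordinate systems, stance windowing), a gold-standard force-plate feature
    extractor (impact peak via high-frequency spectral reconstruction, loading
    rate, active peak, stance average), a registry of 27 published estimation
    methods in four families with a leave-one-participant-out training harness,
    and linked-replicates agreement statistics (bias, repeatability
    coefficient, limits of agreement, condition-effect mixed models).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    nlme,
    signal,
    stats,
    utils
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
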