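Package: voiceflow
Title: Ambulatory Glottal Airflow Estimation from Neck-Surface Acceleration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the glottal airflow waveform from a neck-surface
    accelerometer signal by subglottal impedance-based inverse filtering
    (IBIF): a mechano-acoustic transmission-line model of the subglottal
    tract and neck skin yields a subject-specific inverse FIR filter whose
    five scale parameters are calibrated against oral-airflow recordings by
    particle swarm optimization. Week-long recordings are processed in
    hourly chunks, segmented into 50 ms frames, gated by voicing and
    onset/offset stability, and summarized into eleven cycle- and
    spectrum-based aerodynamic measures (ACFL, MFDR, OQ, SQ, NAQ, H1-H2,
    HRF and SPL-normalized variants). Window- and week-level statistics
    feed paired hypothesis tests with Benjamini-Hochberg false-discovery
    control and L1-regularized logistic-regression / support-vector
    screening of phonotraumatic vocal hyperfunction under
    leave-one-pair-out nested cross-validation. A forward simulator
    generates accelerometer signals, calibration gestures and two-group
    cohorts for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    MASS,
    e1071,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
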