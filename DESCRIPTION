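Package: stereomotion
Title: Simulation and Single-Trial Decoding of 3D Motion Direction from fMRI Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how 3D motion direction (toward versus away from the
    observer) can be decoded from single-trial fMRI responses in the human motion
    complex. Provides a binocular motion-in-depth stimulus engine (stereoscopic,
    perspective and combined cue conditions, plus a 90-degree rotated control), a
    synthetic generator of population-receptive-field-structured cortical surface
    time series with injectable coarse-scale retinotopic biases, a single-trial
    amplitude extraction pipeline (high-pass filtering, nuisance regression,
    peristimulus z-normalization, window averaging), linear support-vector-machine
    decoding with balanced bootstrap splits and shuffled-label null distributions,
    coarse-scale bias diagnostics (eccentricity and horizontal-meridian sub-ROI
    splits with vertex-count equating), and exact nonparametric group tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    lme4,
    lmerTest,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
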