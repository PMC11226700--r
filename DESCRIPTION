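Package: ecogvad
Title: Speech Event Detection from Electrocorticography
Version: 0.1.0
Authors@R:
    person("Aurelien", "Marchal", email = "a.marchal@posteo.net", role = c("aut", "cre"))
Description: Frame-wise detection of speech events (a neural analogue of
    voice-activity detection) from multichannel electrocorticography (ECoG).
    Implements the full analysis chain: per-grid common-average referencing,
    line-noise removal, a seven-band zero-phase Butterworth filter bank with
    smoothed Hilbert envelopes, 21-dimensional lagged band-power features, a
    linear frame-wise detector with Haufe activation-pattern interpretation,
    leave-one-trial-out cross-validation with trial-wise permutation testing,
    surrogate labeling for imagined (covert) speech, correlation-ranked
    multi-electrode stacking, and cross-mode / cross-subject model transfer.
    Ships a paradigm-structured synthetic ECoG generator with known
    ground-truth speech windows and band-modulation profiles so the whole
    pipeline can be exercised and validated without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
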