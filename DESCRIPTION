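Package: lfpphase
Title: Amplifier Phase Distortion and Offline Correction for Extracellular Field Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for quantifying and undoing the phase distortion that the
    analog high-pass filter of a neural data acquisition system introduces
    into local field potential (LFP) recordings. Provides parametric and
    tabulated amplifier transfer functions, sine-wave calibration of a
    system's gain and phase response, a frequency-domain generator of
    synthetic signal pairs with prescribed power spectrum and coherence,
    phase-only spectral correction, and cross-correlation / spike-triggered
    LFP averaging diagnostics, including a classifier for the artefactual
    biphasic correlation shape that high-pass filtering produces from a
    purely monophasic underlying correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
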