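Package: entrainr
Title: Neural Entrainment and ERP Analysis for Statistical Word
    Segmentation EEG Experiments
Version: 0.1.0
Authors@R:
    person("EEG", "Methods Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for frequency-tagging experiments on statistical word
    segmentation from continuous syllable streams, aimed at neonatal and
    infant high-density EEG. Builds constrained artificial-language
    stimulus streams and session schedules, audits their transitional
    probability structure, simulates multichannel EEG recordings with a
    controlled signal model (steady-state syllable response, emergent
    word-rate entrainment, condition-dependent ERPs, 1/f plus sensor
    noise, artifacts), and analyses them: zero-phase filtering,
    resampling, epoching and artifact rejection; denoising source
    separation (DSS); evoked power, inter-trial coherence and SNR
    against a power-law noise floor; sliding-window learning curves;
    electrode-wise tests with FDR correction and repeated-measures
    ANOVA; and spatio-temporal cluster-based permutation statistics for
    ERP contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
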