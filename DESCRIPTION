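Package: choicebias
Title: Decoupling Sensory and Decisional Biases in Two-Alternative
    Perceptual Decisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Joint maximum-likelihood fitting of signal-detection
    psychometric models across two mirrored response mappings to separate
    sensory biases (shifts in the internal stimulus representation) from
    decisional biases (criterion shifts). Includes lapse-rate and two-slope
    model variants, a consecutive likelihood-ratio-test model-selection
    ladder with four-way bias classification, comparison against a
    high-threshold indecision (guessing) model by AIC, a constant-stimuli
    trial simulator for parameter-recovery and calibration studies, and
    end-to-end dataset orchestration with group-level summaries.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
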