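Package: cardiosync
Title: Cardiorespiratory Synchrony Analysis for Audience Physiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying stimulus-response and inter-subject
    synchrony of heart and respiration signals recorded from audiences,
    for example during live concerts. Covers preprocessing of raw ECG and
    respiration-belt recordings (gap interpolation, zero-phase filtering,
    R-peak and inspiration-peak detection with reproducible manual edits),
    conversion of peak trains to instantaneous rate (BPM) and wrapped
    cycle-phase series on a common 20 Hz grid, spectral-flux stimulus
    features with audience-frequency sub-bands, four sliding-window
    synchrony families (stimulus-response and inter-subject correlation
    and phase coherence), circular-shift permutation tests with false
    discovery rate control, section-averaged and boundary-epoched
    aggregation, and linear mixed-model contrasts between presentation
    modalities. A seedable synthetic concert-audience generator provides
    ground-truth fixtures for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    signal,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    broom,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
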