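Package: neuroplay
Title: EEG Band-Power Analysis for Game-Based Learning Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studies that instrument a virtual-reality supply-chain
    role-play game with consumer-grade EEG. Provides a deterministic
    multi-echelon inventory game engine (safety stock, reorder point,
    economic order quantity, scripted demand, bullwhip diagnostics), a
    seeded generator of synthetic two-group 14-channel EEG cohorts and
    7-point Likert survey tables with known ground truth, quality
    filtering and epoch rejection, five-band FFT absolute power per
    electrode, transparent band-ratio performance-metric proxies
    (attention, engagement, excitement, stress, relaxation, interest),
    0-1 normalised topographic scalp maps with a 10-20 to MNI152 lookup,
    and a non-parametric statistical layer (Shapiro-Wilk screening,
    Mann-Whitney U, seeded two-sample permutation tests, Likert sentiment
    aggregation), plus an end-to-end reproducible pipeline with EDF+ and
    CSV interchange.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    withr,
    zoo,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
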