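Package: surfspike
Title: Validation Analysis for Surface-Recorded Single-Unit Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to validate putative single-unit activity recorded from the
    brain surface with micro-electrocorticography grids against simultaneous
    penetrating-probe recordings. Provides extracellular waveform shape
    features (peak-to-trough duration, amplitude, trough/peak ratio,
    symmetry), log inter-spike-interval burst classification via the void
    parameter, spike-train cross-correlograms and peak lags, the SPIKE-distance
    synchrony measure against physical electrode distance, stimulus-evoked
    response quantification (response lag, onset-window Pearson correlation
    with Bonferroni control, effect size), group comparison tables, and a
    synthetic-session generator with the statistical structure these analyses
    assume (inhomogeneous Poisson and burst firing, envelope-driven responses
    with a fixed neural lag, distance-decaying shared-drive synchrony).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
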