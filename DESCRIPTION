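Package: fastconn
Title: Filter Average Short-Term (FAST) Functional Connectivity for EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for high-temporal-resolution dynamic functional
    connectivity analysis of multichannel EEG. Implements the filter
    average short-term (FAST) approach: a cohort-averaged long-term
    connectivity matrix (mean absolute Pearson correlation across
    participants) used as a static support that weights instantaneous
    squared-difference graph signals, yielding noise-robust connectivity
    tensors at up to single-sample resolution. Includes a synthetic
    EEG/ERP generator with 1/f background spectra and jittered N100/P300
    components, windowed network metrics (mean edge weight, average
    weighted clustering coefficient), a Morlet continuous-wavelet power
    baseline, nonparametric two-group statistics with Benjamini-Hochberg
    false-discovery-rate control and Cohen's d effect sizes, band-pass
    preprocessing, plain-text file formats, and an experiment runner that
    reproduces the ERP-detection simulation study end to end.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
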