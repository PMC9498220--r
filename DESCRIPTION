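Package: rqascale
Title: Monofractal Scaling Estimation from Recurrence Plots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the monofractal scaling exponent of a univariate time
    series from its recurrence plot. Implements four recurrence-based
    estimators (bin-wise standard deviation of the recurrence rate,
    laminarity, the log-log slope of the diagonal recurrence profile, and the
    ratio of consecutive diagonal recurrence rates) together with a
    Wiener-Khinchin spectral variant, a detrended fluctuation analysis
    benchmark, a 1/f^alpha colored-noise generator, and a Monte-Carlo driver
    that measures how well each estimator tracks the true spectral exponent
    across persistent and antipersistent signals, with and without
    observation noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
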