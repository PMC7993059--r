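Package: mmdews
Title: Moving Multivariate Distance as an Early-Warning Signal in Longitudinal Biomarker Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the Moving Multivariate Distance (MMD), a visit-to-visit
    Mahalanobis distance that quantifies intraindividual multivariate
    variability in longitudinal biomarker panels, and provides the analysis
    pipeline around it: cohort filtering for hemodialysis-style visit data,
    biomarker-set construction with variance-stabilizing transforms and
    population z-standardization, covariance sensitivity variants, Cox
    proportional-hazards survival analysis with clustered robust variance and
    the HR95 percentile-contrast effect size, pre-event half-year trend
    curves, a shuffled-visit permutation negative control, and a
    synthetic-cohort simulator for calibration and power studies.
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
    readr,
    rlang,
    splines,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
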