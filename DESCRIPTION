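Package: clockvar
Title: Clock Variability from Short Interval-Production Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates per-participant internal clock noise from a short
    1-second production task using drift-corrected, mean-scaled residual
    variability (the scaled RMSR), and validates the measure against the
    central-tendency (regression-to-the-mean) slope of a multi-duration
    temporal reproduction task. Includes a Bayesian-observer synthetic data
    generator with closed-form oracles, participant screening and outlier
    filtering, and default-prior Bayes factors (one-sample t test,
    correlation with posterior summaries, and nested linear mixed-model
    comparison with a participant random intercept) computed by numerical
    quadrature.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    lme4,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
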