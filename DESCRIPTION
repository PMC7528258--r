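Package: surprisal
Title: Compatibility and Surprisal Measures for Reported Effect Estimates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Translates reported summary effect estimates (point estimate
    plus interval limits or standard error) into evidential panels for
    arbitrary test hypotheses under the Wald normal approximation:
    two-sided and one-sided P-values, S-values (Shannon surprisals in bits
    or nats), maximum-likelihood ratios, and deviance (likelihood-ratio)
    statistics. Builds P-value (compatibility) and S-value (surprisal)
    functions over a grid of hypotheses, extracts compatibility and
    likelihood intervals at arbitrary levels, combines evidence across
    independent studies via the chi-squared referral of summed surprisals,
    and checks P-value validity (uniformity under the test model) by
    simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    jsonlite,
    readr,
    rlang,
    scales,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
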