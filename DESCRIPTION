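Package: pmroutes
Title: Robust Statistical Analysis of Mobile PM2.5 Route Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing time-ordered particulate-matter (PM2.5)
    concentration series collected along walking routes with a portable
    monitor. Provides heavy-tailed synthetic route generation, summary
    statistics and moving-average smoothing, exact order-statistic
    (sign-test) confidence intervals for the median, classification of
    route medians against the Quito Air Quality Index bands, a
    tie-corrected one-sided Wilcoxon rank-sum group comparison, the
    alpha-trimmed mean and trimean robust location estimators, and seven
    classical and robust scale estimators including the biweight
    midvariance family, subrange estimators, and the least-median-of-
    squares scale. All user-facing functions take data frames and return
    tibbles so analyses compose with the pipe.
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
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
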