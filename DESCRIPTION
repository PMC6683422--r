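Package: depcea
Title: Trial-Based Cost-Effectiveness Analysis of Depression-Care Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for trial-based cost-effectiveness
    analysis of four primary-care depression-care strategies (standard care,
    treatment as usual, online CBT, and a stepped-care pathway). Provides a
    calibrated synthetic patient-level cohort generator; cost cleaning with
    boxplot (IQR) outlier trimming; chained-equation multiple imputation with
    predictive-mean-matching draws and Rubin's-rules pooling; covariate
    adjustment by OLS for 12-week outcomes and by an identity-link gamma GLM
    for skewed sector costs; QALY construction from EQ-5D-5L utilities by
    area under the curve with carry-forward and two effect-persistence
    scenarios; a five-branch service-mix decision-tree expected-cost model;
    and Monte Carlo probabilistic sensitivity analysis yielding ICERs, net
    monetary benefit, cost-effectiveness acceptability curves, and
    incremental cost-effectiveness scatterplots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
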