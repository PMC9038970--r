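Package: eventmem
Title: Event Segmentation, Everyday Memory, and Mediation Analysis for Clinical Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how the segmentation of continuous everyday
    activity into discrete events relates to memory in case-control designs
    (for example PTSD versus control). Provides a synthetic cohort generator
    with an explicit exposure-mediator-outcome structure and known ground
    truth; segmentation-agreement scoring of button-press logs against
    one-second-bin group norms with min-max rescaling at each participant's
    number of marked bins; recall-proportion scoring and Cohen's kappa for
    coder validation; crossed random-intercept linear mixed models for
    group and symptom-severity analyses; quasi-Bayesian causal mediation
    (average causal mediation effect, average direct effect, proportion
    mediated) with Monte-Carlo intervals; and a one-call pipeline that runs
    the full analysis chain and writes a structured report.
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
    lme4,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
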