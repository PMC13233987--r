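Package: cedesign
Title: Design of Two-Arm Randomized Trials with Composite Endpoints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the design phase of two-arm randomized controlled trials
    whose primary endpoint is a composite of two events. For time-to-event
    composites the law of the time to the first event is derived from Weibull
    component marginals bound by an Archimedean copula (Frank, Gumbel or
    Clayton); the package computes non-proportional-hazards effect summaries
    (geometric average hazard ratio, average hazard ratio, median ratio,
    restricted mean survival time ratio), logrank-based sample sizes
    (Schoenfeld and Freedman forms on the geometric average hazard ratio),
    and the asymptotic relative efficiency criterion for choosing between the
    composite and its most relevant component. Binary composite analogues
    (composite probability, Pearson-correlation attainability bounds, effect
    conversion across risk difference, relative risk and odds ratio, sample
    size, and relative efficiency) are included, together with simulators for
    both endpoint types and a command-line interface.
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
    pracma,
    purrr,
    stats,
    tibble,
    utils
Suggests:
    fitdistrplus,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
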