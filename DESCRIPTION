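Package: msltcba
Title: Multi-State Lifetable Cost-Benefit Analysis of Outdoor Unhealthy
    Food Advertising Restrictions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Societal cost-benefit analysis of restricting unhealthy food
    and drink advertising on state-owned public transport assets, built
    around a proportional multi-state lifetable Markov cohort model.  The
    pipeline converts an advertising-restriction effect on unhealthy food
    purchasing into stratum-level changes in energy intake, body weight and
    body mass index, shifts the incidence of nine obesity-related diseases
    via potential impact fractions, simulates disease and survival
    trajectories to obtain health-adjusted life years and healthcare cost
    offsets, monetises outcomes with a value of a statistical life year,
    and reports net present value and benefit-cost ratios with Monte Carlo
    uncertainty intervals and a suite of sensitivity scenarios.  All inputs
    are synthetic, internally consistent population tables generated with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
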