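Package: discountr
Title: Simulation and Group Analysis of Adaptive Delay-Discounting Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to simulate, score, and analyze an adaptive monetary
    delay-discounting (intertemporal choice) task. Implements the
    bisection titration staircase that brackets per-delay indifference
    points, simulated responders (deterministic and logistic hyperbolic
    discounters, inattentive responders), hyperbolic discount-rate
    scoring with catch-trial validity exclusion, a synthetic-cohort
    generator for clinical group comparisons (ARFID, anorexia nervosa,
    healthy controls), and the corresponding inference stack: ANCOVA of
    log discount rate on group with an age covariate, age-adjusted-mean
    Bonferroni contrasts, Hedges' g, multiple regression on clinical
    presentation flags, and achieved power from the noncentral F
    distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    car,
    emmeans,
    optparse
Config/testthat/edition: 3
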