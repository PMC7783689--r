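Package: bmicohort
Title: Markov Cohort Simulation of Body-Mass-Index Class Dynamics, Costs and
    Life Expectancy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates age-varying transition probabilities between body-mass-index
    (BMI) classes from sparse longitudinal height/weight records via left-truncated
    parametric survival analysis, and simulates a gender-stratified Markov birth
    cohort (ages 2 to 100) across the states normal weight, overweight, obese grade
    1, obese grade 2 and dead.  Produces prevalence trajectories, survival-adjusted
    discounted incremental health-care costs from two-part cost models, life
    expectancy and years of life lost under base-case, probabilistic-sensitivity
    and scenario (obesity-elimination, conditional-start) settings.  Includes a
    synthetic-data generator with known transition hazards for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    flexsurv,
    survival,
    jsonlite,
    optparse
Config/testthat/edition: 3
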