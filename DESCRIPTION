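Package: diabproj
Title: Dynamic Markov Projection of Diagnosed Diabetes Burden
Version: 0.1.0
Authors@R:
    person("Projection", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A discrete-time, three-state (no diabetes, diagnosed diabetes,
    death) Markov projection of the adult diagnosed-diabetes population by
    single year of age, race, and sex.  Transition inputs are estimated from
    survey-style microdata: survey-weighted logistic regression with
    predictive margins for initial prevalence, a period-grouped logistic
    model for annual incidence, and a discretized-survival Poisson model for
    the relative mortality risk used to allocate externally projected deaths
    between disease states.  Includes a seeded synthetic-data generator
    emulating cross-sectional health-interview surveys, mortality follow-up,
    and a cohort-component census projection; Monte Carlo uncertainty
    propagation from regression-coefficient draws; and incidence sensitivity
    scenarios with publication-style reporting tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
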