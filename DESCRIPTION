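Package: contresist
Title: Continuum-of-Resistance Estimators for Cohort Generalizability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generalizes prevalences, incidence rates, and Kaplan-Meier
    curves from the participants of an epidemiological cohort to the full
    invited population by exploiting nested re-examination participation.
    Implements the substitution estimator (non-participants assumed similar
    to baseline participants who declined a re-examination) and the
    two-point linear extrapolation estimator over participation-propensity
    shares, together with rate-scale handling, backing-out of unobserved
    non-participant statistics, mean-squared-error representativeness
    scoring, Kaplan-Meier mixture and extrapolation adjustments, and a
    synthetic selective-participation cohort simulator for validating the
    estimators against known population truths.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    survival,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
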