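Package: remedbp
Title: Symbolic Threshold Rule Extraction for Ambulatory Blood Pressure Cohorts
Version: 0.1.0
Authors@R:
    person("MAS", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for mining prognostic thresholds from 24-hour ambulatory
    blood pressure (ABP) recordings. Implements reading-level quality control,
    time-weighted 24-hour blood pressure level (WBP) and the Average Real
    Variability (ARV) index, univariate logistic screening of candidate risk
    factors, sensitivity-first conjunctive threshold-rule induction in the
    style of the REMED algorithm for imbalanced clinical outcomes,
    imbalance-preserving cross-validated evaluation with a Gaussian naive
    Bayes baseline, and a seeded synthetic-cohort simulator for end-to-end
    validation when the original cohort data are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
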