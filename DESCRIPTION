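Package: paptitrate
Title: Decision Support for Positive Airway Pressure and Oxygen Titration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for attended positive-airway-pressure (CPAP/BiPAP) and
    supplemental-oxygen titration in obstructive sleep apnea with chronic
    hypercapnia. Provides a data model for overnight titration sessions
    (airflow, SpO2, transcutaneous pCO2, device-setting schedules), AASM-style
    apnea/hypopnea scoring and AHI computation, discretization of each epoch
    into a patient state over the three clinically controlled conditions
    (apnea, oxygenation band, pCO2 trend), an explainable rule-based titration
    policy, a Markov-decision-process layer that estimates transition
    probabilities from treatment records and optimizes the probability of
    reaching the target state, a stochastic overnight patient simulator, and
    cohort correlation analysis stratified by hypercapnia and modality.
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
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
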