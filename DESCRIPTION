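Package: riskpath
Title: Risk-Factor Time-Path Simulation and Estimation for Type 2 Diabetes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Patient-level annual-cycle simulation of clinical risk-factor
    trajectories in type 2 diabetes: first-order dynamic panel equations for
    seven continuous risk factors (HDL-C, LDL-C, systolic blood pressure,
    HbA1c, haemoglobin, heart rate, BMI), Weibull proportional-hazards
    annual transition probabilities for absorbing conditions (atrial
    fibrillation, albuminuria, peripheral vascular disease, eGFR below 60),
    and a two-part Tobit engine for continuous eGFR. Ships a published
    coefficient set, refits every equation family from long-format panel
    data (random-effects dynamic panel, censored-normal Tobit,
    left-truncated parametric proportional hazards with backwards stepwise
    selection), generates synthetic trial-like cohorts and panels, and
    provides internal-validation machinery (observed-versus-predicted time
    paths, quintile calibration, Kaplan-Meier versus simulated cumulative
    incidence).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    MASS,
    Matrix,
    stats,
    survival,
    utils
Suggests:
    flexsurv,
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
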