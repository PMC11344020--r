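# Independent oracles: hand-coded arithmetic kept deliberately separate from
# the package's own code paths.

# Published dynamic-equation coefficients, typed directly from the printed
# table (column order: phi1 lag, phi2 first, phi6 ln-duration, phi5 age,
# phi3 female, phi4 white/black/asian, phi0 constant).
TABLE_DYNAMIC <- list(
  hdl = c(phi1 = 0.238, phi2 = 0.506, phi6 = -0.001, phi5 = 0.001,
          phi3 = 0.055, w = 0.019, b = 0.045, a = 0.015, phi0 = 0.188),
  ldl = c(phi1 = 0.295, phi2 = 0.383, phi6 = -0.037, phi5 = -0.004,
          phi3 = 0.100, w = -0.001, b = 0.032, a = -0.037, phi0 = 1.027),
  sbp = c(phi1 = 0.271, phi2 = 0.291, phi6 = 0.034, phi5 = 0.027,
          phi3 = 0.356, w = 0.365, b = 0.780, a = -0.416, phi0 = 56.461),
  hba1c = c(phi1 = 0.456, phi2 = 0.243, phi6 = 0.083, phi5 = -0.012,
            phi3 = 0.031, w = -0.082, b = 0.065, a = -0.091, phi0 = 2.945),
  haemoglobin = c(phi1 = 0.329, phi2 = 0.462, phi6 = -0.096, phi5 = -0.010,
                  phi3 = -0.177, w = -0.037, b = -0.208, a = -0.081,
                  phi0 = 3.698),
  heart_rate = c(phi1 = 0.283, phi2 = 0.346, phi6 = -0.186, phi5 = -0.059,
                 phi3 = 0.560, w = 0.316, b = 0.376, a = 1.389,
                 phi0 = 30.755),
  bmi = c(phi1 = 0.684, phi2 = 0.289, phi6 = 0.000, phi5 = -0.008,
          phi3 = 0.039, w = 0.022, b = -0.079, a = -0.078, phi0 = 1.219))

# Published condition-equation coefficients (Weibull PH), typed directly.
TABLE_SURVIVAL <- list(
  AF = list(betas = c(constant = -11.269, age_at_rand = 0.060,
                      female = -0.576, eth_white = 1.073,
                      eth_black = 1.150, `lag:bmi` = 0.058,
                      `lag:hdl` = -0.487), ln_gamma = 0.191),
  ALB = list(betas = c(constant = -8.590, age_at_rand = 0.011,
                       female = -0.298, eth_white = 0.291,
                       `lag:bmi` = 0.028, `lag:sbp` = 0.011,
                       `lag:hba1c` = 0.102), ln_gamma = 0.204),
  PVD = list(betas = c(constant = -11.596, age_at_rand = 0.030,
                       eth_white = 1.120, smoker_baseline = 0.465,
                       `lag:hba1c` = 0.151), ln_gamma = 0.443),
  EGFR_LT60 = list(betas = c(constant = 0.706, `first:egfr` = -0.037,
                             `lag:egfr` = -0.032), ln_gamma = 0.078))

# Published eGFR Tobit coefficients, typed directly.
TABLE_TOBIT <- list(
  below60 = list(betas = c(constant = 36.058, age_at_rand = -0.100,
                           `first:egfr` = 0.232, `lag:egfr` = 0.459,
                           `lag:sbp` = -0.025, ln_duration = -1.335),
                 sigma = 11.888),
  atabove60 = list(betas = c(constant = 36.317, age_at_rand = -0.230,
                             `first:egfr` = 0.446, `lag:egfr` = 0.303,
                             `lag:sbp` = -0.011, ln_duration = -0.753),
                   sigma = 13.839))

# spreadsheet-style dot product for the dynamic prediction of one patient
oracle_dynamic_pred <- function(tab, y_prev, y_first, female, ethnicity,
                                age, duration) {
  eth_term <- switch(ethnicity, white = tab[["w"]], black = tab[["b"]],
                     asian = tab[["a"]], other = 0)
  tab[["phi0"]] + tab[["phi1"]] * y_prev + tab[["phi2"]] * y_first +
    tab[["phi3"]] * female + eth_term + tab[["phi5"]] * age +
    tab[["phi6"]] * log(max(duration, 0.5))
}

# dot product for a named beta vector against one patient row
oracle_linear_predictor <- function(betas, row) {
  val <- 0
  for (nm in names(betas)) {
    x <- if (nm == "constant") 1
    else if (nm == "age_at_rand") row$age_at_rand
    else if (nm == "female") row$female
    else if (nm == "smoker_baseline") row$smoker_baseline
    else if (nm == "eth_white") as.numeric(row$ethnicity == "white")
    else if (nm == "eth_black") as.numeric(row$ethnicity == "black")
    else if (nm == "eth_asian") as.numeric(row$ethnicity == "asian")
    else if (nm == "ln_duration") log(max(row$duration, 0.5))
    else if (startsWith(nm, "lag:")) row[[sub("^lag:", "", nm)]]
    else if (startsWith(nm, "first:"))
      row[[paste0("first_", sub("^first:", "", nm))]]
    else stop("oracle: unknown covariate ", nm)
    val <- val + betas[[nm]] * x
  }
  val
}

# cumulative hazard by numerical integration of h(u) = gamma u^(g-1) exp(eta)
oracle_cumhaz_weibull <- function(eta, ln_gamma, t) {
  g <- exp(ln_gamma)
  if (t == 0) return(0)
  stats::integrate(function(u) g * u^(g - 1) * exp(eta), 0, t,
                   rel.tol = 1e-10)$value
}

# closed-form moments of N(mu, sd^2) truncated to (lo, hi)
oracle_truncnorm_moments <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  Z <- pnorm(b) - pnorm(a)
  da <- dnorm(a); db <- dnorm(b)
  m <- mu + sd * (da - db) / Z
  aa <- if (is.finite(a)) a * da else 0
  bb <- if (is.finite(b)) b * db else 0
  v <- sd^2 * (1 + (aa - bb) / Z - ((da - db) / Z)^2)
  c(mean = m, var = v)
}

# hand-coded product-limit estimator (right-censored, no delayed entry)
oracle_km <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(tt))
  for (k in seq_along(tt)) {
    n_risk <- sum(time >= tt[k])
    d <- sum(time == tt[k] & event == 1)
    s <- s * (1 - d / n_risk)
    out[k] <- s
  }
  data.frame(time = tt, surv = out)
}

# Nelson-Aalen slope of unit-exponential residuals: cumulative hazard of the
# residual sample regressed through the origin against the residual value
oracle_na_slope <- function(residual, event) {
  fit <- survival::survfit(survival::Surv(residual, event) ~ 1)
  H <- -log(fit$surv)
  ok <- is.finite(H) & fit$n.event > 0
  sum(H[ok] * fit$time[ok]) / sum(fit$time[ok]^2)
}
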