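# Fixture builders (all in code; nothing read from disk).

# one- or multi-row cohort table with sensible defaults
make_state <- function(n = 1L, id = sprintf("S%03d", seq_len(n)),
                       age_at_rand = 64, female = 0, ethnicity = "white",
                       smoker_baseline = 0, duration = 16, hdl = 1.1,
                       ldl = 2.2, sbp = 135, hba1c = 7, haemoglobin = 13.8,
                       heart_rate = 72, bmi = 30, egfr = 75, ...) {
  as_cohort(data.frame(id = id, age_at_rand = age_at_rand, female = female,
                       ethnicity = ethnicity,
                       smoker_baseline = smoker_baseline,
                       duration = duration, hdl = hdl, ldl = ldl,
                       sbp = sbp, hba1c = hba1c, haemoglobin = haemoglobin,
                       heart_rate = heart_rate, bmi = bmi, egfr = egfr,
                       ..., stringsAsFactors = FALSE))
}

# randomized patient states spanning realistic covariate ranges
random_states <- function(n, seed) {
  set.seed(seed)
  make_state(
    n = n,
    age_at_rand = runif(n, 40, 85),
    female = rbinom(n, 1, 0.5),
    ethnicity = sample(c("white", "black", "asian", "other"), n,
                       replace = TRUE),
    smoker_baseline = rbinom(n, 1, 0.3),
    duration = runif(n, 1, 40),
    hdl = runif(n, 0.6, 2.5), ldl = runif(n, 1, 5),
    sbp = runif(n, 100, 180), hba1c = runif(n, 5.5, 11),
    haemoglobin = runif(n, 10, 17), heart_rate = runif(n, 50, 100),
    bmi = runif(n, 20, 45), egfr = runif(n, 30, 120))
}

# a custom dynamic equation for targeted tests
dyn <- function(risk_factor = "hba1c", phi0 = 0, phi1 = 0, phi2 = 0,
                phi3 = 0, phi4_white = 0, phi4_black = 0, phi4_asian = 0,
                phi5 = 0, phi6 = 0, resid_sd = 0, re_sd = 0) {
  dynamic_coefficients(risk_factor, phi0, phi1, phi2, phi3, phi4_white,
                       phi4_black, phi4_asian, phi5, phi6, resid_sd, re_sd)
}

# panel whose eGFR observation process is *censored* at the regime limits
# (boundary mass present), generated from known Tobit coefficients - the
# observation model under which the censored-normal likelihood is correct
censored_tobit_panel <- function(n, years, coef, seed,
                                 base_mean = 80, base_sd = 12) {
  set.seed(seed)
  lo <- coef$lower_limit
  hi <- coef$upper_limit
  demo <- data.frame(
    id = sprintf("C%05d", seq_len(n)),
    age_at_rand = rnorm(n, 64, 8), female = rbinom(n, 1, 0.35),
    ethnicity = sample(c("white", "black", "asian", "other"), n, TRUE,
                       prob = c(0.75, 0.05, 0.12, 0.08)),
    smoker_baseline = rbinom(n, 1, 0.12),
    stringsAsFactors = FALSE)
  dur0 <- pmax(rlnorm(n, log(16) - 0.125, 0.5), 1)
  egfr0 <- pmin(pmax(rnorm(n, base_mean, base_sd), lo), 200)
  sbp <- matrix(rnorm(n * (years + 1), 135, 14), n)
  eg <- matrix(NA_real_, n, years + 1)
  eg[, 1] <- egfr0
  for (t in 1:years) {
    mu <- coef$betas[["constant"]] +
      coef$betas[["age_at_rand"]] * demo$age_at_rand +
      coef$betas[["first:egfr"]] * egfr0 +
      coef$betas[["lag:egfr"]] * eg[, t] +
      coef$betas[["lag:sbp"]] * sbp[, t] +
      coef$betas[["ln_duration"]] * log(dur0 + t)
    latent <- mu + rnorm(n, 0, coef$sigma)
    eg[, t + 1] <- pmin(pmax(latent, lo), min(hi, 1e6))
  }
  rows <- lapply(0:years, function(y) {
    cbind(demo, data.frame(year = y, duration = dur0 + y,
                           egfr = eg[, y + 1], sbp = sbp[, y + 1]))
  })
  visits <- do.call(rbind, rows)
  visits <- visits[order(visits$id, visits$year), ]
  rownames(visits) <- NULL
  structure(list(visits = visits,
                 events = data.frame(id = character(),
                                     outcome = character(),
                                     entry = numeric(), exit = numeric(),
                                     event = integer()),
                 baseline = NULL, follow_up = years,
                 bundle_provenance = "censored tobit fixture"),
            class = "panel_dataset")
}

# simulate a dynamic-panel dataset directly from known phi (no egfr/events)
dynamic_panel_fixture <- function(n, years, coef, seed, base_mean = 7.5,
                                  base_sd = 1.2) {
  set.seed(seed)
  rf <- coef$risk_factor
  demo <- data.frame(
    id = sprintf("D%05d", seq_len(n)),
    age_at_rand = rnorm(n, 64, 8), female = rbinom(n, 1, 0.35),
    ethnicity = sample(c("white", "black", "asian", "other"), n, TRUE,
                       prob = c(0.75, 0.05, 0.12, 0.08)),
    smoker_baseline = rbinom(n, 1, 0.12),
    stringsAsFactors = FALSE)
  dur0 <- pmax(rlnorm(n, log(16) - 0.125, 0.5), 1)
  y0 <- rnorm(n, base_mean, base_sd)
  mu_i <- rnorm(n, 0, coef$re_sd)
  eth_term <- ifelse(demo$ethnicity == "white", coef$phi4_white,
              ifelse(demo$ethnicity == "black", coef$phi4_black,
              ifelse(demo$ethnicity == "asian", coef$phi4_asian, 0)))
  Y <- matrix(NA_real_, n, years + 1)
  Y[, 1] <- y0
  for (t in 1:years) {
    m <- coef$phi0 + coef$phi1 * Y[, t] + coef$phi2 * y0 +
      coef$phi3 * demo$female + eth_term +
      coef$phi5 * demo$age_at_rand + coef$phi6 * log(dur0 + t)
    Y[, t + 1] <- m + mu_i + rnorm(n, 0, coef$resid_sd)
  }
  rows <- lapply(0:years, function(y) {
    df <- cbind(demo, data.frame(year = y, duration = dur0 + y))
    df[[rf]] <- Y[, y + 1]
    df
  })
  visits <- do.call(rbind, rows)
  visits <- visits[order(visits$id, visits$year), ]
  rownames(visits) <- NULL
  structure(list(visits = visits,
                 events = data.frame(id = character(),
                                     outcome = character(),
                                     entry = numeric(), exit = numeric(),
                                     event = integer()),
                 baseline = NULL, follow_up = years,
                 bundle_provenance = "dynamic panel fixture"),
            class = "panel_dataset")
}

# left-truncated, censored survival sample with fixed covariates from a
# known PH model, generated by hand-coded inverse-transform sampling on the
# conditional survivor S(t | entry) -- independent of the package's hazard
# code
ph_sample <- function(n, betas, shape, distribution, seed,
                      covariate_gen = NULL,
                      entry_gen = function(n) runif(n, 0, 20),
                      follow_up = 6) {
  set.seed(seed)
  X <- if (is.null(covariate_gen)) {
    data.frame(x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
  } else {
    covariate_gen(n)
  }
  eta <- rep(betas[["constant"]], n)
  for (nm in setdiff(names(betas), "constant")) {
    eta <- eta + betas[[nm]] * X[[nm]]
  }
  Hfun <- switch(distribution,
    weibull = function(t) exp(eta) * t^exp(shape),
    exponential = function(t) exp(eta) * t,
    gompertz = function(t) if (abs(shape) < 1e-12) exp(eta) * t else
      exp(eta) * (exp(shape * t) - 1) / shape)
  Hinv <- switch(distribution,
    weibull = function(H) (H / exp(eta))^(1 / exp(shape)),
    exponential = function(H) H / exp(eta),
    gompertz = function(H) if (abs(shape) < 1e-12) H / exp(eta) else
      log(1 + shape * H / exp(eta)) / shape)
  entry <- entry_gen(n)
  target <- Hfun(entry) - log(runif(n))
  tt <- Hinv(target)
  cens <- entry + follow_up
  out <- data.frame(id = sprintf("T%06d", seq_len(n)), entry = entry,
                    exit = pmin(tt, cens),
                    event = as.integer(tt <= cens))
  cbind(out, X)
}
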