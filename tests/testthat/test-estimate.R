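test_that("a noiseless dynamic panel is recovered exactly", {
  truth <- dyn(phi0 = 2.945, phi1 = 0.456, phi2 = 0.243, phi3 = 0.031,
               phi4_white = -0.082, phi4_black = 0.065,
               phi4_asian = -0.091, phi5 = -0.012, phi6 = 0.083)
  pan <- dynamic_panel_fixture(400, years = 5, truth, seed = 61)
  fit <- fit_dynamic_panel(pan, "hba1c")
  cf <- fit$coefficients
  for (f in c("phi0", "phi1", "phi2", "phi3", "phi4_white", "phi4_black",
              "phi4_asian", "phi5", "phi6")) {
    expect_equal(cf[[f]], truth[[f]], tolerance = 1e-6)
  }
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("without a random effect the dynamic fitter agrees with an OLS
           oracle", {
  truth <- dyn(phi0 = 1, phi1 = 0.5, phi2 = 0.2, phi3 = 0.1, phi5 = -0.01,
               phi6 = 0.05, resid_sd = 0.4, re_sd = 0)
  pan <- dynamic_panel_fixture(800, years = 5, truth, seed = 62)
  fit <- fit_dynamic_panel(pan, "hba1c")
  df <- riskpath:::build_lag_frame(pan, "hba1c")
  ols <- lm(y ~ ylag + yfirst + female + eth_white + eth_black +
              eth_asian + age_at_rand + ln_duration, data = df)
  expect_equal(unname(fit$estimates),
               unname(coef(ols)), tolerance = 1e-4)
  expect_lt(fit$coefficients$re_sd, 0.02)
})

test_that("the fitted bundle round-trips to a usable coefficient file", {
  truth <- dyn("bmi", phi0 = 1.219, phi1 = 0.684, phi2 = 0.289,
               phi3 = 0.039, phi5 = -0.008, resid_sd = 0.3, re_sd = 0.2)
  pan <- dynamic_panel_fixture(500, years = 5, truth, seed = 63,
                               base_mean = 31, base_sd = 5)
  fit <- fit_dynamic_panel(pan, "bmi")
  b <- default_bundle()
  b$dynamic$bmi <- fit$coefficients
  b$provenance <- "refit"
  f <- withr::local_tempfile(fileext = ".json")
  save_bundle(b, f)
  b2 <- load_bundle(f)
  expect_identical(b2$dynamic$bmi$phi1, fit$coefficients$phi1)
  co <- generate_cohort(cohort_spec(n_patients = 10, seed = 1))
  tr <- simulate_cohort(b2, co, simulation_config(horizon = 3))
  expect_false(anyNA(tr$factors))
})

test_that("tobit likelihood reduces to OLS when censoring is inert and is
           invariant to sign reparameterization", {
  set.seed(71)
  n <- 2000
  X <- cbind(x1 = rnorm(n), x2 = runif(n))
  y <- 5 + 2 * X[, "x1"] - 1 * X[, "x2"] + rnorm(n, 0, 1.5)
  eng <- riskpath:::tobit_mle(y, X, lower = -Inf, upper = Inf)
  ols <- lm(y ~ X)
  expect_equal(unname(eng$estimates), unname(coef(ols)), tolerance = 1e-4)
  # flip the sign of covariates and coefficients: same likelihood
  eng2 <- riskpath:::tobit_mle(y, -X, lower = -Inf, upper = Inf)
  expect_equal(eng2$loglik, eng$loglik, tolerance = 1e-6)
  expect_equal(unname(eng2$estimates[-1]), -unname(eng$estimates[-1]),
               tolerance = 1e-4)
})

test_that("censored-normal recovery and the all-censored guard", {
  set.seed(72)
  n <- 4000
  X <- cbind(x1 = rnorm(n))
  latent <- 58 + 4 * X[, "x1"] + rnorm(n, 0, 6)
  y <- pmin(latent, 60)  # ~37% censored at the upper limit
  eng <- riskpath:::tobit_mle(y, X, lower = -Inf, upper = 60)
  expect_lt(abs(eng$estimates[["constant"]] - 58), 3 * eng$se[["constant"]])
  expect_lt(abs(eng$estimates[["x1"]] - 4), 3 * eng$se[["x1"]])
  expect_lt(abs(eng$sigma - 6), 3 * eng$sigma_se)
  expect_error(riskpath:::tobit_mle(rep(60, 50), X[1:50, , drop = FALSE],
                                    lower = -Inf, upper = 60),
               "censored")
})

test_that("tobit cross-checks against survreg on interval-censored data", {
  skip_if_not_installed("survival")
  set.seed(73)
  n <- 3000
  X <- data.frame(x1 = rnorm(n))
  latent <- 65 + 5 * X$x1 + rnorm(n, 0, 8)
  y <- pmax(pmin(latent, 80), 60)
  eng <- riskpath:::tobit_mle(y, as.matrix(X), lower = 60, upper = 80)
  # interval2 coding: NA lower = left-censored, NA upper = right-censored
  lower <- ifelse(y <= 60, NA, y)
  upper <- ifelse(y >= 80, NA, y)
  sr <- survival::survreg(
    survival::Surv(time = lower, time2 = upper, type = "interval2") ~ x1,
    data = X, dist = "gaussian")
  expect_equal(unname(eng$estimates), unname(coef(sr)), tolerance = 1e-3)
  expect_equal(unname(eng$sigma), sr$scale, tolerance = 1e-3)
})

test_that("weibull fit on exponential data shrinks the shape toward zero
           (nesting)", {
  fit_data <- ph_sample(5000, c(constant = -2.5, x1 = 0.4), shape = 0,
                        distribution = "exponential", seed = 81)
  fit <- ph_mle(fit_data, "x1", "weibull")
  expect_lt(abs(fit$shape), 3 * fit$shape_se)
  # exponential AIC should win on its own data more often than not
  fe <- ph_mle(fit_data, "x1", "exponential")
  expect_lt(fe$aic, fit$aic + 2.1)
})

test_that("the PH log-likelihood matches a quadrature oracle at the true
           parameters", {
  betas <- c(constant = -3.1, x1 = 0.5, x2 = -0.3)
  d <- ph_sample(200, betas, shape = 0.19, distribution = "weibull",
                 seed = 82)
  ll <- sum(riskpath:::ph_loglik_terms(
    c(-3.1, 0.5, -0.3, 0.19), d$entry, d$exit, d$event,
    cbind(1, d$x1, d$x2), "weibull"))
  oracle <- 0
  g <- exp(0.19)
  for (i in seq_len(nrow(d))) {
    eta <- -3.1 + 0.5 * d$x1[i] - 0.3 * d$x2[i]
    Hdiff <- oracle_cumhaz_weibull(eta, 0.19, d$exit[i]) -
      oracle_cumhaz_weibull(eta, 0.19, d$entry[i])
    oracle <- oracle - Hdiff +
      d$event[i] * (log(g) + (g - 1) * log(d$exit[i]) + eta)
  }
  expect_equal(ll, oracle, tolerance = 1e-6)
})

test_that("left-truncated weibull recovery and flexsurv cross-check", {
  betas <- c(constant = -4.2, x1 = 0.5, x2 = -0.3)
  d <- ph_sample(8000, betas, shape = log(1.21),
                 distribution = "weibull", seed = 83)
  expect_gt(mean(d$event == 0), 0.4)  # heavy censoring, as in trials
  fit <- ph_mle(d, c("x1", "x2"), "weibull")
  expect_lt(abs(fit$estimates[["constant"]] + 4.2),
            3 * fit$se[["constant"]])
  expect_lt(abs(fit$estimates[["x1"]] - 0.5), 3 * fit$se[["x1"]])
  expect_lt(abs(fit$estimates[["x2"]] + 0.3), 3 * fit$se[["x2"]])
  expect_lt(abs(fit$shape - log(1.21)), 3 * fit$shape_se)
  expect_error(ph_mle(d[d$event == 0, ], "x1", "weibull"), "events")
  skip_if_not_installed("flexsurv")
  fs <- flexsurv::flexsurvreg(
    survival::Surv(entry, exit, event) ~ x1 + x2, data = d,
    dist = "weibullPH")
  # flexsurv parameterizes h(t) = shape * scale * t^(shape-1) * exp(x'b)
  expect_equal(unname(fit$estimates[c("x1", "x2")]),
               unname(fs$res[c("x1", "x2"), "est"]), tolerance = 1e-3)
  expect_equal(exp(fit$shape), unname(fs$res["shape", "est"]),
               tolerance = 0.01)  # near-flat shape direction
  expect_gte(fit$loglik, fs$loglik - 0.01)
})

test_that("gompertz fits its own data and AIC separates the families", {
  betas <- c(constant = -4.5, x1 = 0.4)
  d <- ph_sample(8000, betas, shape = 0.08, distribution = "gompertz",
                 seed = 84)
  fg <- ph_mle(d, "x1", "gompertz")
  expect_lt(abs(fg$shape - 0.08), 3 * fg$shape_se)
  fw <- ph_mle(d, "x1", "weibull")
  expect_lt(fg$aic, fw$aic)
})

test_that("backwards stepwise keeps strong signals, returns the input
           model when everything is significant, and can empty the set", {
  betas <- c(constant = -3.5, x1 = 0.8, x2 = 0.5)
  d <- ph_sample(4000, betas, shape = 0.2, distribution = "weibull",
                 seed = 85)
  d$noise1 <- rnorm(4000)
  fitter <- function(panel, outcome, covariates) {
    ph_mle(panel, covariates, "weibull")
  }
  # both true covariates strongly significant: no removals
  fit <- backwards_stepwise(d, "AF", c("x1", "x2"), fitter = fitter)
  expect_identical(attr(fit, "selected"), c("x1", "x2"))
  expect_identical(nrow(attr(fit, "trace")), 0L)
  # noise covariate goes first, strong ones stay
  fit2 <- backwards_stepwise(d, "AF", c("x1", "x2", "noise1"),
                             fitter = fitter)
  expect_true(all(c("x1", "x2") %in% attr(fit2, "selected")))
  # constant-only end state is allowed
  d0 <- d
  d0$pure <- rnorm(4000)
  fit3 <- backwards_stepwise(d0, "AF", "pure", fitter = fitter,
                             alpha = 1e-12)
  expect_identical(attr(fit3, "selected"), character(0))
})

test_that("deterministic tie-break removes the later-declared covariate", {
  set.seed(86)
  d <- ph_sample(500, c(constant = -3), shape = 0,
                 distribution = "exponential", seed = 86)
  d$dup_a <- rnorm(500)
  d$dup_b <- d$dup_a  # identical columns: identical p-values
  fitter <- function(panel, outcome, covariates) {
    f <- ph_mle(panel, covariates, "exponential")
    # collinear columns: force equal p so the tie-break decides
    if (all(c("dup_a", "dup_b") %in% covariates)) {
      f$wald_p[c("dup_a", "dup_b")] <- 0.5
    }
    f
  }
  fit <- backwards_stepwise(d, "AF", c("dup_a", "dup_b"), fitter = fitter)
  expect_identical(attr(fit, "trace")$removed[1], "dup_b")
})

test_that("cox-snell residuals behave as unit exponentials under the
           fitted model", {
  betas <- c(constant = -3.6, x1 = 0.5)
  d <- ph_sample(8000, betas, shape = 0.2, distribution = "weibull",
                 seed = 87)
  fit <- ph_mle(d, "x1", "weibull")
  res <- cox_snell_residuals(fit, d)
  expect_true(all(res$residual >= 0))
  slope <- oracle_na_slope(res$residual, res$event)
  expect_gt(slope, 0.9)
  expect_lt(slope, 1.1)
  # zero-duration exposure gives a zero residual
  d0 <- d[1:2, ]
  d0$exit <- d0$entry + 1e-12
  r0 <- cox_snell_residuals(fit, d0)
  expect_equal(r0$residual, c(0, 0), tolerance = 1e-9)
})

test_that("optimizer sanity: fitted likelihood is at least the likelihood
           at the generating parameters", {
  betas <- c(constant = -3.8, x1 = 0.4)
  d <- ph_sample(3000, betas, shape = 0.15, distribution = "weibull",
                 seed = 88)
  fit <- ph_mle(d, "x1", "weibull")
  ll_truth <- sum(riskpath:::ph_loglik_terms(
    c(-3.8, 0.4, 0.15), d$entry, d$exit, d$event, cbind(1, d$x1),
    "weibull"))
  expect_gte(fit$loglik, ll_truth)
  expect_equal(fit$aic, 2 * 3 - 2 * fit$loglik)
})
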