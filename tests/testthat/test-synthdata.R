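test_that("cohort generation is reproducible and hits its anchors", {
  spec <- cohort_spec(n_patients = 2e4, seed = 123)
  co <- generate_cohort(spec)
  co2 <- generate_cohort(spec)
  expect_identical(co, co2)
  # mean age anchored at 64 (generator target)
  expect_lt(abs(mean(co$age_at_rand) - 64), 3 * 8 / sqrt(2e4))
  # lognormal duration with mean about 16 years
  expect_lt(abs(mean(co$duration) - 16), 0.5)
  expect_lt(abs(mean(co$female) - 0.35), 3 * sqrt(0.35 * 0.65 / 2e4))
  # egfr flag consistent with the drawn value
  expect_identical(co$egfr_lt60, co$egfr < 60)
  expect_true(all(co[, c("hdl", "ldl", "sbp", "hba1c")] > 0))
})

test_that("a zero-variance specification yields identical patients", {
  spec <- cohort_spec(n_patients = 8, seed = 2, age_sd = 0,
                      duration_sdlog = 0, prop_female = 0,
                      ethnicity_mix = c(white = 1, black = 0, asian = 0,
                                        other = 0),
                      prop_smoker = 0,
                      factor_sds = c(hdl = 0, ldl = 0, sbp = 0,
                                     hba1c = 0, haemoglobin = 0,
                                     heart_rate = 0, bmi = 0, egfr = 0),
                      prevalence = c(af = 0, alb = 0, pvd = 0))
  co <- generate_cohort(spec)
  for (cl in setdiff(names(co), "id")) {
    expect_length(unique(co[[cl]]), 1)
  }
})

test_that("an infeasible correlation matrix is repaired with a warning", {
  R <- diag(8)
  R[1, 2] <- R[2, 1] <- 0.9
  R[1, 3] <- R[3, 1] <- 0.9
  R[2, 3] <- R[3, 2] <- -0.9
  vars <- c("hdl", "ldl", "sbp", "hba1c", "haemoglobin", "heart_rate",
            "bmi", "egfr")
  dimnames(R) <- list(vars, vars)
  expect_warning(generate_cohort(cohort_spec(n_patients = 10, seed = 1,
                                             correlation = R)),
                 "positive definite")
})

test_that("a noiseless panel without dropout equals the deterministic
           trajectory", {
  b <- default_bundle()  # resid_sd = re_sd = 0: values are deterministic
  spec <- panel_spec(cohort_spec(n_patients = 30, seed = 44),
                     follow_up = 4, dropout = 0, bundle = b)
  pan <- generate_panel(spec)
  co <- generate_cohort(spec$cohort)
  tr <- simulate_cohort(b, co, simulation_config(horizon = 4))
  for (y in 1:4) {
    vy <- pan$visits[pan$visits$year == y, ]
    vy <- vy[order(vy$id), ]
    expect_equal(vy$hba1c, tr$factors[, "hba1c", y])
    expect_equal(vy$sbp, tr$factors[, "sbp", y])
  }
  v0 <- pan$visits[pan$visits$year == 0, ]
  expect_equal(v0$bmi[order(v0$id)], co$bmi)
})

test_that("dropout thins follow-up at the configured geometric rate", {
  spec <- panel_spec(cohort_spec(n_patients = 1e4, seed = 9),
                     follow_up = 6, dropout = 0.1)
  pan <- generate_panel(spec)
  retained <- sum(pan$visits$year == 6) / sum(pan$visits$year == 0)
  # a patient reaches the year-6 visit after surviving 6 dropout draws
  want <- 0.9^6
  se <- sqrt(want * (1 - want) / 1e4)
  expect_lt(abs(retained - want), 3 * se)
})

test_that("generated event times respect the generating survivor
           (Kolmogorov-Smirnov)", {
  # fixed covariates: one-patient design replicated, no censoring beyond
  # the administrative horizon
  cf <- survival_coefficients("PVD", betas = c(constant = -2.8),
                              ln_gamma = 0.3)
  st <- make_state(n = 1e4, duration = 12)
  set.seed(77)
  tims <- simulate_event_times(cf, st, censor_after = Inf)
  g <- exp(0.3)
  # conditional CDF given entry at 12
  cdf <- function(t) 1 - exp(exp(-2.8) * (12^g - t^g))
  ks <- stats::ks.test(tims$exit, cdf)
  expect_gt(ks$p.value, 0.01)
})

test_that("missingness and measurement noise act per variable", {
  spec <- panel_spec(cohort_spec(n_patients = 2000, seed = 3),
                     follow_up = 3, dropout = 0,
                     noise_sd = list(hba1c = 0.3),
                     missing_rate = list(sbp = 0.25))
  pan <- generate_panel(spec)
  post <- pan$visits[pan$visits$year > 0, ]
  expect_lt(abs(mean(is.na(post$sbp)) - 0.25), 0.03)
  expect_false(anyNA(post$hba1c))
  # noise is centred: annual means agree with the noiseless panel
  spec0 <- panel_spec(cohort_spec(n_patients = 2000, seed = 3),
                      follow_up = 3, dropout = 0)
  pan0 <- generate_panel(spec0)
  m1 <- mean(pan$visits$hba1c[pan$visits$year == 2])
  m0 <- mean(pan0$visits$hba1c[pan0$visits$year == 2])
  expect_lt(abs(m1 - m0), 3 * 0.3 / sqrt(2000))
})

test_that("raw preprocessing drops early/implausible measurements,
           averages within year and logs exclusions", {
  demo <- data.frame(id = c("A", "B", "C", "D"), age_at_rand = 64,
                     female = 0,
                     ethnicity = c("white", "white", NA, "white"),
                     smoker_baseline = 0, duration = 10,
                     stringsAsFactors = FALSE)
  raw <- rbind(
    # A: baseline + two in-year-1 values averaging to 7.2, one early value
    data.frame(id = "A", month = c(0, 3, 7, 11), variable = "hba1c",
               value = c(7.0, 9.9, 7.0, 7.4)),
    # A: an out-of-range value in year 2
    data.frame(id = "A", month = 20, variable = "hba1c", value = 25),
    # B: baseline only for hba1c -> excluded from the hba1c panel
    data.frame(id = "B", month = 0, variable = "hba1c", value = 8),
    data.frame(id = "B", month = c(0, 8), variable = "sbp",
               value = c(140, 138)),
    # C: missing ethnicity -> excluded globally
    data.frame(id = "C", month = c(0, 9), variable = "hba1c",
               value = c(7, 7)),
    # D: withdrew on the randomisation day
    data.frame(id = "D", month = 0, variable = "sbp", value = 150))
  out <- preprocess_panel(raw, demo)
  log <- attr(out, "exclusion_log")
  expect_identical(log$dropped_lt6_months, 1L)     # A's month-3 value
  expect_identical(log$dropped_out_of_range, 1L)   # A's 25% hba1c
  expect_identical(log$excluded_missing_ethnicity, 1L)
  expect_identical(log$excluded_withdrawal_day0, 1L)
  expect_identical(log$excluded_no_followup, 1L)   # B for hba1c
  v <- out$visits
  expect_false(any(v$id %in% c("C", "D")))
  expect_equal(v$hba1c[v$id == "A" & v$year == 1], 7.2)
  expect_equal(v$sbp[v$id == "B" & v$year == 1], 138)
  expect_true(is.na(v$hba1c[v$id == "B" & v$year == 1]))
})

test_that("preprocessing an already-clean annualized stream is the
           identity (idempotence)", {
  demo <- data.frame(id = c("A", "B"), age_at_rand = c(60, 70),
                     female = c(0, 1), ethnicity = "white",
                     smoker_baseline = 0, duration = c(8, 12),
                     stringsAsFactors = FALSE)
  clean <- expand.grid(id = c("A", "B"), year = 0:3,
                       variable = c("hba1c", "sbp"),
                       stringsAsFactors = FALSE)
  set.seed(5)
  clean$value <- ifelse(clean$variable == "hba1c", 7.5, 135) + rnorm(16)
  clean$month <- clean$year * 12
  out1 <- preprocess_panel(clean, demo)
  # re-export the annualized output as a raw stream and process again
  back <- reshape(out1$visits[, c("id", "year", "hba1c", "sbp")],
                  idvar = c("id", "year"),
                  varying = c("hba1c", "sbp"), v.names = "value",
                  times = c("hba1c", "sbp"), timevar = "variable",
                  direction = "long")
  back$month <- back$year * 12
  out2 <- preprocess_panel(back, demo)
  for (v in c("hba1c", "sbp")) {
    expect_equal(out2$visits[[v]], out1$visits[[v]])
  }
})
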