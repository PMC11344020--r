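# bundle with realistic process noise on the continuous equations, so that
# validation checks are non-degenerate
noisy_bundle <- function() {
  b <- default_bundle()
  sds <- c(hdl = 0.15, ldl = 0.4, sbp = 9, hba1c = 0.5, haemoglobin = 0.7,
           heart_rate = 6, bmi = 0.6)
  res <- c(hdl = 0.1, ldl = 0.25, sbp = 6, hba1c = 0.3, haemoglobin = 0.5,
           heart_rate = 4, bmi = 0.4)
  for (rf in names(sds)) {
    b$dynamic[[rf]]$resid_sd <- sds[[rf]]
    b$dynamic[[rf]]$re_sd <- res[[rf]]
  }
  b
}

test_that("the product-limit estimate matches a hand-coded oracle on a
           worked dataset", {
  time <- c(1, 2, 2, 3, 4, 4, 5, 6, 7, 8)
  event <- c(1, 1, 0, 1, 1, 0, 1, 0, 1, 0)
  want <- oracle_km(time, event)
  got <- survival::survfit(survival::Surv(time, event) ~ 1)
  gs <- summary(got, times = want$time)
  expect_equal(gs$surv, want$surv, tolerance = 1e-12)
  # with no censoring the estimator is one minus the empirical CDF
  t2 <- c(2, 4, 4, 5, 9)
  k2 <- survival::survfit(survival::Surv(t2, rep(1, 5)) ~ 1)
  expect_equal(summary(k2, times = sort(unique(t2)))$surv,
               1 - ecdf(t2)(sort(unique(t2))), tolerance = 1e-12)
})

test_that("time-path agreement is perfect when validating the generating
           bundle without noise", {
  b <- default_bundle()
  pan <- generate_panel(panel_spec(cohort_spec(n_patients = 500, seed = 31),
                                   follow_up = 5, dropout = 0, bundle = b))
  cmp <- suppressWarnings(timepath_agreement(pan, b, "hba1c"))
  expect_true(all(cmp$covered))
  expect_equal(cmp$predicted_mean, cmp$observed_mean, tolerance = 1e-9)
  expect_true(all(diff(cmp$duration) > 0))
  expect_true(all(cmp$ci_lower <= cmp$observed_mean &
                    cmp$observed_mean <= cmp$ci_upper))
})

test_that("a deliberately biased bundle is flagged by zero coverage", {
  b <- noisy_bundle()
  pan <- generate_panel(panel_spec(cohort_spec(n_patients = 2000,
                                               seed = 32),
                                   follow_up = 5, dropout = 0, bundle = b))
  bad <- b
  bad$dynamic$hba1c$phi0 <- bad$dynamic$hba1c$phi0 + 2.5  # +5 sigma shift
  cmp <- suppressWarnings(
    timepath_agreement(pan, bad, "hba1c", min_bin_n = 50))
  expect_equal(mean(cmp$covered), 0)
})

test_that("time-path coverage under realistic noise is near-complete", {
  b <- noisy_bundle()
  pan <- generate_panel(panel_spec(cohort_spec(n_patients = 5000,
                                               seed = 33),
                                   follow_up = 6, dropout = 0.03,
                                   bundle = b))
  for (rf in c("hba1c", "sbp", "bmi")) {
    cmp <- suppressWarnings(
      timepath_agreement(pan, b, rf, min_bin_n = 100))
    expect_gte(mean(cmp$covered), 0.9)
  }
})

test_that("simulated-lag (re-fed) predictions drift but stay on the
           observed scale", {
  b <- noisy_bundle()
  pan <- generate_panel(panel_spec(cohort_spec(n_patients = 2000,
                                               seed = 34),
                                   follow_up = 5, dropout = 0, bundle = b))
  cmp <- suppressWarnings(
    timepath_agreement(pan, b, "hba1c", lag_source = "simulated",
                       min_bin_n = 100))
  expect_lt(max(abs(cmp$predicted_mean - cmp$observed_mean)), 0.4)
})

test_that("quintile strata are balanced, ordered and each validated", {
  b <- noisy_bundle()
  pan <- generate_panel(panel_spec(cohort_spec(n_patients = 1000,
                                               seed = 35),
                                   follow_up = 4, dropout = 0, bundle = b))
  qs <- suppressWarnings(quintile_agreement(pan, b, "hba1c",
                                            min_bin_n = 20))
  expect_named(qs, paste0("Q", 1:5))
  sizes <- vapply(qs, attr, integer(1), "n_patients")
  expect_lte(max(sizes) - min(sizes), 1L)
  # monotone relation between first value and later mean across strata
  year3 <- vapply(qs, function(q) {
    mean(q$observed_mean)
  }, numeric(1))
  expect_true(all(diff(year3) > 0))
})

test_that("a homogeneous cohort cannot be split into quintiles", {
  b <- default_bundle()
  spec <- cohort_spec(n_patients = 50, seed = 2, age_sd = 0,
                      duration_sdlog = 0, prop_female = 0,
                      ethnicity_mix = c(white = 1, black = 0, asian = 0,
                                        other = 0), prop_smoker = 0,
                      factor_sds = c(hdl = 0, ldl = 0, sbp = 0, hba1c = 0,
                                     haemoglobin = 0, heart_rate = 0,
                                     bmi = 0, egfr = 0),
                      prevalence = c(af = 0, alb = 0, pvd = 0))
  pan <- generate_panel(panel_spec(spec, follow_up = 3, dropout = 0,
                                   bundle = b))
  expect_error(quintile_agreement(pan, b, "hba1c"), "distinct")
})

test_that("km_vs_simulated is self-consistent on data from the same
           bundle", {
  b <- default_bundle()
  pan <- generate_panel(panel_spec(cohort_spec(n_patients = 4000,
                                               seed = 36),
                                   follow_up = 6, dropout = 0.03,
                                   bundle = b))
  for (o in c("AF", "ALB")) {
    cmp <- km_vs_simulated(pan, b, o, min_risk = 300)
    expect_true(all(diff(cmp$simulated_ci) >= 0))
    expect_true(all(cmp$observed_ci >= 0 & cmp$observed_ci <= 1))
    inside <- cmp$simulated_ci >= cmp$ci_lower &
      cmp$simulated_ci <= cmp$ci_upper
    expect_gte(mean(inside), 0.85)
  }
})

test_that("a halved-hazard comparator falls below the observed curve", {
  b <- default_bundle()
  pan <- generate_panel(panel_spec(cohort_spec(n_patients = 4000,
                                               seed = 37),
                                   follow_up = 6, dropout = 0, bundle = b))
  weak <- b
  weak$survival$ALB$betas[["constant"]] <-
    weak$survival$ALB$betas[["constant"]] - log(2)
  cmp <- km_vs_simulated(pan, weak, "ALB", min_risk = 300)
  tail_cmp <- cmp[cmp$duration >= stats::median(cmp$duration), ]
  expect_true(all(tail_cmp$simulated_ci < tail_cmp$observed_ci))
})

test_that("an outcome without events degenerates with a warning", {
  b <- default_bundle()
  pan <- generate_panel(panel_spec(cohort_spec(n_patients = 300, seed = 38),
                                   follow_up = 3, dropout = 0, bundle = b))
  pan$events$event[pan$events$outcome == "PVD"] <- 0L
  expect_warning(km_vs_simulated(pan, b, "PVD", min_risk = 50),
                 "degenerate")
})
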