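#' Specification of a synthetic baseline cohort
#'
#' Defaults emulate a pooled contemporary cardiovascular-outcome-trial
#' population with long-standing type 2 diabetes: mean age 64 (sd 8) years
#' at randomisation, lognormal diabetes duration with mean about 16 years,
#' about a third female, majority white with asian/black/other minorities,
#' and clinically plausible baseline risk-factor levels. The risk-factor
#' means, SDs and correlations are generator choices, not estimates from
#' any trial's baseline table, and every one of them can be overridden.
#'
#' @param n_patients cohort size.
#' @param seed integer seed; generation is fully reproducible from it.
#' @param age_mean,age_sd age at randomisation, years.
#' @param duration_meanlog,duration_sdlog lognormal parameters of diabetes
#'   duration (defaults give mean about 16 years).
#' @param prop_female proportion female.
#' @param ethnicity_mix named proportions over
#'   \code{white, black, asian, other}; must sum to 1.
#' @param prop_smoker baseline smoking prevalence.
#' @param factor_means,factor_sds named baseline means/SDs for the seven
#'   risk factors and \code{egfr}.
#' @param correlation baseline correlation matrix across those eight
#'   variables (repaired to the nearest positive-definite matrix with a
#'   warning if infeasible).
#' @param prevalence named baseline prevalence of \code{af}, \code{alb},
#'   \code{pvd}; the \code{egfr_lt60} flag follows from the drawn eGFR.
#' @return a \code{cohort_spec} list.
#' @export
cohort_spec <- function(n_patients, seed = 1L, age_mean = 64, age_sd = 8,
                        duration_meanlog = log(16) - 0.125,
                        duration_sdlog = 0.5,
                        prop_female = 0.35,
                        ethnicity_mix = c(white = 0.75, black = 0.05,
                                          asian = 0.12, other = 0.08),
                        prop_smoker = 0.12,
                        factor_means = c(hdl = 1.1, ldl = 2.2, sbp = 135,
                                         hba1c = 7.5, haemoglobin = 13.8,
                                         heart_rate = 72, bmi = 31,
                                         egfr = 75),
                        factor_sds = c(hdl = 0.3, ldl = 0.9, sbp = 16,
                                       hba1c = 1.2, haemoglobin = 1.6,
                                       heart_rate = 11, bmi = 5.5,
                                       egfr = 20),
                        correlation = NULL,
                        prevalence = c(af = 0.05, alb = 0.12, pvd = 0.04)) {
  vars <- c(RISK_FACTORS, "egfr")
  if (abs(sum(ethnicity_mix) - 1) > 1e-8 || any(ethnicity_mix < 0)) {
    stop("ethnicity_mix proportions must be >= 0 and sum to 1",
         call. = FALSE)
  }
  if (any(factor_sds < 0)) stop("factor_sds must be >= 0", call. = FALSE)
  if (is.null(correlation)) {
    correlation <- diag(length(vars))
    dimnames(correlation) <- list(vars, vars)
    set_cor <- function(a, b, r) {
      correlation[a, b] <<- r
      correlation[b, a] <<- r
    }
    set_cor("hdl", "bmi", -0.2)
    set_cor("hdl", "ldl", 0.1)
    set_cor("sbp", "bmi", 0.15)
    set_cor("hba1c", "bmi", 0.1)
  }
  structure(list(n_patients = as.integer(n_patients),
                 seed = as.integer(seed),
                 age_mean = age_mean, age_sd = age_sd,
                 duration_meanlog = duration_meanlog,
                 duration_sdlog = duration_sdlog,
                 prop_female = prop_female, ethnicity_mix = ethnicity_mix,
                 prop_smoker = prop_smoker, factor_means = factor_means,
                 factor_sds = factor_sds, correlation = correlation,
                 prevalence = prevalence),
            class = "cohort_spec")
}

# physiologically sensible floors keeping drawn values positive
BASELINE_FLOORS <- c(hdl = 0.3, ldl = 0.3, sbp = 70, hba1c = 4,
                     haemoglobin = 6, heart_rate = 40, bmi = 15, egfr = 5)

#' Generate a synthetic baseline cohort
#'
#' Draws a cohort table from a [cohort_spec()]: correlated Gaussian baseline
#' risk factors (floored at physiological minima), lognormal diabetes
#' duration, and Bernoulli demographics and baseline condition flags.
#' Baseline values double as the first-recorded values.
#'
#' @param spec a [cohort_spec()].
#' @return a cohort table (see [as_cohort()]).
#' @export
#' @examples
#' co <- generate_cohort(cohort_spec(n_patients = 100, seed = 7))
#' mean(co$age_at_rand)
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(derive_seed(spec$seed, "cohort"))
  n <- spec$n_patients
  vars <- c(RISK_FACTORS, "egfr")
  R <- spec$correlation[vars, vars]
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) {
    warning("correlation matrix not positive definite; ",
            "repaired to the nearest PD matrix")
    R <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
  }
  D <- diag(spec$factor_sds[vars], length(vars))
  X <- MASS::mvrnorm(n, mu = spec$factor_means[vars], Sigma = D %*% R %*% D)
  X <- matrix(pmax(X, rep(BASELINE_FLOORS[vars], each = n)), n,
              dimnames = list(NULL, vars))
  co <- data.frame(
    id = sprintf("P%06d", seq_len(n)),
    age_at_rand = stats::rnorm(n, spec$age_mean, spec$age_sd),
    female = as.numeric(stats::runif(n) < spec$prop_female),
    ethnicity = sample(names(spec$ethnicity_mix), n, replace = TRUE,
                       prob = spec$ethnicity_mix),
    smoker_baseline = as.numeric(stats::runif(n) < spec$prop_smoker),
    duration = stats::rlnorm(n, spec$duration_meanlog, spec$duration_sdlog),
    stringsAsFactors = FALSE)
  co$duration <- pmax(co$duration, 1)
  for (v in vars) co[[v]] <- X[, v]
  co$af <- stats::runif(n) < spec$prevalence[["af"]]
  co$alb <- stats::runif(n) < spec$prevalence[["alb"]]
  co$pvd <- stats::runif(n) < spec$prevalence[["pvd"]]
  as_cohort(co)
}

#' Specification of a synthetic longitudinal panel
#'
#' A [cohort_spec()] plus follow-up structure and a generating coefficient
#' bundle. The generated panel mimics annualized trial data: yearly
#' measurements over a limited follow-up with non-informative dropout,
#' optional measurement noise and missingness, and condition onset/censoring
#' times on the diabetes-duration scale with entry truncation.
#'
#' @param cohort a [cohort_spec()].
#' @param follow_up years of scheduled follow-up (>= 2 so lags exist).
#' @param dropout annual probability of permanent dropout, in \code{[0, 1)}.
#' @param noise_sd named vector of measurement-noise SDs per variable
#'   (default: none — the process noise in the bundle is the only
#'   stochasticity).
#' @param missing_rate named vector of per-measurement missingness rates.
#' @param bundle the generating [coefficient_bundle()].
#' @return a \code{panel_spec} list.
#' @export
panel_spec <- function(cohort, follow_up = 6, dropout = 0.03,
                       noise_sd = NULL, missing_rate = NULL,
                       bundle = default_bundle()) {
  stopifnot(inherits(cohort, "cohort_spec"))
  if (follow_up < 2) stop("follow_up must be >= 2 (lag construction)",
                          call. = FALSE)
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)",
                                        call. = FALSE)
  structure(list(cohort = cohort, follow_up = as.integer(follow_up),
                 dropout = dropout, noise_sd = noise_sd,
                 missing_rate = missing_rate, bundle = bundle),
            class = "panel_spec")
}

# invert the within-year conditional event-time distribution: given onset in
# (t, t+1] with start-of-year covariates, H(s) = H(t) - log(1 - v * p)
invert_event_time <- function(coef, eta, t, p, v) {
  H0 <- cumulative_hazard(coef, eta, t)
  invert_cumhaz(coef, eta, H0 - log1p(-v * p))
}

#' Generate a synthetic longitudinal panel
#'
#' Simulates each patient forward with the trajectory/event/eGFR engines in
#' stochastic mode, then applies the observation process: yearly visit
#' records up to dropout, measurement noise and missingness, and
#' onset/censoring times for the four absorbing conditions on the
#' diabetes-duration scale (entry = duration at randomisation; onset times
#' placed continuously within the onset year by inverting the within-year
#' conditional distribution).
#'
#' @param spec a [panel_spec()].
#' @return a \code{panel_dataset}: list with \code{visits} (one row per
#'   patient-year: demographics, duration, measured values), \code{events}
#'   (one row per patient and outcome at risk at entry: \code{entry},
#'   \code{exit}, \code{event}), and \code{baseline} (the generating cohort
#'   table).
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  co <- generate_cohort(spec$cohort)
  n <- nrow(co)
  H <- spec$follow_up
  cfg <- simulation_config(horizon = H, mode = "stochastic",
                           seed = derive_seed(spec$cohort$seed, "panel"))
  tr <- simulate_cohort(spec$bundle, co, cfg)

  set.seed(derive_seed(spec$cohort$seed, "observation"))
  # dropout: last observed visit year (0 = baseline only)
  last_year <- rep(H, n)
  if (spec$dropout > 0) {
    drop_draws <- matrix(stats::runif(n * H) < spec$dropout, n, H)
    for (i in seq_len(n)) {
      w <- which(drop_draws[i, ])
      if (length(w)) last_year[i] <- w[1L] - 1L
    }
  }

  vars <- c(RISK_FACTORS, "egfr")
  visit_rows <- vector("list", H + 1L)
  demo <- co[, c("id", "age_at_rand", "female", "ethnicity",
                 "smoker_baseline")]
  for (y in 0:H) {
    keep <- last_year >= y
    if (!any(keep)) next
    vals <- if (y == 0) as.matrix(co[keep, vars]) else
      cbind(matrix(tr$factors[keep, , y], sum(keep), 7L,
                   dimnames = list(NULL, RISK_FACTORS)),
            egfr = tr$egfr[keep, y])
    for (v in vars) {
      nsd <- spec$noise_sd[[v]] %||% 0
      if (nsd > 0) vals[, v] <- vals[, v] + stats::rnorm(sum(keep), 0, nsd)
      mr <- spec$missing_rate[[v]] %||% 0
      if (mr > 0) vals[stats::runif(sum(keep)) < mr, v] <- NA
    }
    visit_rows[[y + 1L]] <- cbind(
      demo[keep, , drop = FALSE],
      data.frame(year = y, duration = co$duration[keep] + y),
      as.data.frame(vals))
  }
  visits <- do.call(rbind, visit_rows)
  visits <- visits[order(visits$id, visits$year), , drop = FALSE]
  rownames(visits) <- NULL

  # condition onset / censoring on the duration scale with entry truncation
  ev_rows <- list()
  for (o in OUTCOMES) {
    coef <- spec$bundle$survival[[o]]
    fc <- flag_column(o)
    at_risk <- !co[[fc]]
    flags_o <- matrix(tr$flags[, o, ], n, H)
    onset_year <- apply(flags_o, 1L, function(f) {
      w <- which(f)
      if (length(w)) w[1L] else NA_integer_
    })
    censor_t <- co$duration + pmax(last_year, 0)
    exit <- censor_t
    event <- rep(0L, n)
    has <- at_risk & !is.na(onset_year) & onset_year <= last_year
    if (any(has)) {
      for (i in which(has)) {
        y <- onset_year[i]
        # start-of-onset-year state: lagged covariates from year y-1
        st <- co[i, , drop = FALSE]
        if (y > 1L) {
          for (k in seq_along(RISK_FACTORS)) {
            st[[RISK_FACTORS[k]]] <- tr$factors[i, k, y - 1L]
          }
          st$egfr <- tr$egfr[i, y - 1L]
          st$duration <- co$duration[i] + (y - 1L)
        }
        eta <- linear_predictor(coef$betas, st)
        p <- tr$probabilities[i, o, y]
        tt <- invert_event_time(coef, eta, st$duration, p,
                                stats::runif(1L))
        exit[i] <- tt
        event[i] <- 1L
      }
    }
    keep <- at_risk & exit > co$duration
    ev_rows[[o]] <- data.frame(
      id = co$id[keep], outcome = o, entry = co$duration[keep],
      exit = exit[keep], event = event[keep], stringsAsFactors = FALSE)
  }
  events <- do.call(rbind, ev_rows)
  rownames(events) <- NULL

  structure(list(visits = visits, events = events, baseline = co,
                 follow_up = H, bundle_provenance = spec$bundle$provenance),
            class = "panel_dataset")
}

#' Read and write panel datasets as delimited text
#'
#' A panel is stored as two tab-separated files, \code{<prefix>_visits.tsv}
#' and \code{<prefix>_events.tsv}.
#'
#' @param panel a \code{panel_dataset}.
#' @param prefix file path prefix.
#' @return [write_panel()]: \code{prefix}, invisibly; [read_panel()]: a
#'   \code{panel_dataset}.
#' @export
write_panel <- function(panel, prefix) {
  utils::write.table(panel$visits, paste0(prefix, "_visits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(panel$events, paste0(prefix, "_events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_panel
#' @export
read_panel <- function(prefix) {
  visits <- utils::read.table(paste0(prefix, "_visits.tsv"), header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE)
  ef <- paste0(prefix, "_events.tsv")
  events <- if (file.exists(ef)) {
    utils::read.table(ef, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  } else {
    data.frame(id = character(), outcome = character(), entry = numeric(),
               exit = numeric(), event = integer())
  }
  structure(list(visits = visits, events = events, baseline = NULL,
                 follow_up = max(visits$year), bundle_provenance = ""),
            class = "panel_dataset")
}

#' @export
print.panel_dataset <- function(x, ...) {
  cat("<panel_dataset> ", length(unique(x$visits$id)), " patients, ",
      nrow(x$visits), " patient-year visit rows, ",
      nrow(x$events), " at-risk event records\n", sep = "")
  invisible(x)
}
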