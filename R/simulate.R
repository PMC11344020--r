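#' Simulation configuration
#'
#' @param horizon number of annual cycles, 1-70.
#' @param mode \code{"deterministic"} (expected values everywhere, event
#'   probabilities recorded but never binarized) or \code{"stochastic"}
#'   (Monte-Carlo event binarization plus value noise).
#' @param seed integer seed; every random draw in the run derives from it
#'   through fixed per-patient substreams, so results are reproducible and
#'   permuting the cohort permutes output rows only.
#' @param intervention optional named numeric vector of additive shifts
#'   (e.g. \code{c(hba1c = -0.5, sbp = -10)}) applied once to the cycle-1
#'   values and to the first-recorded store — the conventional way a
#'   first-year treatment effect enters before the background time-path
#'   equations take over.
#' @param value_draws in stochastic mode, draw the continuous-factor
#'   residuals and the truncated-normal eGFR values (\code{TRUE}, default)
#'   or keep the value channels at their expected paths so that only the
#'   probability-to-event conversion is stochastic (\code{FALSE}).
#' @param first_source after cycle 1, keep the first-recorded store at the
#'   baseline values (\code{"baseline"}, default) or reset it to the
#'   realized year-1 values (\code{"year1"}).
#' @param clamp optional named list of \code{c(lower, upper)} physiological
#'   ranges applied to continuous predictions.
#' @param egfr_cap physiological cap on the at/above-60 eGFR regime.
#' @return a \code{simulation_config} list.
#' @export
simulation_config <- function(horizon, mode = c("deterministic",
                                                "stochastic"),
                              seed = 1L, intervention = NULL,
                              value_draws = TRUE,
                              first_source = c("baseline", "year1"),
                              clamp = NULL, egfr_cap = 200) {
  mode <- match.arg(mode)
  first_source <- match.arg(first_source)
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon < 1 ||
      horizon > 70) {
    stop("horizon must be a single integer in 1..70", call. = FALSE)
  }
  if (!is.null(intervention)) {
    bad <- setdiff(names(intervention), RISK_FACTORS)
    if (length(bad)) {
      stop("intervention names must be risk factors; unknown: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(horizon = as.integer(horizon), mode = mode,
                 seed = as.integer(seed), intervention = intervention,
                 value_draws = isTRUE(value_draws),
                 first_source = first_source, clamp = clamp,
                 egfr_cap = egfr_cap),
            class = "simulation_config")
}

# pre-generate all random draws, one substream per patient with a fixed
# block layout (random effects, then event uniforms per outcome, then
# factor residuals per factor, then eGFR value uniforms)
generate_draws <- function(ids, seed, horizon) {
  n <- length(ids)
  H <- horizon
  MU <- matrix(0, n, 7L)
  U_ev <- array(0, c(n, 4L, H))
  Z <- array(0, c(n, 7L, H))
  U_eg <- matrix(0, n, H)
  for (i in seq_len(n)) {
    set.seed(derive_seed(seed, ids[i]))
    MU[i, ] <- stats::rnorm(7L)
    for (j in 1:4) U_ev[i, j, ] <- stats::runif(H)
    for (k in 1:7) Z[i, k, ] <- stats::rnorm(H)
    U_eg[i, ] <- stats::runif(H)
  }
  list(MU = MU, U_ev = U_ev, Z = Z, U_eg = U_eg)
}

#' Simulate a cohort over an annual-cycle horizon
#'
#' Runs the full annual cycle for every patient: each year (1) the four
#' absorbing condition equations are evaluated on last year's risk-factor
#' values and, in stochastic mode, flags are flipped by Monte-Carlo draws;
#' (2) the seven continuous factors are advanced by their dynamic equations;
#' (3) eGFR is advanced by the two-part Tobit engine matching the (possibly
#' newly crossed) regime. Trajectories are conditional on survival — no
#' mortality is modelled, so every patient contributes exactly
#' \code{horizon} records.
#'
#' @param bundle a complete [coefficient_bundle()].
#' @param cohort a cohort table ([as_cohort()]).
#' @param config a [simulation_config()].
#' @return an object of class \code{cohort_trajectory}: per-year arrays of
#'   factor values, eGFR, condition flags and annual event probabilities,
#'   with [as.data.frame.cohort_trajectory()] giving the long-format
#'   (patient, year, variable, value) view.
#' @export
#' @examples
#' b <- default_bundle()
#' co <- generate_cohort(cohort_spec(n_patients = 5, seed = 1))
#' tr <- simulate_cohort(b, co, simulation_config(horizon = 3))
#' head(as.data.frame(tr))
simulate_cohort <- function(bundle, cohort, config) {
  stopifnot(inherits(config, "simulation_config"))
  validate_coefficient_bundle(bundle, require_complete = TRUE)
  cohort <- as_cohort(cohort)
  check_complete_for_simulation(cohort)
  n <- nrow(cohort)
  H <- config$horizon
  stoch <- config$mode == "stochastic"
  ev_mode <- if (stoch) "stochastic" else "expected"
  val_mode <- if (stoch && config$value_draws) "stochastic" else
    "deterministic"

  draws <- if (stoch) generate_draws(cohort$id, config$seed, H) else NULL
  re_sd <- vapply(bundle$dynamic[RISK_FACTORS], `[[`, numeric(1), "re_sd")
  mu <- if (stoch && val_mode == "stochastic") {
    sweep(draws$MU, 2L, re_sd, `*`)
  } else {
    matrix(0, n, 7L)
  }

  factors <- array(NA_real_, c(n, 7L, H),
                   dimnames = list(NULL, RISK_FACTORS, NULL))
  egfr <- matrix(NA_real_, n, H)
  flags <- array(NA, c(n, 4L, H), dimnames = list(NULL, OUTCOMES, NULL))
  probs <- array(NA_real_, c(n, 4L, H),
                 dimnames = list(NULL, OUTCOMES, NULL))

  state <- cohort
  for (y in seq_len(H)) {
    upd <- update_flags(bundle, state, mode = ev_mode,
                        u = if (stoch) {
                          matrix(draws$U_ev[, , y], nrow = n, ncol = 4L)
                        } else NULL)
    state_f <- upd$state
    # eGFR first (it needs last year's SBP), continuous update after; both
    # are functions of the incoming state only, so order does not matter
    eg <- advance_egfr(bundle, state_f, mode = val_mode,
                       run_crossing = FALSE,
                       u_value = if (stoch) draws$U_eg[, y] else NULL,
                       upper_cap = config$egfr_cap)
    state <- advance_continuous(bundle, state_f, mode = val_mode,
                                mu = mu,
                                eps = if (stoch) {
                                  matrix(draws$Z[, , y], nrow = n, ncol = 7L)
                                } else NULL,
                                clamp = config$clamp)
    eg_state <- attr(eg, "state")
    state$egfr <- eg_state$egfr
    state$egfr_lt60 <- eg_state$egfr_lt60
    if (y == 1L && !is.null(config$intervention)) {
      for (rf in names(config$intervention)) {
        d <- config$intervention[[rf]]
        state[[rf]] <- state[[rf]] + d
        state[[paste0("first_", rf)]] <-
          state[[paste0("first_", rf)]] + d
      }
    }
    if (y == 1L && config$first_source == "year1") {
      for (rf in RISK_FACTORS) state[[paste0("first_", rf)]] <- state[[rf]]
      state$first_egfr <- state$egfr
    }
    factors[, , y] <- as.matrix(state[, RISK_FACTORS])
    egfr[, y] <- state$egfr
    flags[, , y] <- as.matrix(state[, flag_column(OUTCOMES)])
    probs[, , y] <- upd$probabilities
  }

  structure(list(ids = cohort$id, duration0 = cohort$duration,
                 factors = factors, egfr = egfr, flags = flags,
                 probabilities = probs, config = config,
                 provenance = bundle$provenance,
                 final_state = state),
            class = "cohort_trajectory")
}

check_complete_for_simulation <- function(cohort) {
  need <- c("age_at_rand", "female", "smoker_baseline", "duration",
            RISK_FACTORS, "egfr", paste0("first_", c(RISK_FACTORS, "egfr")))
  bad_rows <- character(0)
  bad_fields <- character(0)
  for (f in need) {
    miss <- !is.finite(cohort[[f]])
    if (any(miss)) {
      bad_rows <- union(bad_rows, as.character(cohort$id[miss]))
      bad_fields <- union(bad_fields, f)
    }
  }
  if (length(bad_rows)) {
    stop("cohort incomplete for simulation; patient(s) ",
         paste(utils::head(bad_rows, 10L), collapse = ", "),
         " missing field(s) ", paste(bad_fields, collapse = ", "),
         call. = FALSE)
  }
  invisible(cohort)
}

#' @export
print.cohort_trajectory <- function(x, ...) {
  cat("<cohort_trajectory> ", length(x$ids), " patients x ",
      dim(x$factors)[3L], " years (", x$config$mode, " mode, seed ",
      x$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Long-format view of a simulated trajectory
#'
#' @param x a \code{cohort_trajectory}.
#' @param ... unused.
#' @return data frame with columns \code{patient}, \code{year},
#'   \code{variable}, \code{value}. Variables are the seven risk factors,
#'   \code{egfr}, \code{duration}, the four flags (0/1) and, where defined,
#'   the annual event probabilities (\code{p_af}, ...).
#' @export
as.data.frame.cohort_trajectory <- function(x, ...) {
  n <- length(x$ids)
  H <- dim(x$factors)[3L]
  blocks <- list()
  grid <- expand.grid(patient = x$ids, year = seq_len(H),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  add <- function(variable, values) {
    blocks[[length(blocks) + 1L]] <<- data.frame(
      patient = grid$patient, year = grid$year, variable = variable,
      value = as.vector(values))
  }
  for (k in seq_along(RISK_FACTORS)) add(RISK_FACTORS[k], x$factors[, k, ])
  add("egfr", x$egfr)
  add("duration", outer(x$duration0, seq_len(H), `+`))
  for (j in seq_along(OUTCOMES)) {
    add(flag_column(OUTCOMES[j]), x$flags[, j, ] * 1)
    add(paste0("p_", flag_column(OUTCOMES[j])), x$probabilities[, j, ])
  }
  out <- do.call(rbind, blocks)
  out[order(out$patient, out$year, out$variable), , drop = FALSE]
}

#' Write a trajectory and its run metadata to disk
#'
#' Writes the long-format trajectory as tab-separated text and a JSON
#' sidecar (\code{<path>.meta.json}) recording the seed, mode, horizon,
#' intervention and bundle provenance.
#'
#' @param trajectory a \code{cohort_trajectory}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  df <- as.data.frame(trajectory)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- list(seed = trajectory$config$seed,
               mode = trajectory$config$mode,
               horizon = trajectory$config$horizon,
               intervention = as.list(trajectory$config$intervention),
               provenance = trajectory$provenance,
               n_patients = length(trajectory$ids))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Cumulative incidence implied by expected-mode probabilities
#'
#' Accumulates per-patient annual probabilities as
#' \eqn{1 - \prod_t (1 - p_t)} and averages over the cohort, giving the
#' cumulative incidence a Monte-Carlo binarization of the same
#' probabilities converges to.
#'
#' @param trajectory a deterministic-mode \code{cohort_trajectory}.
#' @param outcome one of the four outcome identifiers.
#' @return numeric vector of cohort cumulative incidence per year.
#' @export
expected_cumulative_incidence <- function(trajectory, outcome) {
  outcome <- match.arg(outcome, OUTCOMES)
  n <- length(trajectory$ids)
  H <- dim(trajectory$probabilities)[3L]
  p <- matrix(trajectory$probabilities[, outcome, ], nrow = n, ncol = H)
  # patients already in the state contribute incidence 1 from year 1
  p[is.na(p)] <- 1
  surv <- matrix(t(apply(1 - p, 1L, cumprod)), nrow = n, ncol = H)
  colMeans(1 - surv)
}

#' Per-year mean differences between two simulation scenarios
#'
#' Runs the same cohort under two configurations (which may differ only in
#' intervention and/or mode) with common random numbers and returns paired
#' per-year mean differences (B minus A) with normal-approximation 95%
#' confidence intervals, for the seven risk factors and eGFR.
#'
#' @param bundle a [coefficient_bundle()].
#' @param cohort a cohort table.
#' @param config_a,config_b two [simulation_config()]s sharing horizon and
#'   seed.
#' @return data frame with columns \code{year}, \code{variable},
#'   \code{mean_diff}, \code{ci_lower}, \code{ci_upper}.
#' @export
compare_scenarios <- function(bundle, cohort, config_a, config_b) {
  if (config_a$horizon != config_b$horizon ||
      config_a$seed != config_b$seed) {
    stop("configs must share horizon and seed (common random numbers)",
         call. = FALSE)
  }
  tr_a <- simulate_cohort(bundle, cohort, config_a)
  tr_b <- simulate_cohort(bundle, cohort, config_b)
  H <- config_a$horizon
  n <- nrow(as_cohort(cohort))
  rows <- list()
  vars <- c(RISK_FACTORS, "egfr")
  for (y in seq_len(H)) {
    for (v in vars) {
      d <- if (v == "egfr") tr_b$egfr[, y] - tr_a$egfr[, y] else
        tr_b$factors[, v, y] - tr_a$factors[, v, y]
      m <- mean(d)
      se <- stats::sd(d) / sqrt(n)
      rows[[length(rows) + 1L]] <- data.frame(
        year = y, variable = v, mean_diff = m,
        ci_lower = m - 1.96 * se, ci_upper = m + 1.96 * se)
    }
  }
  do.call(rbind, rows)
}

#' The last-observation-carried-forward comparator bundle
#'
#' A bundle whose dynamic equations are the identity (\eqn{\phi_1 = 1}, all
#' other coefficients 0), whose condition hazards are numerically zero and
#' whose eGFR value models carry last year's value forward: the LOCF
#' assumption used as a reference scenario, under which every risk factor
#' stays at its baseline value forever and no condition ever occurs.
#'
#' @return a complete [coefficient_bundle()].
#' @export
locf_bundle <- function() {
  dyn <- lapply(RISK_FACTORS, function(rf) {
    dynamic_coefficients(rf, phi0 = 0, phi1 = 1, phi2 = 0, phi3 = 0,
                         phi4_white = 0, phi4_black = 0, phi4_asian = 0,
                         phi5 = 0, phi6 = 0)
  })
  names(dyn) <- RISK_FACTORS
  surv <- lapply(OUTCOMES, function(o) {
    # exp(-1000) underflows to exactly 0: zero hazard at all durations
    survival_coefficients(o, betas = c(constant = -1000), ln_gamma = 0)
  })
  names(surv) <- OUTCOMES
  tob <- list(
    below60 = tobit_coefficients("below60",
      betas = c(constant = 0, `lag:egfr` = 1), sigma = 1e-8,
      lower_limit = 0, upper_limit = 60),
    atabove60 = tobit_coefficients("atabove60",
      betas = c(constant = 0, `lag:egfr` = 1), sigma = 1e-8,
      lower_limit = 60, upper_limit = Inf))
  coefficient_bundle(dyn, surv, tob,
                     provenance = "last observation carried forward")
}
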