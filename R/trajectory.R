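#' One-year-ahead prediction of a continuous risk factor
#'
#' Evaluates the first-order dynamic equation for one risk factor on every
#' patient of a cohort table. In deterministic mode the expected value
#' \deqn{\phi_0 + \phi_1 y_{prev} + \phi_2 y_{first} + \phi_3 female +
#'   \phi_4(ethnicity) + \phi_5 age + \phi_6 \ln(duration)}
#' is returned. In stochastic mode a zero-mean Gaussian disturbance is
#' added: the patient-level random effect \eqn{\mu_i} (sd \code{re_sd},
#' drawn once per patient and passed in via \code{mu} when the same patient
#' is advanced repeatedly) plus a fresh residual (sd \code{resid_sd}), so a
#' single call adds noise with sd \code{sqrt(re_sd^2 + resid_sd^2)} when
#' \code{mu} is not supplied.
#'
#' \code{ln(duration)} uses \code{state$duration} as given; the annual-cycle
#' driver increments duration before calling, so predictions for year
#' \eqn{t} use duration at year \eqn{t}. Duration is floored at 0.5 years
#' before logging.
#'
#' @param coef a [dynamic_coefficients()] object.
#' @param state a cohort table (see [as_cohort()]); the factor's current
#'   value is taken as \eqn{y_{prev}} and \code{first_<factor>} as
#'   \eqn{y_{first}}.
#' @param mode \code{"deterministic"} or \code{"stochastic"}.
#' @param mu optional numeric vector of per-patient random effects to hold
#'   fixed across years; if \code{NULL} in stochastic mode, fresh
#'   \eqn{N(0, re\_sd^2)} values are drawn.
#' @param eps optional residual draws (standard normal scale, multiplied by
#'   \code{resid_sd}); drawn fresh if \code{NULL}.
#' @return numeric vector of predicted values, one per patient.
#' @export
#' @examples
#' b <- default_bundle()
#' st <- as_cohort(data.frame(id = 1, age_at_rand = 64, female = 1,
#'   ethnicity = "white", smoker_baseline = 0, duration = 16,
#'   hdl = 1.1, ldl = 2.2, sbp = 135, hba1c = 7, haemoglobin = 13.8,
#'   heart_rate = 72, bmi = 31, egfr = 75))
#' predict_next_value(b$dynamic$hba1c, st)
predict_next_value <- function(coef, state,
                               mode = c("deterministic", "stochastic"),
                               mu = NULL, eps = NULL) {
  mode <- match.arg(mode)
  rf <- coef$risk_factor
  y_prev <- state[[rf]]
  y_first <- state[[paste0("first_", rf)]]
  if (is.null(y_prev) || anyNA(y_prev)) {
    stop("missing covariate: current value of '", rf, "'", call. = FALSE)
  }
  if (is.null(y_first) || anyNA(y_first)) {
    stop("missing covariate: first recorded value of '", rf, "'",
         call. = FALSE)
  }
  eth <- state$ethnicity
  phi4 <- numeric(nrow(state))
  phi4[eth == "white"] <- coef$phi4_white
  phi4[eth == "black"] <- coef$phi4_black
  phi4[eth == "asian"] <- coef$phi4_asian
  pred <- coef$phi0 + coef$phi1 * y_prev + coef$phi2 * y_first +
    coef$phi3 * resolve_covariate("female", state) + phi4 +
    coef$phi5 * resolve_covariate("age_at_rand", state) +
    coef$phi6 * resolve_covariate("ln_duration", state)
  if (mode == "stochastic") {
    n <- nrow(state)
    if (is.null(mu)) mu <- stats::rnorm(n, 0, coef$re_sd)
    if (is.null(eps)) eps <- stats::rnorm(n)
    pred <- pred + mu + coef$resid_sd * eps
  }
  pred
}

#' Advance all seven continuous risk factors by one year
#'
#' Increments diabetes duration by one year and replaces every continuous
#' risk factor with its one-year-ahead prediction (all predictions computed
#' from the incoming state, then assigned simultaneously). First-recorded
#' values, eGFR and condition flags are untouched; use [advance_egfr()] and
#' [update_flags()] for those, or [simulate_cohort()] for the full annual
#' cycle.
#'
#' @inheritParams predict_next_value
#' @param bundle a complete [coefficient_bundle()].
#' @param clamp optional named list of \code{c(lower, upper)} ranges per
#'   factor; predictions are clamped into their range when supplied.
#' @return the advanced cohort table.
#' @export
advance_continuous <- function(bundle, state,
                               mode = c("deterministic", "stochastic"),
                               mu = NULL, eps = NULL, clamp = NULL) {
  mode <- match.arg(mode)
  new_state <- state
  new_state$duration <- state$duration + 1
  pred_state <- state
  pred_state$duration <- new_state$duration  # ln(duration) at the new year
  for (k in seq_along(RISK_FACTORS)) {
    rf <- RISK_FACTORS[k]
    p <- predict_next_value(bundle$dynamic[[rf]], pred_state, mode,
                            mu = if (is.null(mu)) NULL else mu[, k],
                            eps = if (is.null(eps)) NULL else eps[, k])
    if (!is.null(clamp[[rf]])) {
      p <- pmin(pmax(p, clamp[[rf]][1L]), clamp[[rf]][2L])
    }
    new_state[[rf]] <- p
  }
  new_state
}

#' Long-run level of a dynamic risk-factor equation
#'
#' With duration frozen, iterating the deterministic one-year-ahead
#' prediction converges geometrically (rate \eqn{|\phi_1|}) to
#' \deqn{y^* = \frac{\phi_0 + \phi_2 y_{first} + \phi_3 female +
#'   \phi_4(ethnicity) + \phi_5 age + \phi_6 \ln(duration)}{1 - \phi_1}.}
#' A diagnostic for the implied equilibrium of each equation.
#'
#' @inheritParams predict_next_value
#' @param duration_frozen the duration (years) at which \code{ln(duration)}
#'   is held.
#' @return numeric vector of long-run levels, one per patient.
#' @export
long_run_mean <- function(coef, state, duration_frozen = state$duration) {
  if (abs(coef$phi1) >= 1) {
    stop("long_run_mean undefined: |phi1| >= 1, the path diverges",
         call. = FALSE)
  }
  st <- state
  st$duration <- duration_frozen
  st[[coef$risk_factor]] <- 0  # phi1 * y_prev term excluded
  predict_next_value(coef, st, mode = "deterministic") / (1 - coef$phi1)
}
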