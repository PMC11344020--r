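#' Latent mean of an eGFR Tobit equation
#'
#' The unbounded linear predictor \eqn{x'\beta} of a regime's censored-normal
#' value model. Covariates: constant, age at randomisation, first-recorded
#' eGFR, last year's eGFR and systolic blood pressure, and
#' \code{ln(duration)}.
#'
#' @param coef a [tobit_coefficients()] object.
#' @param state a cohort table; \code{lag:egfr} and \code{lag:sbp} are read
#'   from the current columns (the state before this year's update) and
#'   \code{ln_duration} from \code{state$duration}.
#' @return numeric vector of latent means.
#' @export
tobit_latent_mean <- function(coef, state) {
  linear_predictor(coef$betas, state)
}

#' Annual eGFR value from a Tobit equation
#'
#' Deterministic mode returns the mean of the \eqn{N(x'\beta, \sigma^2)}
#' distribution truncated to the regime's limits (the usual inverse-Mills
#' correction); stochastic mode draws from that truncated normal by
#' inversion. Either way the value lies strictly inside the limits, so the
#' two-part invariant (below-60 values in \eqn{[0, 60)}, at/above-60 values
#' \eqn{\ge 60}) holds on every simulated patient-year.
#'
#' @inheritParams tobit_latent_mean
#' @param mode \code{"deterministic"} or \code{"stochastic"}.
#' @param u optional uniforms for the stochastic draw (inversion sampling);
#'   drawn from the session RNG if \code{NULL}.
#' @param upper_cap optional physiological cap overriding an infinite upper
#'   limit (the simulator passes 200 by default).
#' @return numeric vector of eGFR values.
#' @export
tobit_value <- function(coef, state,
                        mode = c("deterministic", "stochastic"), u = NULL,
                        upper_cap = NULL) {
  mode <- match.arg(mode)
  if (!(coef$sigma > 0)) stop("tobit sigma must be > 0", call. = FALSE)
  mu <- tobit_latent_mean(coef, state)
  lo <- coef$lower_limit
  hi <- coef$upper_limit
  if (!is.null(upper_cap) && is.infinite(hi)) hi <- upper_cap
  if (mode == "deterministic") {
    truncnorm_mean(mu, coef$sigma, lo, hi)
  } else {
    if (is.null(u)) u <- stats::runif(length(mu))
    truncnorm_draw(mu, coef$sigma, lo, hi, u)
  }
}

#' Two-part annual eGFR update
#'
#' Runs the two-part eGFR engine for one annual cycle: (1) if the patient is
#' not yet below 60, the Weibull crossing equation decides (stochastically,
#' or never in expected mode) whether they cross this year; (2) the Tobit
#' value model matching the resulting regime produces the continuous value.
#' The below-60 state is absorbing: once crossed, the below-60 value model
#' is used permanently.
#'
#' The incoming \code{state} is the *last-year* state: \code{lag:egfr} and
#' \code{lag:sbp} are its current columns, while \code{ln(duration)} in the
#' Tobit is evaluated at \code{duration + 1} (the year being predicted).
#'
#' @param bundle a [coefficient_bundle()].
#' @param state a cohort table (pre-update).
#' @param mode \code{"deterministic"} or \code{"stochastic"}.
#' @param run_crossing run the Weibull crossing update internally (default).
#'   The annual-cycle driver sets \code{FALSE} because [update_flags()] has
#'   already updated the \code{egfr_lt60} flag for this cycle.
#' @param u_cross,u_value optional uniforms for the crossing draw and the
#'   truncated-normal value draw.
#' @param upper_cap physiological upper cap on the at/above-60 regime
#'   (default 200 ml/min/1.73m2).
#' @return a data frame of class \code{egfr_annual_result} with columns
#'   \code{below60}, \code{value}, \code{regime_used}, \code{draw_mode};
#'   attribute \code{state} holds the updated cohort (new \code{egfr} and
#'   \code{egfr_lt60} columns; duration unchanged — the driver owns it).
#' @export
advance_egfr <- function(bundle, state,
                         mode = c("deterministic", "stochastic"),
                         run_crossing = TRUE, u_cross = NULL, u_value = NULL,
                         upper_cap = 200) {
  mode <- match.arg(mode)
  if (is.null(state$egfr) || anyNA(state$egfr)) {
    stop("missing covariate: 'egfr'", call. = FALSE)
  }
  if (is.null(state$first_egfr) || anyNA(state$first_egfr)) {
    stop("missing covariate: 'first_egfr'", call. = FALSE)
  }
  n <- nrow(state)
  below <- state[[flag_column("EGFR_LT60")]]
  if (run_crossing && mode == "stochastic") {
    at_risk <- !below
    if (any(at_risk)) {
      res <- annual_event_probability(bundle$survival$EGFR_LT60,
                                      state[at_risk, , drop = FALSE],
                                      check_flag = FALSE)
      uc <- if (is.null(u_cross)) stats::runif(sum(at_risk)) else
        u_cross[at_risk]
      below[at_risk] <- uc < res$probability
    }
  }
  # Tobit ln(duration) is evaluated at the predicted year
  tstate <- state
  tstate$duration <- state$duration + 1
  value <- numeric(n)
  for (regime in c("below60", "atabove60")) {
    sel <- if (regime == "below60") below else !below
    if (!any(sel)) next
    value[sel] <- tobit_value(
      bundle$tobit[[regime]], tstate[sel, , drop = FALSE], mode,
      u = if (is.null(u_value)) NULL else u_value[sel],
      upper_cap = upper_cap)
  }
  out <- data.frame(
    below60 = below, value = value,
    regime_used = ifelse(below, "below60", "atabove60"),
    draw_mode = mode)
  class(out) <- c("egfr_annual_result", class(out))
  new_state <- state
  new_state$egfr <- value
  new_state[[flag_column("EGFR_LT60")]] <- below
  attr(out, "state") <- new_state
  out
}
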