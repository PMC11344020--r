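# Cumulative hazard H(t) at duration t for a survival equation with linear
# predictor eta. Weibull: H = exp(eta) t^gamma; exponential: H = exp(eta) t;
# Gompertz (shape g, possibly 0): H = exp(eta) (exp(g t) - 1)/g.
cumulative_hazard <- function(coef, eta, t) {
  t <- pmax(t, 0)
  switch(coef$distribution,
    weibull = {
      g <- exp(coef$ln_gamma)
      exp(eta) * t^g
    },
    exponential = exp(eta) * t,
    gompertz = {
      g <- coef$ln_gamma  # natural-scale slope for Gompertz
      if (abs(g) < 1e-12) exp(eta) * t else exp(eta) * expm1(g * t) / g
    },
    stop("unknown distribution: ", coef$distribution, call. = FALSE))
}

# inverse of the cumulative hazard: the duration t with H(t) = target
invert_cumhaz <- function(coef, eta, target) {
  switch(coef$distribution,
    weibull = (target / exp(eta))^(1 / exp(coef$ln_gamma)),
    exponential = target / exp(eta),
    gompertz = {
      g <- coef$ln_gamma
      if (abs(g) < 1e-12) target / exp(eta) else
        log1p(g * target / exp(eta)) / g
    },
    stop("unknown distribution: ", coef$distribution, call. = FALSE))
}

#' Simulate left-truncated event times from a condition equation
#'
#' Draws exact (continuous) onset times on the diabetes-duration scale by
#' inverting the conditional survivor function
#' \eqn{S(t \mid t_0) = \exp(H(t_0) - H(t))}, where \eqn{t_0} is the entry
#' duration, with administrative censoring after \code{censor_after} years
#' of follow-up. Covariates are held fixed at their values in \code{state}.
#'
#' @param coef a [survival_coefficients()] object.
#' @param state a cohort table supplying the covariates and entry durations.
#' @param censor_after follow-up years after entry at which observation
#'   stops (scalar or per-patient vector).
#' @param u optional uniforms for inversion.
#' @return data frame with \code{id}, \code{entry}, \code{exit},
#'   \code{event}.
#' @export
simulate_event_times <- function(coef, state, censor_after, u = NULL) {
  n <- nrow(state)
  eta <- linear_predictor(coef$betas, state)
  entry <- state$duration
  if (is.null(u)) u <- stats::runif(n)
  target <- cumulative_hazard(coef, eta, entry) - log(u)
  tt <- numeric(n)
  for (i in seq_len(n)) tt[i] <- invert_cumhaz(coef, eta[i], target[i])
  cens <- entry + rep_len(censor_after, n)
  data.frame(id = state$id, entry = entry, exit = pmin(tt, cens),
             event = as.integer(tt <= cens))
}

#' Annual probability of an absorbing condition
#'
#' Converts a proportional-hazards condition equation into the probability of
#' onset during the coming year of the annual cycle. With diabetes duration
#' \eqn{t} as the time scale, linear predictor \eqn{\eta} (evaluated from
#' last year's risk-factor values) and cumulative hazard \eqn{H},
#' \deqn{p = 1 - \exp(H(t) - H(t+1)) =
#'       1 - \frac{S(t+1)}{S(t)},}
#' the standard conversion of a parametric survival equation into an annual
#' discrete-cycle transition probability. Covariates are held at their
#' start-of-year (lagged) values across the one-year interval.
#'
#' @param coef a [survival_coefficients()] object.
#' @param state a cohort table; lagged covariates (\code{lag:<factor>}) are
#'   read from the current values, i.e. the state *before* this year's
#'   continuous update.
#' @param check_flag error if the condition flag is already \code{TRUE} for
#'   any patient (the state is absorbing and has no annual probability);
#'   disable when computing probabilities for a mixed cohort.
#' @return a data frame of class \code{annual_hazard_result} with columns
#'   \code{outcome}, \code{linear_predictor}, \code{cum_hazard_t},
#'   \code{cum_hazard_t1}, \code{probability}.
#' @export
#' @examples
#' b <- default_bundle()
#' st <- as_cohort(data.frame(id = 1, age_at_rand = 64, female = 0,
#'   ethnicity = "white", smoker_baseline = 0, duration = 16,
#'   hdl = 1.1, ldl = 2.2, sbp = 135, hba1c = 7, haemoglobin = 13.8,
#'   heart_rate = 72, bmi = 30, egfr = 75))
#' annual_event_probability(b$survival$AF, st)
annual_event_probability <- function(coef, state, check_flag = TRUE) {
  fc <- flag_column(coef$outcome)
  if (check_flag && !is.null(state[[fc]]) && any(state[[fc]])) {
    stop("absorbing state: flag '", fc, "' already TRUE for patient(s) ",
         paste(utils::head(state$id[state[[fc]]], 5L), collapse = ", "),
         call. = FALSE)
  }
  t <- state$duration
  if (any(t < 0)) stop("duration must be >= 0", call. = FALSE)
  eta <- linear_predictor(coef$betas, state)
  H0 <- cumulative_hazard(coef, eta, t)
  H1 <- cumulative_hazard(coef, eta, t + 1)
  p <- -expm1(H0 - H1)
  res <- data.frame(outcome = coef$outcome, linear_predictor = eta,
                    cum_hazard_t = H0, cum_hazard_t1 = H1, probability = p)
  class(res) <- c("annual_hazard_result", class(res))
  res
}

#' Update absorbing condition flags for one annual cycle
#'
#' For each outcome whose flag is still \code{FALSE}, computes the annual
#' onset probability from the (lagged) state and, in stochastic mode, flips
#' the flag when a uniform draw falls below it. Flags never revert. In
#' expected mode no flag is flipped; the probabilities are recorded for
#' calibration (accumulate survival as \eqn{\prod_t (1 - p_t)}).
#'
#' @param bundle a [coefficient_bundle()].
#' @param state a cohort table.
#' @param mode \code{"stochastic"} (Monte-Carlo binarization) or
#'   \code{"expected"}.
#' @param u optional matrix of uniforms, one column per outcome in the order
#'   \code{AF, ALB, PVD, EGFR_LT60}; drawn from the session RNG if
#'   \code{NULL}.
#' @return list with \code{state} (flags updated) and \code{probabilities}
#'   (n x 4 matrix; \code{NA} for patients already in the state).
#' @export
update_flags <- function(bundle, state, mode = c("stochastic", "expected"),
                         u = NULL) {
  mode <- match.arg(mode)
  n <- nrow(state)
  probs <- matrix(NA_real_, n, length(OUTCOMES),
                  dimnames = list(NULL, OUTCOMES))
  for (j in seq_along(OUTCOMES)) {
    o <- OUTCOMES[j]
    coef <- bundle$survival[[o]]
    if (is.null(coef)) next
    fc <- flag_column(o)
    at_risk <- !state[[fc]]
    if (!any(at_risk)) next
    res <- annual_event_probability(coef, state[at_risk, , drop = FALSE],
                                    check_flag = FALSE)
    probs[at_risk, j] <- res$probability
    if (mode == "stochastic") {
      uj <- if (is.null(u)) stats::runif(sum(at_risk)) else u[at_risk, j]
      hit <- uj < res$probability
      state[[fc]][at_risk] <- hit
    }
  }
  list(state = state, probabilities = probs)
}
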