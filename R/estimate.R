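#' Fit results
#'
#' Every fitter returns a \code{fit_result}: the typed coefficient object
#' (reusable by the simulator), the raw coefficient vector with standard
#' errors and Wald p-values, the maximized log-likelihood, AIC
#' (\eqn{2k - 2\ell}), sample sizes and convergence diagnostics.
#'
#' @name fit_result
#' @keywords internal
NULL

new_fit_result <- function(coefficients, estimates, se, loglik, n_obs,
                           n_patients, convergence, vcov = NULL,
                           n_params = length(estimates), extra = list()) {
  k <- n_params
  stopifnot(all(se > 0 | is.na(se)))
  structure(c(list(
    coefficients = coefficients, estimates = estimates, se = se,
    wald_p = 2 * stats::pnorm(-abs(estimates / se)),
    loglik = loglik, aic = 2 * k - 2 * loglik, n_obs = n_obs,
    n_patients = n_patients, convergence = convergence, vcov = vcov),
    extra), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> loglik =", format(x$loglik), " AIC =", format(x$aic),
      " n_obs =", x$n_obs, " n_patients =", x$n_patients, "\n")
  tab <- data.frame(estimate = x$estimates, se = x$se, p = x$wald_p)
  print(round(tab, 4))
  invisible(x)
}

# --- dynamic panel ---------------------------------------------------------

#' Fit a dynamic risk-factor equation on panel data
#'
#' Maximum-likelihood random-intercept regression of a risk factor on its
#' one-year lag, its first recorded (baseline) value, sex, ethnicity, age at
#' randomisation and \code{ln(duration)} — the estimation counterpart of
#' [predict_next_value()]. The lagged regressor is treated as exogenous
#' (classical random-effects estimation of a dynamic panel); the baseline
#' value in the regressor set absorbs most of the initial-conditions
#' problem, and the residual small-T bias is accepted by design.
#'
#' @param panel a \code{panel_dataset} (see [generate_panel()]).
#' @param risk_factor which continuous factor to fit.
#' @return a \code{fit_result} whose \code{coefficients} is a
#'   [dynamic_coefficients()] including the estimated \code{resid_sd} and
#'   \code{re_sd}; \code{r_squared} is the squared correlation between
#'   fitted and observed values.
#' @export
fit_dynamic_panel <- function(panel, risk_factor) {
  risk_factor <- match.arg(risk_factor, RISK_FACTORS)
  df <- build_lag_frame(panel, risk_factor)
  if (nrow(df) == 0L) stop("no usable lag pairs for '", risk_factor, "'",
                           call. = FALSE)
  fit <- lme4::lmer(
    y ~ ylag + yfirst + female + eth_white + eth_black + eth_asian +
      age_at_rand + ln_duration + (1 | id),
    data = df, REML = FALSE,
    control = lme4::lmerControl(calc.derivs = FALSE))
  fe <- lme4::fixef(fit)
  se <- sqrt(Matrix::diag(stats::vcov(fit)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  re_sd <- vc$sdcor[vc$grp == "id"]
  resid_sd <- vc$sdcor[vc$grp == "Residual"]
  coefs <- dynamic_coefficients(
    risk_factor,
    phi0 = unname(fe["(Intercept)"]), phi1 = unname(fe["ylag"]),
    phi2 = unname(fe["yfirst"]), phi3 = unname(fe["female"]),
    phi4_white = unname(fe["eth_white"]),
    phi4_black = unname(fe["eth_black"]),
    phi4_asian = unname(fe["eth_asian"]),
    phi5 = unname(fe["age_at_rand"]), phi6 = unname(fe["ln_duration"]),
    resid_sd = resid_sd, re_sd = re_sd)
  est <- stats::setNames(as.numeric(fe), names(fe))
  names(est)[1L] <- "constant"
  se <- stats::setNames(as.numeric(se), names(est))
  conv <- length(fit@optinfo$conv$lme4$messages) == 0L
  ll <- stats::logLik(fit)
  new_fit_result(coefs, est, se, loglik = as.numeric(ll),
                 n_obs = nrow(df), n_patients = length(unique(df$id)),
                 convergence = conv, n_params = attr(ll, "df"),
                 extra = list(
                   r_squared = stats::cor(stats::fitted(fit), df$y)^2,
                   resid_sd = resid_sd, re_sd = re_sd, model = "lmm"))
}

# estimation frame: one row per (patient, year >= 1) with a measured value
# and a measured value in the immediately preceding year
build_lag_frame <- function(panel, var) {
  v <- panel$visits
  if (is.null(v[[var]])) stop("panel has no column '", var, "'",
                              call. = FALSE)
  v <- v[!is.na(v[[var]]), c("id", "year", "duration", "age_at_rand",
                             "female", "ethnicity", "smoker_baseline",
                             var)]
  v <- v[order(v$id, v$year), , drop = FALSE]
  base <- v[v$year == 0L, c("id", var)]
  names(base)[2L] <- "yfirst"
  prev <- v[, c("id", "year", var)]
  prev$year <- prev$year + 1L
  names(prev)[3L] <- "ylag"
  df <- v[v$year >= 1L, , drop = FALSE]
  names(df)[names(df) == var] <- "y"
  df <- merge(df, prev, by = c("id", "year"))
  df <- merge(df, base, by = "id")
  df$eth_white <- as.numeric(df$ethnicity == "white")
  df$eth_black <- as.numeric(df$ethnicity == "black")
  df$eth_asian <- as.numeric(df$ethnicity == "asian")
  df$ln_duration <- log(pmax(df$duration, 0.5))
  df
}

# --- Tobit -----------------------------------------------------------------

#' Censored-normal (Tobit) maximum likelihood
#'
#' Fits \eqn{y^* = X\beta + e}, \eqn{e \sim N(0, \sigma^2)}, with
#' observations at the censoring limits contributing probability mass and
#' interior observations contributing the normal density. The engine behind
#' [fit_tobit()]; usable directly on any design matrix.
#'
#' @param y observed (censored) responses.
#' @param X design matrix (no intercept column; one is added as
#'   \code{constant}).
#' @param lower,upper censoring limits (\code{-Inf}/\code{Inf} allowed).
#' @return a \code{fit_result}; \code{sigma} holds the estimated residual
#'   SD.
#' @export
tobit_mle <- function(y, X, lower = -Inf, upper = Inf) {
  X <- cbind(constant = 1, as.matrix(X))
  n <- length(y)
  at_lo <- is.finite(lower) & y <= lower
  at_hi <- is.finite(upper) & y >= upper
  inside <- !at_lo & !at_hi
  if (!any(inside)) stop("all observations censored: Tobit parameters not ",
                         "identifiable", call. = FALSE)
  nll <- function(par) {
    beta <- par[-length(par)]
    sigma <- exp(par[length(par)])
    mu <- drop(X %*% beta)
    ll <- numeric(n)
    ll[inside] <- stats::dnorm(y[inside], mu[inside], sigma, log = TRUE)
    if (any(at_lo)) {
      ll[at_lo] <- stats::pnorm(lower, mu[at_lo], sigma, log.p = TRUE)
    }
    if (any(at_hi)) {
      ll[at_hi] <- stats::pnorm(upper, mu[at_hi], sigma, log.p = TRUE,
                                lower.tail = FALSE)
    }
    -sum(ll)
  }
  ols <- stats::lm.fit(X, y)
  start <- c(ols$coefficients,
             log(max(stats::sd(ols$residuals), 1e-3)))
  opt <- stats::optim(start, nll, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-12))
  if (opt$convergence != 0L) {
    stop("Tobit likelihood failed to converge (optim code ",
         opt$convergence, ")", call. = FALSE)
  }
  k <- ncol(X)
  vc <- solve(opt$hessian)
  est <- opt$par[1:k]
  names(est) <- colnames(X)
  se <- sqrt(diag(vc))[1:k]
  names(se) <- names(est)
  sigma <- exp(opt$par[k + 1L])
  list(estimates = est, se = se, sigma = sigma,
       sigma_se = sigma * sqrt(diag(vc))[k + 1L],
       loglik = -opt$value, vcov = vc, n_obs = n)
}

#' Fit a regime's eGFR Tobit equation on panel data
#'
#' Builds the regime-consistent patient-year subsample (observed eGFR below
#' or at/above 60), assembles the published covariate set (age at
#' randomisation, first-recorded eGFR, last year's eGFR and SBP,
#' \code{ln(duration)}) and maximizes the censored-normal likelihood with
#' the regime's limits. A pooled (single-\eqn{\sigma}) Tobit is fit: the
#' forecast standard error reported with the published equations is a
#' single total SD, and the simulator treats it as the draw SD.
#'
#' @param panel a \code{panel_dataset}.
#' @param regime \code{"below60"} or \code{"atabove60"}.
#' @return a \code{fit_result} whose \code{coefficients} is a
#'   [tobit_coefficients()].
#' @export
fit_tobit <- function(panel, regime = c("below60", "atabove60")) {
  regime <- match.arg(regime)
  lo <- if (regime == "below60") 0 else 60
  hi <- if (regime == "below60") 60 else Inf
  df <- build_lag_frame(panel, "egfr")
  sbp_lag <- build_lag_frame(panel, "sbp")[, c("id", "year", "ylag")]
  names(sbp_lag)[3L] <- "sbp_lag"
  df <- merge(df, sbp_lag, by = c("id", "year"))
  sel <- if (regime == "below60") df$y < 60 else df$y >= 60
  df <- df[sel, , drop = FALSE]
  if (nrow(df) == 0L) stop("empty regime subsample '", regime, "'",
                           call. = FALSE)
  X <- cbind(age_at_rand = df$age_at_rand, `first:egfr` = df$yfirst,
             `lag:egfr` = df$ylag, `lag:sbp` = df$sbp_lag,
             ln_duration = df$ln_duration)
  eng <- tobit_mle(df$y, X, lower = lo, upper = hi)
  coefs <- tobit_coefficients(regime, betas = eng$estimates,
                              sigma = eng$sigma, lower_limit = lo,
                              upper_limit = hi)
  new_fit_result(coefs, eng$estimates, eng$se, eng$loglik,
                 n_obs = eng$n_obs,
                 n_patients = length(unique(df$id)), convergence = TRUE,
                 vcov = eng$vcov, n_params = length(eng$estimates) + 1L,
                 extra = list(sigma = eng$sigma, sigma_se = eng$sigma_se,
                              model = "tobit"))
}

# --- parametric proportional hazards ---------------------------------------

ph_loglik_terms <- function(par, entry, exit, event, X, distribution) {
  k <- ncol(X)
  beta <- par[1:k]
  eta <- drop(X %*% beta)
  if (distribution == "weibull") {
    lg <- par[k + 1L]
    g <- exp(lg)
    logh <- lg + (g - 1) * log(exit) + eta
    Hdiff <- exp(eta) * (exit^g - entry^g)
  } else if (distribution == "exponential") {
    logh <- eta
    Hdiff <- exp(eta) * (exit - entry)
  } else { # gompertz
    g <- par[k + 1L]
    logh <- eta + g * exit
    Hdiff <- if (abs(g) < 1e-12) exp(eta) * (exit - entry) else
      exp(eta) * (exp(g * exit) - exp(g * entry)) / g
  }
  event * logh - Hdiff
}

#' Left-truncated parametric proportional-hazards maximum likelihood
#'
#' Maximizes \eqn{\sum_i d_i \log h(t_{exit,i}) + H(t_{entry,i}) -
#' H(t_{exit,i})} over counting-process rows \code{(entry, exit, event)} —
#' the delayed-entry likelihood appropriate when subjects enter observation
#' years after diagnosis. Time-varying covariates are supported through
#' episode-split rows sharing an \code{id}. Weibull, exponential and
#' Gompertz hazard families are available with AICs directly comparable.
#' Standard errors are cluster-robust (sandwich over subjects) by default.
#'
#' @param data data frame with columns \code{id}, \code{entry}, \code{exit},
#'   \code{event} plus covariate columns.
#' @param covariates character vector of covariate column names (may be
#'   empty for a constant-only model).
#' @param distribution \code{"weibull"}, \code{"exponential"} or
#'   \code{"gompertz"}.
#' @param outcome outcome label stored in the coefficient object.
#' @param robust cluster-robust standard errors (default) or inverse-Hessian.
#' @return a \code{fit_result} whose \code{coefficients} is a
#'   [survival_coefficients()] (for exponential, \code{ln_gamma} is fixed 0;
#'   for Gompertz it stores the natural-scale shape slope).
#' @export
ph_mle <- function(data, covariates, distribution = c("weibull",
                                                      "exponential",
                                                      "gompertz"),
                   outcome = "AF", robust = TRUE) {
  distribution <- match.arg(distribution)
  if (sum(data$event) == 0L) stop("no events: hazard not identifiable",
                                  call. = FALSE)
  X <- cbind(constant = 1,
             if (length(covariates)) as.matrix(data[, covariates,
                                                    drop = FALSE]))
  colnames(X) <- c("constant", covariates)
  entry <- pmax(data$entry, 0)
  exit <- data$exit
  if (any(exit <= entry)) stop("exit must exceed entry for every row",
                               call. = FALSE)
  event <- data$event
  k <- ncol(X)
  has_shape <- distribution != "exponential"
  nll <- function(par) {
    -sum(ph_loglik_terms(if (has_shape) par else c(par, 0),
                         entry, exit, event, X, distribution))
  }
  rate0 <- log(sum(event) / sum(exit - entry))
  start <- c(rate0, rep(0, k - 1L), if (has_shape) 0)
  opt <- stats::optim(start, nll, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 1000, reltol = 1e-12))
  if (opt$convergence != 0L) {
    stop("PH likelihood failed to converge (optim code ", opt$convergence,
         "); ", opt$counts[["function"]], " evaluations", call. = FALSE)
  }
  par <- opt$par
  npar <- length(par)
  A <- opt$hessian  # negative-loglik Hessian
  vc <- tryCatch(solve(A), error = function(e) {
    matrix(NA_real_, npar, npar)
  })
  if (robust && !anyNA(vc)) {
    # numeric per-row scores, clustered by subject
    h <- 1e-6 * pmax(abs(par), 1)
    G <- matrix(0, nrow(data), npar)
    for (j in seq_len(npar)) {
      up <- par; up[j] <- up[j] + h[j]
      dn <- par; dn[j] <- dn[j] - h[j]
      full <- function(p) ph_loglik_terms(
        if (has_shape) p else c(p, 0), entry, exit, event, X, distribution)
      G[, j] <- (full(up) - full(dn)) / (2 * h[j])
    }
    cl <- if (!is.null(data$id)) data$id else seq_len(nrow(data))
    Gc <- rowsum(G, cl)
    B <- crossprod(Gc)
    vc <- vc %*% B %*% vc
  }
  est <- par[1:k]
  names(est) <- colnames(X)
  se <- sqrt(diag(vc))[1:k]
  names(se) <- names(est)
  shape <- if (has_shape) par[k + 1L] else 0
  shape_se <- if (has_shape) sqrt(diag(vc))[k + 1L] else NA_real_
  coefs <- survival_coefficients(outcome, betas = est, ln_gamma = shape,
                                 covariate_spec = covariates,
                                 distribution = distribution)
  n_pat <- if (!is.null(data$id)) length(unique(data$id)) else nrow(data)
  new_fit_result(coefs, est, se, loglik = -opt$value, n_obs = nrow(data),
                 n_patients = n_pat, convergence = TRUE, vcov = vc,
                 n_params = npar,
                 extra = list(shape = shape, shape_se = shape_se,
                              distribution = distribution,
                              n_events = sum(event), model = "ph"))
}

#' Fit a condition equation on panel data
#'
#' Episode-splits the panel's event records into patient-year intervals with
#' last year's risk-factor values as covariates and fits the left-truncated
#' parametric proportional-hazards likelihood via [ph_mle()].
#'
#' @param panel a \code{panel_dataset}.
#' @param outcome one of \code{AF}, \code{ALB}, \code{PVD},
#'   \code{EGFR_LT60}.
#' @param distribution hazard family, see [ph_mle()].
#' @param covariates covariate names (controlled vocabulary); defaults to
#'   the published covariate set for the outcome.
#' @param robust cluster-robust SEs (default).
#' @return a \code{fit_result}.
#' @export
fit_parametric_ph <- function(panel, outcome,
                              distribution = c("weibull", "exponential",
                                               "gompertz"),
                              covariates = NULL, robust = TRUE) {
  outcome <- match.arg(outcome, OUTCOMES)
  distribution <- match.arg(distribution)
  if (is.null(covariates)) {
    covariates <- default_bundle()$survival[[outcome]]$covariate_spec
  }
  data <- build_episodes(panel, outcome, covariates)
  ph_mle(data, covariates, distribution, outcome = outcome,
         robust = robust)
}

# episode-split the at-risk follow-up of each patient into yearly intervals
# with lagged (start-of-interval) covariate values
build_episodes <- function(panel, outcome, covariates) {
  ev <- panel$events[panel$events$outcome == outcome, , drop = FALSE]
  if (nrow(ev) == 0L) stop("panel has no event records for '", outcome,
                           "'", call. = FALSE)
  v <- panel$visits
  # "first:" covariates resolve through first_* columns: attach them from
  # each patient's baseline (year 0) visit
  first_vars <- sub("^first:", "", grep("^first:", covariates, value = TRUE))
  base <- v[v$year == 0L, c("id", first_vars), drop = FALSE]
  if (length(first_vars)) {
    names(base)[-1L] <- paste0("first_", first_vars)
    v <- merge(v, base, by = "id", all.x = TRUE)
  }
  n_y <- pmax(ceiling(ev$exit - ev$entry - 1e-9), 1L)
  idx <- rep(seq_len(nrow(ev)), n_y)
  y <- sequence(n_y)
  epi <- data.frame(
    id = ev$id[idx],
    year = y,
    entry = ev$entry[idx] + y - 1,
    exit = pmin(ev$entry[idx] + y, ev$exit[idx]),
    event = as.integer(y == n_y[idx] & ev$event[idx] == 1L),
    stringsAsFactors = FALSE)
  # lagged covariates come from the visit of the previous year
  lagv <- v
  lagv$year <- lagv$year + 1L
  epi <- merge(epi, lagv, by = c("id", "year"), all.x = TRUE,
               suffixes = c("", ".visit"))
  epi$duration <- epi$entry
  cov_mat <- matrix(NA_real_, nrow(epi), length(covariates),
                    dimnames = list(NULL, covariates))
  for (nm in covariates) {
    val <- tryCatch(resolve_covariate(nm, epi), error = function(e) NULL)
    if (is.null(val)) {
      # recompute allowing NAs; rows with NA are dropped below
      src <- if (nm == "constant") rep(1, nrow(epi))
      else if (nm %in% c("age_at_rand", "female", "smoker_baseline"))
        epi[[nm]]
      else if (startsWith(nm, "eth_"))
        as.numeric(epi$ethnicity == sub("^eth_", "", nm))
      else if (nm == "ln_duration") log(pmax(epi$duration, 0.5))
      else if (startsWith(nm, "lag:")) epi[[sub("^lag:", "", nm)]]
      else if (startsWith(nm, "first:"))
        epi[[paste0("first_", sub("^first:", "", nm))]]
      else stop("unknown covariate name: '", nm, "'", call. = FALSE)
      val <- as.numeric(src %||% rep(NA_real_, nrow(epi)))
    }
    cov_mat[, nm] <- val
  }
  ok <- stats::complete.cases(cov_mat)
  if (any(!ok)) {
    warning(sum(!ok), " episode(s) dropped for missing lagged covariates")
  }
  out <- cbind(epi[ok, c("id", "entry", "exit", "event"), drop = FALSE],
               as.data.frame(cov_mat[ok, , drop = FALSE],
                             check.names = FALSE))
  out <- out[order(out$id, out$entry), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- stepwise selection ----------------------------------------------------

#' Backwards stepwise covariate selection
#'
#' Starting from the full candidate set, repeatedly removes the covariate
#' with the largest Wald p-value until every remaining candidate has
#' \eqn{p < \alpha}. Ties are broken deterministically by removing the
#' candidate appearing later in the declared ordering. May return a
#' constant-only model.
#'
#' @param panel a \code{panel_dataset} (or whatever the fitter consumes).
#' @param outcome outcome label passed to the fitter.
#' @param candidate_covariates ordered character vector of candidates.
#' @param alpha retention threshold (default 0.05).
#' @param fitter function \code{(panel, outcome, covariates) ->
#'   fit_result}; defaults to a Weibull [fit_parametric_ph()].
#' @return the final \code{fit_result}, with attribute \code{trace}: a data
#'   frame of removal steps (covariate removed, its p-value).
#' @export
backwards_stepwise <- function(panel, outcome, candidate_covariates,
                               alpha = 0.05, fitter = NULL) {
  if (is.null(fitter)) {
    fitter <- function(panel, outcome, covariates) {
      fit_parametric_ph(panel, outcome, "weibull", covariates = covariates)
    }
  }
  covs <- candidate_covariates
  trace <- list()
  repeat {
    fit <- fitter(panel, outcome, covs)
    if (length(covs) == 0L) break
    p <- fit$wald_p[covs]
    if (all(p < alpha, na.rm = TRUE)) break
    worst_p <- max(p, na.rm = TRUE)
    cand <- covs[which(p == worst_p)]
    drop <- cand[length(cand)]  # later in the declared ordering
    trace[[length(trace) + 1L]] <- data.frame(removed = drop,
                                              p_value = worst_p)
    covs <- setdiff(covs, drop)
  }
  attr(fit, "trace") <- if (length(trace)) do.call(rbind, trace) else
    data.frame(removed = character(), p_value = numeric())
  attr(fit, "selected") <- covs
  fit
}

# --- residual diagnostics --------------------------------------------------

#' Cox-Snell residuals of a fitted proportional-hazards model
#'
#' Per subject, the fitted cumulative hazard experienced over observation:
#' \eqn{r_i = \hat H(t_{exit,i}) - \hat H(t_{entry,i})}, summed over a
#' subject's episode rows. Under a correctly specified model the residuals
#' of subjects, with their event indicators, behave like a unit-exponential
#' censored sample — the Nelson-Aalen cumulative hazard of the residuals
#' should follow the 45-degree line.
#'
#' @param fit a \code{fit_result} from [ph_mle()] or
#'   [fit_parametric_ph()].
#' @param data the counting-process data the model was fit to (columns
#'   \code{id}, \code{entry}, \code{exit}, \code{event} + covariates).
#' @return data frame with \code{id}, \code{residual}, \code{event}.
#' @export
cox_snell_residuals <- function(fit, data) {
  coef <- fit$coefficients
  covs <- coef$covariate_spec
  X <- cbind(constant = 1,
             if (length(covs)) as.matrix(data[, covs, drop = FALSE]))
  beta <- coef$betas[c("constant", covs)]
  eta <- drop(X %*% beta)
  r <- cumulative_hazard(coef, eta, data$exit) -
    cumulative_hazard(coef, eta, pmax(data$entry, 0))
  cl <- if (!is.null(data$id)) data$id else seq_len(nrow(data))
  agg <- rowsum(cbind(residual = r, event = data$event), cl)
  data.frame(id = rownames(agg), residual = agg[, "residual"],
             event = as.integer(agg[, "event"] > 0),
             row.names = NULL, stringsAsFactors = FALSE)
}
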