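#' Observed-versus-predicted time-path agreement
#'
#' Pools patient-years by integer diabetes duration (left-closed bins
#' \eqn{[k, k+1)}, period-life-table style, so patients with different
#' durations contribute to the same duration axis) and compares the
#' observed mean of a risk factor in each bin against the model prediction,
#' with a normal-approximation 95\% confidence interval around the observed
#' mean. A bin "covers" when the predicted mean lies inside the interval.
#'
#' Predictions are one-step-ahead: each observed patient-year with an
#' observed previous-year value is predicted from that observed lag
#' (\code{lag_source = "observed"}, the internal-validation default), or
#' from re-fed model predictions chained from baseline
#' (\code{lag_source = "simulated"}, the extrapolation view).
#'
#' @param panel a \code{panel_dataset}.
#' @param bundle a [coefficient_bundle()].
#' @param factor a continuous risk-factor identifier.
#' @param lag_source \code{"observed"} or \code{"simulated"}.
#' @param min_bin_n bins with fewer patient-years are dropped (with a
#'   warning).
#' @return a data frame of class \code{timepath_comparison}: one row per
#'   duration bin with \code{observed_mean}, \code{ci_lower},
#'   \code{ci_upper}, \code{predicted_mean}, \code{n}, \code{covered}.
#' @export
timepath_agreement <- function(panel, bundle, factor,
                               lag_source = c("observed", "simulated"),
                               min_bin_n = 10L) {
  lag_source <- match.arg(lag_source)
  factor <- match.arg(factor, RISK_FACTORS)
  coef <- bundle$dynamic[[factor]]
  if (is.null(coef)) stop("bundle has no dynamic equation for '", factor,
                          "'", call. = FALSE)
  df <- build_lag_frame(panel, factor)
  if (lag_source == "simulated") {
    df <- df[order(df$id, df$year), , drop = FALSE]
    pred_prev <- df$yfirst  # chain from the baseline value
    prev_id <- c("", utils::head(df$id, -1L))
    prev_year <- c(-1L, utils::head(df$year, -1L))
    chain <- numeric(nrow(df))
    for (r in seq_len(nrow(df))) {
      lag_val <- if (df$id[r] == prev_id[r] &&
                     df$year[r] == prev_year[r] + 1L) {
        chain[r - 1L]
      } else {
        df$ylag[r]
      }
      st <- df[r, , drop = FALSE]
      st[[factor]] <- lag_val
      st[[paste0("first_", factor)]] <- st$yfirst
      chain[r] <- predict_next_value(coef, st)
    }
    df$pred <- chain
  } else {
    st <- df
    st[[factor]] <- df$ylag
    st[[paste0("first_", factor)]] <- df$yfirst
    df$pred <- predict_next_value(coef, st)
  }
  df$bin <- floor(df$duration)
  out <- do.call(rbind, lapply(split(df, df$bin), function(b) {
    n <- nrow(b)
    m <- mean(b$y)
    se <- stats::sd(b$y) / sqrt(n)
    data.frame(duration = b$bin[1L], n = n, observed_mean = m,
               ci_lower = m - 1.96 * se, ci_upper = m + 1.96 * se,
               predicted_mean = mean(b$pred))
  }))
  small <- out$n < min_bin_n
  if (any(small)) {
    warning(sum(small), " duration bin(s) dropped (fewer than ", min_bin_n,
            " patient-years)")
    out <- out[!small, , drop = FALSE]
  }
  out$covered <- out$predicted_mean >= out$ci_lower &
    out$predicted_mean <= out$ci_upper
  out <- out[order(out$duration), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("timepath_comparison", class(out))
  out
}

#' Time-path agreement by quintile of first observed value
#'
#' Splits patients into quintiles of their first observed (baseline) value
#' of the factor — ties assigned to the lower quintile — and runs
#' [timepath_agreement()] within each stratum.
#'
#' @inheritParams timepath_agreement
#' @return named list of five \code{timepath_comparison} tables
#'   (\code{Q1} lowest to \code{Q5} highest), each carrying attribute
#'   \code{n_patients}.
#' @export
quintile_agreement <- function(panel, bundle, factor,
                               lag_source = c("observed", "simulated"),
                               min_bin_n = 10L) {
  factor <- match.arg(factor, RISK_FACTORS)
  v <- panel$visits
  base <- v[v$year == 0L & !is.na(v[[factor]]), c("id", factor)]
  if (length(unique(base[[factor]])) < 5L) {
    stop("need at least 5 distinct first observed values", call. = FALSE)
  }
  r <- rank(base[[factor]], ties.method = "min")
  q <- ceiling(5 * r / nrow(base))
  out <- lapply(1:5, function(k) {
    ids <- base$id[q == k]
    sub <- panel
    sub$visits <- panel$visits[panel$visits$id %in% ids, , drop = FALSE]
    cmp <- timepath_agreement(sub, bundle, factor, lag_source, min_bin_n)
    attr(cmp, "n_patients") <- length(ids)
    cmp
  })
  names(out) <- paste0("Q", 1:5)
  out
}

#' Kaplan-Meier observed versus model-predicted cumulative incidence
#'
#' Observed cumulative incidence is one minus the Kaplan-Meier survivor
#' estimate with delayed entry on the diabetes-duration scale (Greenwood
#' 95\% confidence intervals). The model prediction pools the fitted
#' cumulative-hazard increments of the at-risk patient-time (evaluated on
#' the observed covariate histories, expected mode) into integer duration
#' bins as occurrence-exposure rates, converts them to annual
#' probabilities \eqn{q_k = 1 - e^{-m_k}} and accumulates
#' \eqn{1 - \prod_k (1 - q_k)} — period-life-table pooling on the same
#' time axis as the observed curve.
#'
#' Both curves are conditional on being event-free at the first duration
#' whose risk set reaches \code{min_risk} patients: with delayed entry the
#' product-limit estimate is unstable over the sparse earliest risk sets,
#' so observation and prediction both start accumulating there.
#'
#' @param panel a \code{panel_dataset} with event records for the outcome.
#' @param bundle a [coefficient_bundle()].
#' @param outcome one of \code{AF}, \code{ALB}, \code{PVD},
#'   \code{EGFR_LT60}.
#' @param min_risk minimum risk-set size defining the conditioning
#'   duration.
#' @return a data frame of class \code{incidence_comparison}: one row per
#'   integer duration with observed KM cumulative incidence and its CI,
#'   the simulated (predicted) cumulative incidence and the number at
#'   risk.
#' @export
km_vs_simulated <- function(panel, bundle, outcome, min_risk = 50L) {
  outcome <- match.arg(outcome, OUTCOMES)
  ev <- panel$events[panel$events$outcome == outcome, , drop = FALSE]
  if (nrow(ev) == 0L || sum(ev$event) == 0L) {
    warning("no events for '", outcome, "': degenerate comparison")
  }
  coef <- bundle$survival[[outcome]]
  epi <- build_episodes(panel, outcome, coef$covariate_spec)
  epi$bin <- floor(epi$entry + 1e-9)

  # conditioning duration: first integer bin with an adequate risk set
  risk_by_bin <- table(epi$bin)
  ok_bins <- as.integer(names(risk_by_bin))[risk_by_bin >= min_risk]
  if (!length(ok_bins)) stop("no duration bin reaches min_risk = ",
                             min_risk, call. = FALSE)
  d_min <- min(ok_bins)
  # contiguous adequately-populated duration range
  d_max <- d_min
  while ((d_max + 1L) %in% ok_bins) d_max <- d_max + 1L
  ev <- ev[ev$exit > d_min, , drop = FALSE]
  ev$entry <- pmax(ev$entry, d_min)
  epi <- epi[epi$bin >= d_min & epi$bin <= d_max, , drop = FALSE]

  km <- survival::survfit(
    survival::Surv(entry, exit, event) ~ 1,
    data = ev, conf.type = "log", conf.int = 0.95)
  # episode columns are already the resolved covariates; dot product directly
  eta <- rep(coef$betas[["constant"]], nrow(epi))
  for (nm in coef$covariate_spec) eta <- eta + coef$betas[[nm]] * epi[[nm]]
  # split each episode's realized at-risk time at integer bin boundaries
  # and pool fitted cumulative-hazard increments as occurrence/exposure
  split_piece <- function(a, b, eta_) {
    dH <- cumulative_hazard(coef, eta_, b) - cumulative_hazard(coef, eta_, a)
    data.frame(bin = floor(a + 1e-9), dH = dH, py = b - a)
  }
  a <- epi$entry
  b <- epi$exit
  cut <- pmin(floor(a + 1e-9) + 1, b)
  pieces <- rbind(split_piece(a, cut, eta),
                  split_piece(cut, b, eta)[cut < b, , drop = FALSE])
  pieces <- pieces[pieces$py > 1e-12 & pieces$bin >= d_min &
                     pieces$bin <= d_max, , drop = FALSE]
  m_k <- tapply(pieces$dH, pieces$bin, sum) /
    tapply(pieces$py, pieces$bin, sum)
  bins <- as.integer(names(m_k))
  q_k <- -expm1(-as.numeric(m_k))
  pred_ci <- 1 - cumprod(1 - q_k)
  n_risk <- as.integer(table(factor(epi$bin, levels = bins)))

  # read KM at the end of each bin
  eval_t <- bins + 1
  s <- summary(km, times = eval_t, extend = TRUE)
  out <- data.frame(
    duration = eval_t, n_risk = n_risk,
    observed_ci = 1 - s$surv,
    ci_lower = 1 - s$upper, ci_upper = 1 - s$lower,
    simulated_ci = pred_ci)
  rownames(out) <- NULL
  class(out) <- c("incidence_comparison", class(out))
  out
}
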