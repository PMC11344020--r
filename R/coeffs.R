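#' Coefficients of a first-order dynamic risk-factor equation
#'
#' One continuous risk factor's annual update equation
#' \deqn{y_{t} = \phi_0 + \phi_1 y_{t-1} + \phi_2 y_{0} + \phi_3 female +
#'   \phi_4 ethnicity + \phi_5 age + \phi_6 \ln(duration) + \mu_i +
#'   \epsilon_{t}}
#' where \eqn{y_0} is the first recorded value of the factor, ethnicity
#' effects are relative to the "other" reference group, age is age at
#' randomisation and \eqn{\mu_i} is a time-invariant patient random effect.
#'
#' The residual and random-effect standard deviations are optional (default
#' 0, i.e. a deterministic expected-value equation); the estimation module
#' fills them in when refitting.
#'
#' @param risk_factor one of the seven continuous risk-factor identifiers
#'   (see \link{riskpath-vocabulary}).
#' @param phi0 constant.
#' @param phi1 weight of last year's value; must satisfy \code{abs(phi1) < 1}
#'   for a stable (mean-reverting) path.
#' @param phi2 weight of the first recorded value.
#' @param phi3 additive female effect.
#' @param phi4_white,phi4_black,phi4_asian additive ethnicity effects versus
#'   the "other" reference group.
#' @param phi5 per-year effect of age at randomisation.
#' @param phi6 effect of \code{ln(duration of diabetes)}.
#' @param resid_sd,re_sd residual and patient random-effect standard
#'   deviations (>= 0).
#' @return an object of class \code{dynamic_coefficients}.
#' @export
#' @examples
#' dc <- dynamic_coefficients("hba1c", phi0 = 2.945, phi1 = 0.456,
#'   phi2 = 0.243, phi3 = 0.031, phi4_white = -0.082, phi4_black = 0.065,
#'   phi4_asian = -0.091, phi5 = -0.012, phi6 = 0.083)
dynamic_coefficients <- function(risk_factor, phi0, phi1, phi2, phi3,
                                 phi4_white, phi4_black, phi4_asian,
                                 phi5, phi6, resid_sd = 0, re_sd = 0) {
  risk_factor <- match.arg(risk_factor, RISK_FACTORS)
  num <- function(x) if (is.numeric(x)) as.numeric(x) else x
  obj <- structure(
    list(risk_factor = risk_factor, phi0 = num(phi0), phi1 = num(phi1),
         phi2 = num(phi2), phi3 = num(phi3), phi4_white = num(phi4_white),
         phi4_black = num(phi4_black), phi4_asian = num(phi4_asian),
         phi5 = num(phi5), phi6 = num(phi6), resid_sd = num(resid_sd),
         re_sd = num(re_sd)),
    class = "dynamic_coefficients")
  validate_dynamic_coefficients(obj)
}

validate_dynamic_coefficients <- function(x) {
  num <- c("phi0", "phi1", "phi2", "phi3", "phi4_white", "phi4_black",
           "phi4_asian", "phi5", "phi6", "resid_sd", "re_sd")
  for (f in num) {
    v <- x[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("dynamic equation '", x$risk_factor, "': field '", f,
           "' must be a single finite number", call. = FALSE)
    }
  }
  # |phi1| < 1 is the stability condition; phi1 = 1 exactly is tolerated so
  # that the last-observation-carried-forward comparator can be expressed
  if (abs(x$phi1) > 1) {
    stop("dynamic equation '", x$risk_factor, "': |phi1| must be <= 1 ",
         "(got ", x$phi1, "); the autoregressive path would diverge",
         call. = FALSE)
  }
  if (x$resid_sd < 0 || x$re_sd < 0) {
    stop("dynamic equation '", x$risk_factor,
         "': resid_sd and re_sd must be >= 0", call. = FALSE)
  }
  x
}

#' Coefficients of a Weibull proportional-hazards condition equation
#'
#' An absorbing condition's hazard on the diabetes-duration time scale:
#' \eqn{h(t) = \gamma t^{\gamma-1} e^{x'\beta}} with
#' \eqn{\gamma = e^{ln\_gamma}}, so the cumulative hazard is
#' \eqn{H(t) = e^{x'\beta} t^{\gamma}}.
#'
#' @param outcome one of \code{AF}, \code{ALB}, \code{PVD},
#'   \code{EGFR_LT60}.
#' @param betas named numeric vector of coefficients including
#'   \code{constant}; names from the controlled covariate vocabulary.
#' @param ln_gamma log Weibull shape.
#' @param covariate_spec ordered character vector naming the non-constant
#'   covariates; defaults to the order of \code{betas}.
#' @param distribution hazard family; the published equations are Weibull,
#'   the estimation module can also produce exponential and Gompertz fits
#'   (for which \code{ln_gamma} stores the shape parameter on its natural
#'   scale: fixed 0 for exponential, the rate slope for Gompertz).
#' @return an object of class \code{survival_coefficients}.
#' @export
survival_coefficients <- function(outcome, betas, ln_gamma,
                                  covariate_spec = NULL,
                                  distribution = c("weibull", "exponential",
                                                   "gompertz")) {
  outcome <- match.arg(outcome, OUTCOMES)
  distribution <- match.arg(distribution)
  betas <- unlist(betas)
  if (is.numeric(betas)) storage.mode(betas) <- "double"
  if (is.numeric(ln_gamma)) ln_gamma <- as.numeric(ln_gamma)
  if (is.null(covariate_spec)) {
    covariate_spec <- setdiff(names(betas), "constant")
  }
  obj <- structure(
    list(outcome = outcome, betas = betas, ln_gamma = ln_gamma,
         covariate_spec = covariate_spec, distribution = distribution),
    class = "survival_coefficients")
  validate_survival_coefficients(obj)
}

validate_survival_coefficients <- function(x) {
  if (is.null(names(x$betas)) || any(names(x$betas) == "")) {
    stop("survival equation '", x$outcome, "': betas must be named",
         call. = FALSE)
  }
  if (!"constant" %in% names(x$betas)) {
    stop("survival equation '", x$outcome, "': betas must include ",
         "'constant'", call. = FALSE)
  }
  bad <- setdiff(names(x$betas), c("constant", x$covariate_spec))
  if (length(bad)) {
    stop("survival equation '", x$outcome, "': covariate(s) ",
         paste0("'", bad, "'", collapse = ", "),
         " not listed in covariate_spec", call. = FALSE)
  }
  if (!all(is.finite(x$betas))) {
    stop("survival equation '", x$outcome, "': non-finite beta for '",
         names(x$betas)[!is.finite(x$betas)][1L], "'", call. = FALSE)
  }
  if (!is.numeric(x$ln_gamma) || length(x$ln_gamma) != 1L ||
      !is.finite(x$ln_gamma)) {
    stop("survival equation '", x$outcome,
         "': ln_gamma must be a single finite number", call. = FALSE)
  }
  x
}

#' Coefficients of a censored-normal (Tobit) eGFR value equation
#'
#' Latent value \eqn{y^* = x'\beta + e}, \eqn{e \sim N(0, \sigma^2)},
#' observed/simulated within \code{(lower_limit, upper_limit)}. Two regimes
#' exist: \code{below60} (limits 0-60) and \code{atabove60} (lower limit 60).
#'
#' @param regime \code{"below60"} or \code{"atabove60"}.
#' @param betas named numeric vector including \code{constant}.
#' @param sigma forecast standard error, ml/min/1.73m2; must be > 0.
#' @param lower_limit,upper_limit censoring bounds; \code{upper_limit} may be
#'   \code{Inf}.
#' @return an object of class \code{tobit_coefficients}.
#' @export
tobit_coefficients <- function(regime = c("below60", "atabove60"), betas,
                               sigma, lower_limit = NULL,
                               upper_limit = NULL) {
  regime <- match.arg(regime)
  if (is.null(lower_limit)) lower_limit <- if (regime == "below60") 0 else 60
  if (is.null(upper_limit)) upper_limit <- if (regime == "below60") 60 else Inf
  lower_limit <- as.numeric(lower_limit)
  upper_limit <- as.numeric(upper_limit)
  betas <- unlist(betas)
  if (is.numeric(betas)) storage.mode(betas) <- "double"
  if (is.numeric(sigma)) sigma <- as.numeric(sigma)
  obj <- structure(
    list(regime = regime, betas = betas, sigma = sigma,
         lower_limit = lower_limit, upper_limit = upper_limit),
    class = "tobit_coefficients")
  validate_tobit_coefficients(obj)
}

validate_tobit_coefficients <- function(x) {
  if (is.null(names(x$betas)) || !"constant" %in% names(x$betas)) {
    stop("tobit equation '", x$regime, "': betas must be named and include ",
         "'constant'", call. = FALSE)
  }
  if (!all(is.finite(x$betas))) {
    stop("tobit equation '", x$regime, "': non-finite beta for '",
         names(x$betas)[!is.finite(x$betas)][1L], "'", call. = FALSE)
  }
  if (!is.numeric(x$sigma) || length(x$sigma) != 1L || !(x$sigma > 0)) {
    stop("tobit equation '", x$regime, "': sigma must be > 0", call. = FALSE)
  }
  if (!(x$lower_limit < x$upper_limit)) {
    stop("tobit equation '", x$regime, "': lower_limit must be < upper_limit",
         call. = FALSE)
  }
  x
}

#' Bundle of all equation coefficients
#'
#' Container holding the seven dynamic equations, the four Weibull condition
#' equations and the two eGFR Tobit equations, plus a free-text provenance
#' label. A complete bundle is required by the simulator; partial bundles
#' (e.g. a single refitted equation) can be saved and loaded but are flagged.
#'
#' @param dynamic named list of [dynamic_coefficients()], keyed by risk
#'   factor.
#' @param survival named list of [survival_coefficients()], keyed by outcome.
#' @param tobit list with elements \code{below60} and \code{atabove60}.
#' @param provenance free-text source label.
#' @return an object of class \code{coefficient_bundle}.
#' @export
coefficient_bundle <- function(dynamic, survival, tobit, provenance = "") {
  obj <- structure(
    list(dynamic = dynamic, survival = survival, tobit = tobit,
         provenance = provenance),
    class = "coefficient_bundle")
  validate_coefficient_bundle(obj)
}

validate_coefficient_bundle <- function(x, require_complete = FALSE) {
  for (d in x$dynamic) validate_dynamic_coefficients(d)
  for (s in x$survival) validate_survival_coefficients(s)
  for (tb in x$tobit) validate_tobit_coefficients(tb)
  if (require_complete && !bundle_is_complete(x)) {
    miss <- c(setdiff(RISK_FACTORS, names(x$dynamic)),
              setdiff(OUTCOMES, names(x$survival)),
              setdiff(c("below60", "atabove60"), names(x$tobit)))
    stop("incomplete coefficient bundle: missing equation(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  x
}

#' @rdname coefficient_bundle
#' @param x a coefficient bundle.
#' @export
bundle_is_complete <- function(x) {
  all(RISK_FACTORS %in% names(x$dynamic)) &&
    all(OUTCOMES %in% names(x$survival)) &&
    all(c("below60", "atabove60") %in% names(x$tobit))
}

#' @export
print.coefficient_bundle <- function(x, ...) {
  cat("<coefficient_bundle>", if (bundle_is_complete(x)) "" else "(partial)",
      "\n")
  cat("  provenance:", x$provenance, "\n")
  cat("  dynamic equations: ", paste(names(x$dynamic), collapse = ", "),
      "\n")
  cat("  survival equations:", paste(names(x$survival), collapse = ", "),
      "\n")
  cat("  tobit equations:   ", paste(names(x$tobit), collapse = ", "), "\n")
  invisible(x)
}

#' Read and write coefficient bundles
#'
#' Coefficient files are human-editable JSON with top-level keys
#' \code{dynamic}, \code{survival}, \code{tobit}, \code{provenance} and
#' \code{partial}; numbers are decimal literals and covariate names come
#' from the controlled vocabulary (see \link{riskpath-vocabulary}). An
#' infinite upper Tobit limit is stored as \code{null}. Round-tripping
#' through [save_bundle()] and [load_bundle()] is lossless for every numeric
#' field.
#'
#' @param path file path.
#' @return [load_bundle()]: a validated [coefficient_bundle()];
#'   [save_bundle()]: \code{path}, invisibly.
#' @export
load_bundle <- function(path) {
  if (!file.exists(path)) stop("no such coefficient file: ", path,
                               call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  dyn <- lapply(raw$dynamic, function(d) {
    do.call(dynamic_coefficients, c(
      d[c("risk_factor", "phi0", "phi1", "phi2", "phi3", "phi4_white",
          "phi4_black", "phi4_asian", "phi5", "phi6")],
      list(resid_sd = d$resid_sd %||% 0, re_sd = d$re_sd %||% 0)))
  })
  surv <- lapply(raw$survival, function(s) {
    survival_coefficients(
      outcome = s$outcome, betas = unlist(s$betas), ln_gamma = s$ln_gamma,
      covariate_spec = unlist(s$covariate_spec),
      distribution = s$distribution %||% "weibull")
  })
  tob <- lapply(raw$tobit, function(tb) {
    tobit_coefficients(
      regime = tb$regime, betas = unlist(tb$betas), sigma = tb$sigma,
      lower_limit = tb$lower_limit %||% -Inf,
      upper_limit = tb$upper_limit %||% Inf)
  })
  b <- coefficient_bundle(dynamic = dyn, survival = surv, tobit = tob,
                          provenance = raw$provenance %||% "")
  validate_coefficient_bundle(b, require_complete = FALSE)
  b
}

#' @rdname load_bundle
#' @param bundle a [coefficient_bundle()].
#' @export
save_bundle <- function(bundle, path) {
  validate_coefficient_bundle(bundle)
  ser_tobit <- function(tb) {
    tb <- unclass(tb)
    if (is.infinite(tb$upper_limit)) tb$upper_limit <- NULL
    if (is.infinite(tb$lower_limit)) tb$lower_limit <- NULL
    tb$betas <- as.list(tb$betas)
    tb
  }
  ser_surv <- function(s) {
    s <- unclass(s)
    s$betas <- as.list(s$betas)
    s
  }
  out <- list(
    provenance = bundle$provenance,
    partial = !bundle_is_complete(bundle),
    dynamic = lapply(bundle$dynamic, unclass),
    survival = lapply(bundle$survival, ser_surv),
    tobit = lapply(bundle$tobit, ser_tobit))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' The published coefficient set
#'
#' Loads the bundled coefficient file transcribing the published pooled-trial
#' equations: seven dynamic risk-factor equations, four Weibull condition
#' equations and two eGFR Tobit equations, at the printed three-decimal
#' precision. Residual and random-effect standard deviations of the dynamic
#' equations were not published and default to 0 (deterministic expected-value
#' simulation); set them explicitly for stochastic continuous paths.
#'
#' @return a complete [coefficient_bundle()].
#' @export
#' @examples
#' b <- default_bundle()
#' b$dynamic$hba1c$phi1
default_bundle <- function() {
  path <- system.file("extdata", "coefficients_published.json",
                      package = "riskpath", mustWork = TRUE)
  b <- load_bundle(path)
  validate_coefficient_bundle(b, require_complete = TRUE)
}
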