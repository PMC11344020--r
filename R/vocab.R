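#' Controlled vocabulary
#'
#' Identifiers used throughout the package for risk factors, absorbing
#' outcomes and equation covariates.
#'
#' Continuous risk factors (units fixed by convention, no automatic
#' conversion):
#' \describe{
#'   \item{hdl}{HDL cholesterol, mmol/l}
#'   \item{ldl}{LDL cholesterol, mmol/l}
#'   \item{sbp}{systolic blood pressure, mmHg}
#'   \item{hba1c}{glycated haemoglobin, \%}
#'   \item{haemoglobin}{haemoglobin, g/dl}
#'   \item{heart_rate}{heart rate, bpm}
#'   \item{bmi}{body mass index, kg/m2}
#' }
#'
#' Absorbing outcomes: \code{AF} (atrial fibrillation), \code{ALB} (micro- or
#' macroalbuminuria), \code{PVD} (peripheral vascular disease),
#' \code{EGFR_LT60} (eGFR below 60 ml/min/1.73m2).
#'
#' Covariate names understood by the survival and Tobit equations:
#' \code{constant}, \code{age_at_rand}, \code{female}, \code{eth_white},
#' \code{eth_black}, \code{eth_asian}, \code{smoker_baseline},
#' \code{ln_duration}, \code{lag:<factor>} (last year's value of a continuous
#' factor or of \code{egfr}), \code{first:<factor>} (first recorded value).
#'
#' @name riskpath-vocabulary
#' @keywords internal
NULL

# canonical orderings: fixed so that random-number block layout is stable
RISK_FACTORS <- c("hdl", "ldl", "sbp", "hba1c", "haemoglobin", "heart_rate",
                  "bmi")
OUTCOMES <- c("AF", "ALB", "PVD", "EGFR_LT60")
ETHNICITIES <- c("white", "black", "asian", "other")

# flag column in a cohort table for each outcome
flag_column <- function(outcome) tolower(outcome)

#' Resolve one named covariate from a cohort table
#'
#' Maps a controlled-vocabulary covariate name to a numeric vector, one value
#' per patient row. \code{ln_duration} floors duration at 0.5 years before
#' logging. Raises an error naming the covariate if the column is absent or
#' contains missing values: the simulator never imputes silently.
#'
#' @param name covariate name from the controlled vocabulary.
#' @param state cohort table (see [as_cohort()]).
#' @return numeric vector of length \code{nrow(state)}.
#' @keywords internal
resolve_covariate <- function(name, state) {
  n <- nrow(state)
  val <- if (name == "constant") {
    rep(1, n)
  } else if (name %in% c("age_at_rand", "female", "smoker_baseline")) {
    state[[name]]
  } else if (name %in% paste0("eth_", c("white", "black", "asian"))) {
    eth <- sub("^eth_", "", name)
    as.numeric(state[["ethnicity"]] == eth)
  } else if (name == "ln_duration") {
    log(pmax(state[["duration"]], 0.5))
  } else if (startsWith(name, "lag:")) {
    state[[sub("^lag:", "", name)]]
  } else if (startsWith(name, "first:")) {
    state[[paste0("first_", sub("^first:", "", name))]]
  } else {
    stop("unknown covariate name: '", name, "'", call. = FALSE)
  }
  if (is.null(val)) {
    stop("missing covariate: '", name, "' cannot be resolved from the ",
         "cohort table", call. = FALSE)
  }
  val <- as.numeric(val)
  if (anyNA(val)) {
    stop("missing covariate: '", name, "' has NA values for patient(s) ",
         paste(utils::head(state$id[is.na(val)], 5L), collapse = ", "),
         call. = FALSE)
  }
  val
}

# linear predictor x'beta for a named coefficient vector over a cohort table
linear_predictor <- function(betas, state) {
  eta <- numeric(nrow(state))
  for (nm in names(betas)) {
    eta <- eta + betas[[nm]] * resolve_covariate(nm, state)
  }
  eta
}
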