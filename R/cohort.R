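#' Patient-state (cohort) tables
#'
#' A cohort is a plain data frame with one row per patient. Columns:
#' \describe{
#'   \item{id}{patient identifier (character or integer).}
#'   \item{age_at_rand}{age at randomisation, years.}
#'   \item{female}{0/1.}
#'   \item{ethnicity}{one of \code{white}, \code{black}, \code{asian},
#'     \code{other}.}
#'   \item{smoker_baseline}{0/1, smoking at randomisation.}
#'   \item{duration}{years since diabetes diagnosis (> 0).}
#'   \item{hdl, ldl, sbp, hba1c, haemoglobin, heart_rate, bmi}{current (last
#'     observed or last simulated) values of the continuous risk factors.}
#'   \item{egfr}{current eGFR, ml/min/1.73m2.}
#'   \item{first_hdl, ..., first_bmi, first_egfr}{first recorded values
#'     (the \eqn{y_0} store of the dynamic equations).}
#'   \item{af, alb, pvd, egfr_lt60}{logical absorbing condition flags.}
#' }
#'
#' `as_cohort()` validates a data frame against this contract, filling
#' `first_*` columns from the current values and flags from `FALSE` (except
#' `egfr_lt60`, which defaults to `egfr < 60`) when absent.
#'
#' @param x a data frame.
#' @return the validated cohort data frame.
#' @export
#' @examples
#' as_cohort(data.frame(id = 1, age_at_rand = 64, female = 0,
#'   ethnicity = "white", smoker_baseline = 0, duration = 16,
#'   hdl = 1.1, ldl = 2.2, sbp = 135, hba1c = 7.5, haemoglobin = 13.8,
#'   heart_rate = 72, bmi = 31, egfr = 75))
as_cohort <- function(x) {
  x <- as.data.frame(x)
  need <- c("id", "age_at_rand", "female", "ethnicity", "smoker_baseline",
            "duration", RISK_FACTORS, "egfr")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("cohort table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(x$id)) stop("cohort ids must be unique", call. = FALSE)
  x$ethnicity <- as.character(x$ethnicity)
  bad_eth <- !x$ethnicity %in% ETHNICITIES
  if (any(bad_eth)) {
    stop("unknown ethnicity for patient(s) ",
         paste(utils::head(x$id[bad_eth], 5L), collapse = ", "),
         " (expected one of ", paste(ETHNICITIES, collapse = ", "), ")",
         call. = FALSE)
  }
  for (f in c(RISK_FACTORS, "egfr")) {
    fc <- paste0("first_", f)
    if (is.null(x[[fc]])) x[[fc]] <- x[[f]]
  }
  for (o in OUTCOMES) {
    fc <- flag_column(o)
    if (is.null(x[[fc]])) {
      x[[fc]] <- if (o == "EGFR_LT60") x$egfr < 60 else
        rep(FALSE, nrow(x))
    }
    x[[fc]] <- as.logical(x[[fc]])
  }
  check_cohort(x)
  x
}

# hard validation of an already-shaped cohort table
check_cohort <- function(x) {
  if (any(!is.finite(x$duration)) || any(x$duration <= 0)) {
    stop("cohort: duration must be finite and > 0", call. = FALSE)
  }
  vals <- c(RISK_FACTORS, "egfr",
            paste0("first_", c(RISK_FACTORS, "egfr")))
  for (f in vals) {
    v <- x[[f]]
    bad <- !is.finite(v) | v <= 0
    if (any(bad)) {
      stop("cohort: column '", f, "' must be finite and positive; ",
           "offending patient(s): ",
           paste(utils::head(x$id[bad], 5L), collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(x)
}

#' Read a cohort from a delimited text file
#'
#' Thin wrapper over [utils::read.delim()] + [as_cohort()]. The file must be
#' tab- or comma-separated with a header row using the documented column
#' vocabulary.
#'
#' @param path file path.
#' @param sep field separator; inferred from the file extension by default
#'   (".csv" = comma, otherwise tab).
#' @return a cohort data frame.
#' @export
read_cohort <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  as_cohort(utils::read.table(path, header = TRUE, sep = sep,
                              stringsAsFactors = FALSE))
}
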