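#' Plausibility ranges for raw measurements
#'
#' Placeholder per-variable plausibility ranges used by [preprocess_panel()]
#' to drop implausible raw measurements. These are package defaults chosen
#' to bracket clinically conceivable values; override them to match a
#' study's own data-cleaning protocol.
#'
#' @return named list of \code{c(lower, upper)} ranges.
#' @export
default_ranges <- function() {
  list(hdl = c(0.2, 5), ldl = c(0.2, 10), sbp = c(60, 250),
       hba1c = c(3, 20), haemoglobin = c(5, 25), heart_rate = c(30, 200),
       bmi = c(10, 80), egfr = c(1, 250))
}

#' Annualize and clean raw visit-level measurements
#'
#' Applies the data-preparation rules used before estimation:
#' \enumerate{
#'   \item post-baseline measurements taken less than six months after the
#'     start of randomised treatment are dropped (initial treatment
#'     effect);
#'   \item values outside the per-variable plausibility ranges are dropped;
#'   \item surviving measurements are averaged within patient-year
#'     (year \eqn{k} covers months \eqn{(12(k-1), 12k]}; month <= 0 is the
#'     baseline year 0);
#'   \item patients are excluded per variable when they have no baseline
#'     value or no post-baseline value, and globally when they withdrew on
#'     the randomisation day or have missing ethnicity.
#' }
#' Every exclusion is counted in the returned log.
#'
#' @param raw long-format data frame with columns \code{id}, \code{month}
#'   (months since randomisation; <= 0 marks the baseline visit),
#'   \code{variable} (controlled vocabulary) and \code{value}.
#' @param demographics one row per patient: \code{id}, \code{age_at_rand},
#'   \code{female}, \code{ethnicity} (may be \code{NA}),
#'   \code{smoker_baseline}, \code{duration} (at randomisation).
#' @param ranges plausibility ranges, as [default_ranges()].
#' @param min_months post-baseline measurements earlier than this are
#'   dropped (default 6).
#' @return a \code{panel_dataset} with \code{visits} (annualized wide
#'   table), an empty \code{events} table (condition histories are not part
#'   of the raw measurement stream), and attribute \code{exclusion_log}
#'   (named counts of dropped measurements and excluded patients).
#' @export
preprocess_panel <- function(raw, demographics, ranges = default_ranges(),
                             min_months = 6) {
  need <- c("id", "month", "variable", "value")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("raw table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  log <- list()
  bad_row <- !is.finite(raw$value) | is.na(raw$variable) | is.na(raw$month)
  if (any(bad_row)) {
    warning(sum(bad_row), " unparseable raw row(s) skipped")
    raw <- raw[!bad_row, , drop = FALSE]
  }
  log$unparseable_rows <- sum(bad_row)

  # rule 1: drop early post-baseline measurements
  early <- raw$month > 0 & raw$month < min_months
  log$dropped_lt6_months <- sum(early)
  raw <- raw[!early, , drop = FALSE]

  # rule 2: plausibility ranges
  out_of_range <- rep(FALSE, nrow(raw))
  for (v in names(ranges)) {
    sel <- raw$variable == v
    out_of_range[sel] <- raw$value[sel] < ranges[[v]][1L] |
      raw$value[sel] > ranges[[v]][2L]
  }
  log$dropped_out_of_range <- sum(out_of_range)
  raw <- raw[!out_of_range, , drop = FALSE]

  # global exclusions: withdrawal on randomisation day, missing ethnicity
  max_month <- tapply(raw$month, raw$id, max)
  withdrew <- names(max_month)[max_month <= 0]
  log$excluded_withdrawal_day0 <- length(withdrew)
  no_eth <- demographics$id[is.na(demographics$ethnicity)]
  log$excluded_missing_ethnicity <- length(no_eth)
  drop_ids <- union(withdrew, no_eth)
  raw <- raw[!raw$id %in% drop_ids, , drop = FALSE]
  demographics <- demographics[!demographics$id %in% drop_ids, ,
                               drop = FALSE]

  # rule 3: annualize (mean within patient-year)
  raw$year <- ifelse(raw$month <= 0, 0L, ceiling(raw$month / 12))
  agg <- stats::aggregate(value ~ id + variable + year, data = raw,
                          FUN = mean)

  # rule 4: per-variable exclusions
  log$excluded_no_baseline <- 0L
  log$excluded_no_followup <- 0L
  keep <- rep(TRUE, nrow(agg))
  for (v in unique(agg$variable)) {
    sv <- agg[agg$variable == v, ]
    has_base <- unique(sv$id[sv$year == 0])
    has_fup <- unique(sv$id[sv$year > 0])
    no_base <- setdiff(unique(sv$id), has_base)
    no_fup <- setdiff(has_base, has_fup)
    log$excluded_no_baseline <- log$excluded_no_baseline + length(no_base)
    log$excluded_no_followup <- log$excluded_no_followup + length(no_fup)
    keep[agg$variable == v & agg$id %in% c(no_base, no_fup)] <- FALSE
  }
  agg <- agg[keep, , drop = FALSE]

  wide <- stats::reshape(agg, idvar = c("id", "year"),
                         timevar = "variable", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  visits <- merge(demographics, wide, by = "id")
  visits$duration <- visits$duration + visits$year
  visits <- visits[order(visits$id, visits$year), , drop = FALSE]
  rownames(visits) <- NULL

  out <- structure(list(visits = visits,
                        events = data.frame(id = character(),
                                            outcome = character(),
                                            entry = numeric(),
                                            exit = numeric(),
                                            event = integer()),
                        baseline = NULL, follow_up = max(visits$year),
                        bundle_provenance = ""),
                   class = "panel_dataset")
  attr(out, "exclusion_log") <- log
  out
}
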