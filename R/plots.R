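#' Plot an observed-versus-predicted time-path comparison
#'
#' Observed means with their 95\% confidence band by diabetes duration,
#' overlaid with the model-predicted means. Requires ggplot2.
#'
#' @param comparison a \code{timepath_comparison} from
#'   [timepath_agreement()].
#' @param title optional plot title.
#' @return a ggplot object.
#' @export
plot_timepath <- function(comparison, title = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ggplot2::ggplot(comparison, ggplot2::aes(x = .data$duration)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lower,
                                      ymax = .data$ci_upper),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed_mean,
                                    colour = "observed")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted_mean,
                                    colour = "predicted")) +
    ggplot2::labs(x = "diabetes duration (years)", y = "mean value",
                  colour = NULL, title = title) +
    ggplot2::theme_minimal()
}

#' Plot observed versus simulated cumulative incidence
#'
#' Kaplan-Meier observed cumulative incidence (with its confidence band)
#' against the model-predicted curve, by diabetes duration.
#'
#' @param comparison an \code{incidence_comparison} from
#'   [km_vs_simulated()].
#' @param title optional plot title.
#' @return a ggplot object.
#' @export
plot_incidence <- function(comparison, title = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ggplot2::ggplot(comparison, ggplot2::aes(x = .data$duration)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lower,
                                      ymax = .data$ci_upper),
                         fill = "grey80") +
    ggplot2::geom_step(ggplot2::aes(y = .data$observed_ci,
                                    colour = "observed")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$simulated_ci,
                                    colour = "simulated")) +
    ggplot2::labs(x = "diabetes duration (years)",
                  y = "cumulative incidence", colour = NULL,
                  title = title) +
    ggplot2::theme_minimal()
}
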