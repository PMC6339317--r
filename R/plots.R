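#' Plot a daily-dose distribution
#'
#' Bar chart of the joint (daily units, strength) distribution of one
#' drug: one bar group per strength, filled by daily-unit total.
#'
#' @param object A `medex_dose_distribution` from
#'   [aggregate_dose_distribution()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot medex_dose_distribution
#' @export
autoplot.medex_dose_distribution <- function(object, ...) {
  drug <- attr(object, "drug")
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = factor(strength), y = proportion,
                 fill = factor(daily_units))
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(x) {
      paste0(round(100 * x, 1), "%")
    }) +
    ggplot2::labs(
      x = sprintf("strength [%s]",
                  paste(unique(stats::na.omit(object$unit)),
                        collapse = "/")),
      y = "share of instructions",
      fill = "daily units",
      title = if (is.na(drug)) "Daily-dose distribution" else
        sprintf("Daily-dose distribution: %s", drug)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a medication-prevalence trend
#'
#' Line chart of prevalence percentage per period, one line per drug
#' group.
#'
#' @param object A `medex_trend` from [drug_prevalence_trend()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot medex_trend
#' @export
autoplot.medex_trend <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = period_label, y = percent, colour = group_label,
                 group = group_label)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "period", y = "cases with drug [%]",
                  colour = "drug group") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
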