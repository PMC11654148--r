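#' Forest plot of a disproportionality screen
#'
#' Reporting odds ratios with their 95% confidence intervals on a log scale,
#' one row per term, signals highlighted. With many terms only the
#' `max_terms` most reported are drawn.
#'
#' @param object A `faers_signals` object.
#' @param max_terms Maximum number of terms to draw (by descending case
#'   count).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot faers_signals
#' @export
autoplot.faers_signals <- function(object, max_terms = 30, ...) {
  df <- as_tibble(unclass_result(object)) |>
    arrange(desc(.data$n)) |>
    head(max_terms) |>
    mutate(term = stats::reorder(.data$term, .data$ror))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ror, y = .data$term,
                                   colour = .data$signal)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ror025,
                                         xmax = .data$ror975),
                            height = 0.25) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n)) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#c0392b",
                                            `FALSE` = "grey55"),
                                 name = "signal") +
    ggplot2::scale_size_continuous(name = "cases") +
    ggplot2::labs(x = "reporting odds ratio (95% CI)", y = NULL,
                  title = sprintf("Disproportionality screen (%s level)",
                                  toupper(attr(object, "level") %||% ""))) +
    ggplot2::theme_minimal()
}

#' Forest plot of the combination-therapy screen
#'
#' @param object A `faers_combo_signals` object.
#' @param ... Unused.
#' @return A ggplot object, faceted by ICI.
#' @method autoplot faers_combo_signals
#' @export
autoplot.faers_combo_signals <- function(object, ...) {
  df <- as_tibble(unclass_result(object)) |>
    mutate(term = stats::reorder(.data$term, .data$ror))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ror, y = .data$term,
                                   colour = .data$signal)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ror025,
                                         xmax = .data$ror975),
                            height = 0.25) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n)) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#c0392b",
                                            `FALSE` = "grey55"),
                                 name = "signal") +
    ggplot2::facet_wrap(~ici, scales = "free_y") +
    ggplot2::labs(x = "reporting odds ratio (95% CI)", y = NULL,
                  title = "Combination-therapy comparator screen") +
    ggplot2::theme_minimal()
}

#' Bar chart of a demographics summary
#'
#' @param object A `faers_demographics` object.
#' @param ... Unused.
#' @return A ggplot object, one facet per section.
#' @method autoplot faers_demographics
#' @export
autoplot.faers_demographics <- function(object, ...) {
  df <- as_tibble(unclass_result(object)) |>
    mutate(label = factor(.data$label, levels = rev(unique(.data$label))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$label)) +
    ggplot2::geom_col(fill = "#2c6e91") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", .data$pct)),
                       hjust = -0.1, size = 3) +
    ggplot2::facet_wrap(~section, scales = "free_y") +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0, 0.2))) +
    ggplot2::labs(x = "reports", y = NULL,
                  title = sprintf("Cohort demographics (n = %d)",
                                  attr(object, "total"))) +
    ggplot2::theme_minimal()
}
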