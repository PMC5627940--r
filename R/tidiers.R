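#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a condition result
#'
#' @param x a `condition_result`.
#' @param ... unused.
#' @return The per-run, per-cycle metric tibble.
#' @export
tidy.condition_result <- function(x, ...) x$metrics

#' Tidy a virtual trial
#'
#' @param x a `virtual_trial`.
#' @param ... unused.
#' @return Tibble with `condition`, `run`, `cycle`, `metric`, `value`.
#' @export
tidy.virtual_trial <- function(x, ...) x$metrics

#' One-row-per-condition summary of a virtual trial
#'
#' @param x a `virtual_trial` with control and no-intervention arms.
#' @param ... unused.
#' @return Tibble with one row per condition and one performance-ratio
#'   column per metric category.
#' @export
glance.virtual_trial <- function(x, ...) {
  performance_scores(x) |>
    dplyr::select("condition", "category", "ratio") |>
    tidyr::pivot_wider(names_from = "category", values_from = "ratio",
                       names_prefix = "ratio_")
}

#' Trajectory plot of a virtual trial
#'
#' Mean over runs with a plus/minus one standard deviation ribbon, per
#' metric and condition, over virtual time.
#'
#' @param object a `virtual_trial`.
#' @param metrics metrics to show (default: all present).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.virtual_trial <- function(object, metrics = NULL, ...) {
  df <- object$metrics
  if (!is.null(metrics)) df <- dplyr::filter(df, .data$metric %in% metrics)
  summ <- df |>
    dplyr::group_by(.data$condition, .data$cycle, .data$metric) |>
    dplyr::summarize(m = mean(.data$value, na.rm = TRUE),
                     s = sd(.data$value, na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$cycle, y = .data$m,
                                     colour = .data$condition,
                                     fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$m - .data$s,
                                      ymax = .data$m + .data$s),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "virtual time (degeneration cycle)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Node strength versus original degree
#'
#' Scatter of normalized node strength against original structural degree
#' at selected cycles, with a least-squares trend line per cycle: the
#' hub-vulnerability view of structural damage.
#'
#' @param result a `condition_result`.
#' @param cycles cycles to display (default: an early, middle and final
#'   cycle).
#' @return A ggplot object.
#' @export
plot_node_strength <- function(result, cycles = NULL) {
  ns <- result$node_strength
  if (is.null(cycles)) {
    cmax <- max(ns$cycle)
    cycles <- unique(pmax(1, round(c(cmax / 4, cmax / 2, cmax))))
  }
  df <- ns |>
    dplyr::filter(.data$cycle %in% cycles) |>
    dplyr::group_by(.data$cycle, .data$node, .data$degree0) |>
    dplyr::summarize(strength_ratio = mean(.data$strength_ratio),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree0,
                                   y = .data$strength_ratio)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::facet_wrap(~cycle, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "original degree", y = "normalized node strength") +
    ggplot2::theme_minimal()
}
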