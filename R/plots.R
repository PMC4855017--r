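strategy_labels <- c(
  usual_care = "Usual care", pdt = "Verteporfin PDT",
  ranibizumab = "Ranibizumab", bevacizumab = "Bevacizumab"
)

#' Plot cost-effectiveness acceptability curves
#'
#' Probability that each strategy is the optimal choice (greatest net
#' monetary benefit) across willingness-to-pay values, with dashed
#' verticals at 1x and 3x per-capita GDP.
#'
#' @param object An `amd_ceac` from [compute_ceac()].
#' @param gdp Per-capita GDP for the threshold guides (default 7480).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot amd_ceac
#' @export
autoplot.amd_ceac <- function(object, gdp = 7480, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$wtp, y = .data$probability, colour = .data$strategy
  )) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = c(gdp, 3 * gdp), linetype = "dashed",
      colour = "grey40") +
    ggplot2::scale_colour_discrete(labels = strategy_labels, name = NULL) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Willingness to pay (US$/QALY)",
      y = "Probability cost-effective",
      title = "Cost-effectiveness acceptability curves"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the cost-effectiveness plane of a PSA
#'
#' Incremental cost versus incremental QALYs of each strategy against the
#' reference, one point per draw, with the willingness-to-pay threshold as
#' a line through the origin.
#'
#' @param object An `amd_psa` from [run_psa()].
#' @param wtp Threshold slope to draw (default: the PSA's).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot amd_psa
#' @export
autoplot.amd_psa <- function(object, wtp = attr(object, "wtp"), ...) {
  ref <- attr(object, "reference") %||% "usual_care"
  df <- object |> dplyr::filter(.data$strategy != ref)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$delta_qaly, y = .data$delta_cost, colour = .data$strategy
  )) +
    ggplot2::geom_point(alpha = 0.3, size = 0.7) +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::scale_colour_discrete(labels = strategy_labels, name = NULL) +
    ggplot2::labs(
      x = paste0("Incremental QALYs vs ", strategy_labels[ref]),
      y = paste0("Incremental cost (US$) vs ", strategy_labels[ref]),
      title = "Cost-effectiveness plane"
    ) +
    ggplot2::theme_minimal()
}

#' Tornado diagram of one-way sensitivity results
#'
#' Horizontal bars spanning the ICER at the low and high bound of each
#' parameter, ordered by impact, with the base-case ICER as a vertical
#' line.
#'
#' @param object An `amd_tornado` from [run_tornado()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot amd_tornado
#' @export
autoplot.amd_tornado <- function(object, ...) {
  df <- object |>
    dplyr::mutate(
      span = abs(.data$icer_high - .data$icer_low),
      parameter_id = stats::reorder(.data$parameter_id, .data$span)
    )
  base <- df$icer_base[1]
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter_id)) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$icer_low, xend = .data$icer_high,
      yend = .data$parameter_id
    ), linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base, linetype = "dashed") +
    ggplot2::labs(
      x = "ICER vs usual care (US$/QALY)", y = NULL,
      title = "One-way sensitivity (tornado)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a cohort trace
#'
#' State occupancy over time for a single cohort run.
#'
#' @param object An `amd_trace` from [run_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot amd_trace
#' @export
autoplot.amd_trace <- function(object, ...) {
  labs6 <- setNames(va_states()$label, paste0("occ_", va_states()$code))
  df <- tibble::as_tibble(object) |>
    dplyr::select("age", dplyr::starts_with("occ_")) |>
    tidyr::pivot_longer(-"age", names_to = "state", values_to = "occupancy") |>
    dplyr::mutate(state = factor(labs6[.data$state], levels = labs6))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$age, y = .data$occupancy, fill = .data$state
  )) +
    ggplot2::geom_area() +
    ggplot2::labs(
      x = "Cohort age (years)", y = "Occupancy",
      fill = "Visual acuity",
      title = paste0("Markov trace: ", strategy_labels[attr(object, "strategy")])
    ) +
    ggplot2::theme_minimal()
}
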