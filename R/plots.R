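#' Box-and-whisker plot of an ensemble quantity across periods
#'
#' @param x An `mo_pipeline` run (uses its per-period summaries).
#' @param quantity `"mo_sw_nM"` (seawater Mo, nM) or `"r_in_pct"` (input
#'   as % of the modern flux).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mo_pipeline <- function(x, quantity = c("r_in_pct", "mo_sw_nM"),
                                 ...) {
  quantity <- match.arg(quantity)
  s <- dplyr::filter(x$summaries, .data$quantity == !!quantity)
  lab <- if (quantity == "r_in_pct") {
    "Mo input (% of modern riverine flux)"
  } else {
    "Seawater [Mo] (nM)"
  }
  ggplot2::ggplot(s, ggplot2::aes(x = factor(
    .data$period, levels = period_constraints()$period))) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$whisker_lo, ymax = .data$whisker_hi),
      width = 0.25) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = as.numeric(factor(
        .data$period, levels = period_constraints()$period)) - 0.3,
        xmax = as.numeric(factor(
          .data$period, levels = period_constraints()$period)) + 0.3,
        ymin = .data$q1, ymax = .data$q3),
      fill = "grey85", colour = "black") +
    ggplot2::geom_segment(
      ggplot2::aes(x = as.numeric(factor(
        .data$period, levels = period_constraints()$period)) - 0.3,
        xend = as.numeric(factor(
          .data$period, levels = period_constraints()$period)) + 0.3,
        y = .data$median, yend = .data$median),
      linewidth = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = lab) +
    ggplot2::theme_minimal()
}

#' Plot an ensemble's seawater-Mo or input distribution
#'
#' @param object An `mo_ensemble` or `mo_filtered` tibble.
#' @param ... Unused.
#' @return A ggplot (log10 histograms of seawater Mo and relative input).
#' @export
autoplot.mo_ensemble <- function(object, ...) {
  df <- tibble::tibble(
    value = c(object$mo_sw * 1e9,
              object$r_in / mo_constants()$modern_flux * 100),
    quantity = rep(c("seawater [Mo] (nM)", "input (% modern)"),
                   each = nrow(object))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70", colour = "grey30") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~quantity, scales = "free") +
    ggplot2::labs(x = NULL, y = "solutions") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mo_filtered <- autoplot.mo_ensemble

#' Plot the two-regime oxidative-weathering curve
#'
#' Mo release flux against atmospheric PO2 for the abiotic and biotic
#' variants, with the regime transitions marked. Points for inferred
#' minimum fluxes can be overlaid via `results`.
#'
#' @param params A [weathering_params()] object.
#' @param results Optional `mo_flux_result` tibble; plotted at
#'   (`po2_biotic`, `r_corrected`) and (`po2_abiotic`, `r_corrected`).
#' @param log10_range,n Grid passed to [weathering_curve()].
#' @return A ggplot.
#' @export
plot_weathering_curve <- function(params = weathering_params(),
                                  results = NULL,
                                  log10_range = c(-8, 0), n = 300) {
  curve <- weathering_curve(params, log10_range, n)
  p <- ggplot2::ggplot(curve,
                       ggplot2::aes(.data$po2, .data$flux,
                                    linetype = .data$variant)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = regime_transition(params, FALSE),
                        colour = "grey60") +
    ggplot2::geom_vline(xintercept = regime_transition(params, TRUE),
                        colour = "grey80") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "PO2 (PAL)", y = "Mo release flux (mol/yr)",
                  linetype = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(results)) {
    pts <- dplyr::bind_rows(
      tibble::tibble(po2 = results$po2_biotic, flux = results$r_corrected,
                     variant = "biotic", period = results$period),
      tibble::tibble(po2 = results$po2_abiotic, flux = results$r_corrected,
                     variant = "abiotic", period = results$period)
    )
    p <- p + ggplot2::geom_point(
      data = pts, ggplot2::aes(.data$po2, .data$flux), inherit.aes = FALSE)
  }
  p
}
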