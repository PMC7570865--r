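#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a Pareto boundary
#'
#' Draws the boundary in the (CE, OE) plane, optionally with observed
#' product error pairs overlaid: the gap between a product's point and the
#' curve is the part of its error not attributable to resolution.
#'
#' @param object A `pareto_curve` from [pareto_boundary()].
#' @param observed Optional data frame with columns `ce`, `oe` (and
#'   optionally `label`) of observed product errors to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pareto_curve <- function(object, observed = NULL, ...) {
  res <- attr(object, "resolution_m")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$ce, y = .data$oe)) +
    ggplot2::geom_line(colour = "#b2182b") +
    ggplot2::geom_point(colour = "#b2182b", size = 1.2) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Commission error", y = "Omission error",
      title = sprintf("Pareto boundary%s (AUPB = %.4g)",
                      if (!is.null(res)) sprintf(" at %g m", res) else "",
                      aupb(object))
    ) +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_point(data = observed, shape = 17, size = 2,
                                 colour = "#2166ac")
    if ("label" %in% names(observed)) {
      p <- p + ggplot2::geom_text(
        data = observed, ggplot2::aes(label = .data$label),
        nudge_y = 0.03, size = 3, colour = "#2166ac")
    }
  }
  p
}

#' @rdname fit_te_vs_aupb
#' @param object A `te_aupb_fit`.
#' @export
autoplot.te_aupb_fit <- function(object, ...) {
  g <- glance(object)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$aupb, y = .data$te)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = g$slope, intercept = g$intercept,
                         colour = "#b2182b") +
    ggplot2::labs(x = "Area under Pareto boundary",
                  y = "Total error",
                  title = sprintf("TE = %.3g x AUPB + %.3g (R² = %.2f)",
                                  g$slope, g$intercept, g$r_squared)) +
    ggplot2::theme_minimal()
}

#' @rdname run_assessment
#' @param object A `ba_assessment`.
#' @export
autoplot.ba_assessment <- function(object, ...) {
  stopifnot(nrow(object$annual) > 0)
  ref <- dplyr::distinct(object$annual, .data$year, .data$bar_ha)
  ggplot2::ggplot(object$annual,
                  ggplot2::aes(x = .data$year, y = .data$bap_ha,
                               colour = .data$product)) +
    ggplot2::geom_col(data = ref,
                      ggplot2::aes(x = .data$year, y = .data$bar_ha),
                      inherit.aes = FALSE, fill = "grey85") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Year", y = "Burned area (ha)",
                  colour = "Product",
                  title = "Annual burned area: products vs reference (bars)") +
    ggplot2::theme_minimal()
}
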