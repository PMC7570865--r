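#' Commission/omission errors of a strict binary classification of mixed pixels
#'
#' Classifies each coarse pixel of a burned-fraction map as Burned iff its
#' burned fraction `f` reaches a threshold `p`: `B = {f >= p}` for `p > 0`,
#' and `B = {f > 0}` at `p = 0` (so fully unburned pixels are never called
#' Burned and the commission error stays finite). Errors are computed on an
#' area basis: classifying a mixed pixel as Burned commits its unburned
#' fraction `1 - f`; classifying it Non-Burned omits its burned fraction `f`.
#'
#' \deqn{CE = \sum_{i \in B} (1 - f_i) / |B|, \qquad
#'       OE = \sum_{i \notin B} f_i / \sum_i f_i}
#'
#' with `CE := 0` when `B` is empty. Pixels flagged as zero-padded during
#' aggregation are excluded. These are the lowest errors any binary labelling
#' rule can achieve at this resolution; they are attributable purely to
#' sub-pixel fragmentation.
#'
#' @param frac A [fraction_grid()] with at least one pixel of positive
#'   burned fraction.
#' @param p Threshold(s) in \[0, 1\]; vectorised.
#' @return A tibble with columns `p`, `ce`, `oe` (one row per threshold).
#' @examples
#' spec <- grid_spec(n_rows = 1, n_cols = 4, pixel_size = 250)
#' fg <- fraction_grid(matrix(c(1, 0.6, 0.4, 0), 1, 4), spec, factor = 5L)
#' threshold_classify(fg, 0.5)  # ce = 0.2, oe = 0.2
#' @export
threshold_classify <- function(frac, p) {
  stopifnot(inherits(frac, "fraction_grid"), is.numeric(p))
  if (any(p < 0 | p > 1)) rlang::abort("Thresholds must lie in [0, 1].")
  f <- as.vector(frac$values)
  if (!is.null(frac$padded)) f <- f[!as.vector(frac$padded)]
  tot <- sum(f)
  if (tot <= 0) {
    rlang::abort("The fraction map is entirely unburned: omission error is undefined.")
  }
  res <- purrr::map(p, function(pi) {
    in_b <- if (pi > 0) f >= pi else f > 0
    nb <- sum(in_b)
    ce <- if (nb > 0) sum(1 - f[in_b]) / nb else 0
    oe <- sum(f[!in_b]) / tot
    c(ce = ce, oe = oe)
  })
  tibble::tibble(p = as.numeric(p),
                 ce = purrr::map_dbl(res, "ce"),
                 oe = purrr::map_dbl(res, "oe"))
}

# Keep only Pareto-efficient (ce, oe) pairs: sort by ce then oe, keep points
# with strictly decreasing oe. Duplicates collapse; for tied ce the lowest oe
# survives.
pareto_filter <- function(points) {
  pts <- dplyr::arrange(dplyr::distinct(points, .data$ce, .data$oe,
                                        .keep_all = TRUE),
                        .data$ce, .data$oe)
  keep <- logical(nrow(pts))
  best_oe <- Inf
  for (i in seq_len(nrow(pts))) {
    if (pts$oe[i] < best_oe - 1e-15) {
      keep[i] <- TRUE
      best_oe <- pts$oe[i]
    }
  }
  pts[keep, , drop = FALSE]
}

#' Construct the Pareto boundary of a burned-fraction map
#'
#' Sweeps the classification threshold `p` over \[0, 1\] (either `n_steps`
#' equidistant values, or exactly over every distinct positive pixel fraction
#' plus 0 with `n_steps = "exact"`), computes the area-based (CE, OE) pair at
#' each threshold with [threshold_classify()], drops duplicate and
#' Pareto-dominated pairs, and returns the boundary sorted by ascending CE.
#' Along the boundary OE is strictly decreasing in CE, so the curve is a
#' proper function OE(CE) and its area is well defined.
#'
#' @param frac A [fraction_grid()].
#' @param n_steps Number of equidistant thresholds (>= 2), or `"exact"` for
#'   the exhaustive sweep over distinct pixel fractions. Default 101.
#' @return A tibble of class `pareto_curve` with columns `p` (a threshold
#'   attaining the point), `ce`, `oe`; attributes `resolution_m`, `factor`,
#'   `year`, and `aupb` (see [aupb()]).
#' @examples
#' spec <- grid_spec(n_rows = 1, n_cols = 4, pixel_size = 250)
#' fg <- fraction_grid(matrix(c(1, 0.6, 0.4, 0), 1, 4), spec, factor = 5L)
#' pb <- pareto_boundary(fg)
#' pb          # (0, 0.5), (0.2, 0.2), (1/3, 0)
#' aupb(pb)    # 1/12
#' @export
pareto_boundary <- function(frac, n_steps = 101) {
  stopifnot(inherits(frac, "fraction_grid"))
  if (identical(n_steps, "exact")) {
    f <- as.vector(frac$values)
    if (!is.null(frac$padded)) f <- f[!as.vector(frac$padded)]
    # 1 is always included so the empty classification (CE = 0, OE = 1) is
    # reachable even when no pixel is fully burned
    p <- sort(unique(c(0, f[f > 0], 1)))
  } else {
    n_steps <- as.integer(n_steps)
    if (is.na(n_steps) || n_steps < 2L) {
      rlang::abort('`n_steps` must be an integer >= 2 or "exact".')
    }
    p <- seq(0, 1, length.out = n_steps)
  }
  pts <- pareto_filter(threshold_classify(frac, p))
  curve <- tibble::new_tibble(pts, class = "pareto_curve")
  attr(curve, "resolution_m") <- frac$spec$pixel_size
  attr(curve, "factor") <- frac$factor
  attr(curve, "year") <- frac$year
  attr(curve, "aupb") <- trapezoid_area(pts$ce, pts$oe)
  curve
}

trapezoid_area <- function(ce, oe) {
  n <- length(ce)
  if (n < 2) return(0)
  sum((oe[-1] + oe[-n]) / 2 * diff(ce))
}

#' Area under the Pareto boundary (AUPB)
#'
#' Integrates OE over CE along the boundary by the trapezoidal rule, with CE
#' as the independent variable. AUPB is a scalar in \[0, 1\] measuring the
#' sub-pixel fragmentation of the burned area at the map's resolution: 0 when
#' every pixel is pure (the boundary collapses to the origin), larger when
#' mixed pixels force a commission/omission trade-off.
#'
#' @param curve A `pareto_curve` from [pareto_boundary()], or any data frame
#'   with `ce` and `oe` columns (assumed or re-sorted to ascending CE).
#' @return The area (scalar); 0 for a single-point curve.
#' @export
aupb <- function(curve) {
  if (inherits(curve, "pareto_curve") && !is.null(attr(curve, "aupb"))) {
    return(attr(curve, "aupb"))
  }
  stopifnot(is.data.frame(curve), all(c("ce", "oe") %in% names(curve)))
  pts <- dplyr::arrange(curve, .data$ce)
  trapezoid_area(pts$ce, pts$oe)
}

#' Distance from a product's error pair to the Pareto boundary
#'
#' Minimum Euclidean distance in the (CE, OE) plane from an observed error
#' pair to the piecewise-linear Pareto boundary. Points on or below the
#' boundary return the distance to the nearest boundary segment (a product
#' cannot in fact beat the boundary; small negative excursions only arise
#' from resolution mismatch). Reported as a diagnostic of how much of a
#' map's error is *not* explained by resolution.
#'
#' @param curve A `pareto_curve`.
#' @param ce,oe The observed commission and omission errors.
#' @return The distance (scalar >= 0).
#' @export
distance_to_boundary <- function(curve, ce, oe) {
  stopifnot(is.data.frame(curve), nrow(curve) >= 1)
  px <- curve$ce; py <- curve$oe
  if (length(px) == 1) return(sqrt((ce - px)^2 + (oe - py)^2))
  d2 <- Inf
  for (i in seq_len(length(px) - 1)) {
    vx <- px[i + 1] - px[i]; vy <- py[i + 1] - py[i]
    t <- ((ce - px[i]) * vx + (oe - py[i]) * vy) / (vx^2 + vy^2)
    t <- min(max(t, 0), 1)
    qx <- px[i] + t * vx; qy <- py[i] + t * vy
    d2 <- min(d2, (ce - qx)^2 + (oe - qy)^2)
  }
  sqrt(d2)
}

#' Regress annual total error on annual AUPB
#'
#' Ordinary least-squares fit of the annual total errors of a product on the
#' areas under the annual Pareto boundaries at the product's resolution. The
#' slope measures how sensitive the product's total error is to burned-area
#' fragmentation; R-squared is the squared Pearson correlation of the two
#' annual series.
#'
#' @param pairs A data frame with columns `aupb` and `te` (one row per
#'   year), at least 3 rows, non-degenerate `aupb` variance.
#' @return An object of class `te_aupb_fit` wrapping the [stats::lm()] fit;
#'   supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
fit_te_vs_aupb <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("aupb", "te") %in% names(pairs)))
  pairs <- dplyr::filter(pairs, !is.na(.data$aupb), !is.na(.data$te))
  if (nrow(pairs) < 3) rlang::abort("Need at least 3 (aupb, te) pairs.")
  if (stats::sd(pairs$aupb) == 0) {
    rlang::abort("Degenerate regressor: all AUPB values are equal.")
  }
  fit <- stats::lm(te ~ aupb, data = pairs)
  structure(list(fit = fit, data = tibble::as_tibble(pairs)),
            class = "te_aupb_fit")
}

#' @export
print.te_aupb_fit <- function(x, ...) {
  co <- stats::coef(x$fit)
  cat(sprintf("<te_aupb_fit> TE = %.4g x AUPB + %.4g  (R^2 = %.3f, n = %d)\n",
              co[["aupb"]], co[["(Intercept)"]],
              summary(x$fit)$r.squared, nrow(x$data)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_te_vs_aupb
#' @param x A `te_aupb_fit`.
#' @param ... Unused.
#' @export
tidy.te_aupb_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = s[, 1], std_error = s[, 2],
                 statistic = s[, 3], p_value = s[, 4])
}

#' @rdname fit_te_vs_aupb
#' @export
glance.te_aupb_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(r_squared = s$r.squared,
                 sigma = s$sigma,
                 n = nrow(x$data),
                 slope = stats::coef(x$fit)[["aupb"]],
                 intercept = stats::coef(x$fit)[["(Intercept)"]])
}
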