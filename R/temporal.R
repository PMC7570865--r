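#' Fire size categories
#'
#' Fires are binned into five standard size categories by burned extent, with
#' half-open intervals `[lower, upper)`: very small (< 100 ha), small
#' (100-1000 ha), medium (1000-10,000 ha), large (10,000-100,000 ha) and very
#' large (>= 100,000 ha). A 100 ha fire is therefore "small", not "very
#' small".
#'
#' @param area_ha Numeric vector of burned areas in hectares (all > 0).
#' @return A factor with levels `very_small`, `small`, `medium`, `large`,
#'   `very_large`.
#' @examples
#' fire_size_category(c(99.99, 100, 5000, 2e5))
#' @export
fire_size_category <- function(area_ha) {
  if (any(!is.finite(area_ha)) || any(area_ha <= 0)) {
    rlang::abort("Fire areas must be positive and finite.")
  }
  cut(area_ha, breaks = c(0, fire_size_breaks_ha(), Inf),
      labels = c("very_small", "small", "medium", "large", "very_large"),
      right = FALSE)
}

#' @rdname fire_size_category
#' @export
fire_size_breaks_ha <- function() c(100, 1000, 10000, 100000)

#' Per-category fire counts and burned-area shares
#'
#' Summarises a fire-event table by size category: number of fires, total
#' burned area, and the percentage shares of the fire count and of the total
#' burned area. Empty categories are kept with zero counts so the output
#' always has five rows.
#'
#' @param events A [fire_events()] table, or any data frame with an `area_ha`
#'   column (a `category` column is recomputed from `area_ha`).
#' @return A tibble with columns `category`, `n_fires`, `area_ha`,
#'   `count_share_pct`, `area_share_pct`. Shares sum to 100.
#' @export
categorize_fires <- function(events) {
  stopifnot(is.data.frame(events), "area_ha" %in% names(events))
  cat_ <- fire_size_category(events$area_ha)
  tibble::tibble(category = cat_, area_ha = events$area_ha) |>
    dplyr::group_by(category = .data$category, .drop = FALSE) |>
    dplyr::summarise(n_fires = dplyr::n(),
                     area_ha = sum(.data$area_ha), .groups = "drop") |>
    dplyr::mutate(
      count_share_pct = 100 * .data$n_fires / sum(.data$n_fires),
      area_share_pct = 100 * .data$area_ha / sum(.data$area_ha)
    )
}

#' Annual burned-area percentage of a product
#'
#' The temporal-accuracy statistic for one year: the percentage of the
#' reference burned area that the product maps as burned,
#' `P = 100 * sum(product pixels) / sum(reference pixels)`. This is a ratio
#' of totals, not of the spatial overlap: a product can reach 100% while
#' burning entirely the wrong pixels.
#'
#' @param product,reference [burn_grid()] maps for the same year on one
#'   common geometry; the reference must contain at least one burned pixel.
#' @return The annual percentage (scalar, in percent).
#' @export
annual_percentage <- function(product, reference) {
  stopifnot(inherits(product, "burn_grid"), inherits(reference, "burn_grid"))
  check_same_spec(product$spec, reference$spec, "product and reference maps")
  bar <- sum(reference$values)
  if (bar == 0) {
    rlang::abort("The reference map has no burned pixels: the annual percentage is undefined.")
  }
  100 * sum(product$values) / bar
}

#' Multi-year weighted average of annual burned-area percentages
#'
#' The all-years summary percentage: total product burned area over the whole
#' series divided by total reference burned area, times 100. Algebraically
#' this equals the reference-area-weighted mean of the annual percentages.
#' Years with exactly zero reference area contribute nothing to either sum.
#'
#' @param records A data frame with columns `bar_ha` (reference burned area)
#'   and `bap_ha` (product burned area), one row per year. Rows with `NA`
#'   product area (years the product does not cover) are dropped.
#' @return The weighted average percentage (scalar).
#' @examples
#' weighted_average_percentage(
#'   tibble::tibble(bar_ha = c(100, 100), bap_ha = c(40, 60)))  # 50
#' @export
weighted_average_percentage <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("bar_ha", "bap_ha") %in% names(records)))
  rec <- dplyr::filter(records, !is.na(.data$bap_ha))
  tot_ref <- sum(rec$bar_ha)
  if (nrow(rec) == 0 || tot_ref <= 0) {
    rlang::abort("Need at least one year with positive reference burned area.")
  }
  100 * sum(rec$bap_ha) / tot_ref
}

#' Coefficient of determination between two annual series
#'
#' The square of the Pearson correlation between two yearly burned-area
#' series, used to quantify how well a product tracks the interannual
#' pattern of the reference data. Invariant to affine rescaling of either
#' series.
#'
#' @param x,y Numeric vectors of equal length (>= 3) with non-zero variance.
#' @return R-squared in \[0, 1\].
#' @export
determination_coefficient <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y) || length(x) < 3) {
    rlang::abort("Need two series of equal length >= 3.")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::abort("Both series must have non-zero variance.")
  }
  stats::cor(x, y)^2
}
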