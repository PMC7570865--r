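#' Pixel-level confusion counts between a product and the reference
#'
#' Cross-tabulates the two binary maps over all pixels. Rows of the implied
#' 2x2 matrix are the classified (product) data, columns the reference:
#' `n11` true Burned, `n12` false Burned (commission), `n21` false Non-Burned
#' (omission), `n22` true Non-Burned. Marginals: `n1c = n11 + n12` (pixels the
#' product calls Burned), `n2c = n21 + n22`, `n1r = n11 + n21` (reference
#' Burned), `n2r = n12 + n22`, and `n` the grid total.
#'
#' @param product,reference [burn_grid()] maps on one common geometry.
#' @return A one-row tibble of class `confusion_counts` with columns `n11`,
#'   `n12`, `n21`, `n22`, `n1c`, `n2c`, `n1r`, `n2r`, `n`.
#' @export
confusion_counts <- function(product, reference) {
  stopifnot(inherits(product, "burn_grid"), inherits(reference, "burn_grid"))
  check_same_spec(product$spec, reference$spec, "product and reference maps")
  p <- product$values; r <- reference$values
  n11 <- sum(p == 1L & r == 1L)
  n12 <- sum(p == 1L & r == 0L)
  n21 <- sum(p == 0L & r == 1L)
  n22 <- sum(p == 0L & r == 0L)
  tibble::new_tibble(
    tibble::tibble(n11 = n11, n12 = n12, n21 = n21, n22 = n22,
                   n1c = n11 + n12, n2c = n21 + n22,
                   n1r = n11 + n21, n2r = n12 + n22,
                   n = n11 + n12 + n21 + n22),
    class = "confusion_counts"
  )
}

#' Accuracy metrics from confusion counts
#'
#' Derives the standard thematic-map accuracy metrics for the Burned class:
#' * `oa`, overall accuracy `(n11 + n22) / n`;
#' * `s`, sensitivity (producer's accuracy) `n11 / n1r`;
#' * `sp`, specificity `n22 / n2r` (the rate of correctly identified
#'   Non-Burned pixels: the denominator is the reference Non-Burned total);
#' * `ce`, commission error `n12 / n1c` — the fraction of map-Burned area
#'   that the reference says did not burn;
#' * `oe`, omission error `n21 / n1r` — the fraction of reference burned
#'   area the map missed (`s = 1 - oe`).
#'
#' Empty-class conventions: when the product detects nothing (`n1c = 0`),
#' `ce := 0`; when the reference has no burned pixels (`n1r = 0`), `oe := 0`
#' with a warning (`s` and `sp` are set analogously). These keep annual
#' series well defined in years with no detections.
#'
#' @param counts A `confusion_counts` row (or any data frame with columns
#'   `n11`, `n12`, `n21`, `n22`).
#' @return A one-row tibble with columns `oa`, `s`, `sp`, `ce`, `oe`.
#' @examples
#' accuracy_metrics(tibble::tibble(n11 = 3, n12 = 1, n21 = 2, n22 = 10))
#' @export
accuracy_metrics <- function(counts) {
  stopifnot(is.data.frame(counts),
            all(c("n11", "n12", "n21", "n22") %in% names(counts)))
  n11 <- counts$n11; n12 <- counts$n12; n21 <- counts$n21; n22 <- counts$n22
  n1c <- n11 + n12; n1r <- n11 + n21; n2r <- n12 + n22
  n <- n1c + n21 + n22
  if (any(n == 0)) rlang::abort("Confusion counts total zero pixels.")
  if (any(n1r == 0)) {
    rlang::warn("Reference has no burned pixels; omission error set to 0 by convention.")
  }
  tibble::tibble(
    oa = (n11 + n22) / n,
    s  = ifelse(n1r > 0, n11 / n1r, 1),
    sp = ifelse(n2r > 0, n22 / n2r, 1),
    ce = ifelse(n1c > 0, n12 / n1c, 0),
    oe = ifelse(n1r > 0, n21 / n1r, 0)
  )
}

#' Weighted total error of a burned-area map
#'
#' Commission and omission errors are not directly comparable: both are
#' fractions of "Burned" pixels, but CE is relative to the classified map and
#' OE to the reference. The total error weights the commission error by the
#' detected fraction `P` (the annual percentage expressed as a fraction):
#' `TE = CE * P + OE`. Equivalently in hectares,
#' `TE_ha = CE * BAP + OE * BAR`, and `TE = TE_ha / BAR`. TE can exceed 1
#' (e.g. CE = OE = 1 with any detection at all).
#'
#' @param ce,oe Commission and omission errors (fractions, >= 0).
#' @param p Detected burned-area fraction (annual percentage / 100).
#' @return `total_error()`: the total error as a fraction.
#' @examples
#' total_error(ce = 0.151, oe = 0.345, p = 0.7711)  # 0.461 at 3 dp
#' @export
total_error <- function(ce, oe, p) {
  stopifnot(is.numeric(ce), is.numeric(oe), is.numeric(p))
  if (any(ce < 0 | oe < 0 | p < 0, na.rm = TRUE)) {
    rlang::abort("`ce`, `oe` and `p` must be non-negative fractions.")
  }
  ce * p + oe
}

#' @rdname total_error
#' @param bap_ha,bar_ha Product and reference burned areas in hectares.
#' @return `total_error_ha()`: the total error in hectares.
#' @export
total_error_ha <- function(ce, oe, bap_ha, bar_ha) {
  stopifnot(is.numeric(bap_ha), is.numeric(bar_ha))
  if (any(ce < 0 | oe < 0 | bap_ha < 0 | bar_ha < 0, na.rm = TRUE)) {
    rlang::abort("All inputs must be non-negative.")
  }
  ce * bap_ha + oe * bar_ha
}

#' Compare one product map against the reference, all metrics at once
#'
#' Convenience wrapper producing a one-row tibble with burned areas, the
#' annual percentage, the confusion counts, the derived accuracy metrics and
#' the total error for one year.
#'
#' @inheritParams confusion_counts
#' @return A one-row tibble with columns `year`, `bar_ha`, `bap_ha`, `p_pct`,
#'   the confusion counts, `oa`, `s`, `sp`, `ce`, `oe`, `te`.
#' @export
compare_maps <- function(product, reference) {
  cc <- confusion_counts(product, reference)
  m <- accuracy_metrics(cc)
  bar <- burned_area_ha(reference)
  bap <- burned_area_ha(product)
  p_pct <- if (bar > 0) 100 * bap / bar else NA_real_
  dplyr::bind_cols(
    tibble::tibble(year = reference$year, bar_ha = bar, bap_ha = bap,
                   p_pct = p_pct),
    cc, m,
    tibble::tibble(te = total_error(m$ce, m$oe, p_pct / 100))
  )
}
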