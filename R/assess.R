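#' Run the full annual accuracy assessment
#'
#' Orchestrates the whole validation workflow for one reference series and
#' one or more candidate burned-area products, year by year:
#'
#' 1. temporal accuracy — annual detected percentage per year and product,
#'    and the all-years weighted average;
#' 2. spatial accuracy — confusion counts, OA/S/Sp/CE/OE and the total error
#'    `TE = CE * P + OE` per year and product, plus all-years CE/OE weighted
#'    by each year's share of the total reference burned area and the
#'    all-years TE recomputed from the all-years CE, OE and P;
#' 3. fragmentation — for each aggregation factor, the Pareto boundary of
#'    the aggregated reference map and its AUPB (a reference-only quantity);
#' 4. optionally, the TE-vs-AUPB regression per product at its native
#'    aggregation factor.
#'
#' Years missing from a product are recorded as absent (`NA` rows are simply
#' not produced), mirroring how published assessment tables leave blanks.
#'
#' @param reference Named list of [burn_grid()] maps, names = years.
#' @param products Named list (one element per product) of named lists of
#'   [burn_grid()] maps by year.
#' @param factors Integer vector of aggregation factors for the Pareto
#'   analysis (e.g. `c(5, 6, 10)` for 250/300/500 m from a 50 m base).
#' @param n_steps Threshold count for [pareto_boundary()] (or `"exact"`).
#' @param product_factors Optional named integer vector giving each
#'   product's native aggregation factor; enables the TE-vs-AUPB regression.
#' @param pad Passed to [aggregate_fraction()] for non-divisible dimensions.
#' @return An object of class `ba_assessment`: a list of tibbles `annual`,
#'   `overall`, `aupb`, `curves` (list-column of `pareto_curve`s),
#'   `regressions` (list-column of [fit_te_vs_aupb()] objects, possibly
#'   empty). Supports `tidy()` (annual table), `glance()` (overall table)
#'   and `autoplot()`.
#' @export
run_assessment <- function(reference, products, factors = c(5L, 10L),
                           n_steps = 101, product_factors = NULL,
                           pad = FALSE) {
  stopifnot(is.list(reference), length(reference) >= 1, is.list(products))
  years <- as.integer(names(reference))
  if (anyNA(years)) rlang::abort("`reference` must be a list named by year.")
  base_spec <- reference[[1]]$spec
  purrr::walk(reference, function(g) check_same_spec(base_spec, g$spec))

  annual <- purrr::imap(products, function(by_year, prod) {
    purrr::imap(by_year, function(grid, yr) {
      yr <- as.integer(yr)
      if (!as.character(yr) %in% names(reference)) {
        rlang::abort(sprintf("Product '%s' has year %d absent from the reference.", prod, yr))
      }
      ref <- reference[[as.character(yr)]]
      check_same_spec(base_spec, grid$spec, sprintf("'%s' %d map and reference", prod, yr))
      dplyr::mutate(compare_maps(grid, ref), product = prod, year = yr,
                    .before = 1)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  if (nrow(annual) == 0) {
    annual <- tibble::tibble(
      product = character(), year = integer(), bar_ha = numeric(),
      bap_ha = numeric(), p_pct = numeric(), n11 = integer(),
      n12 = integer(), n21 = integer(), n22 = integer(), n1c = integer(),
      n2c = integer(), n1r = integer(), n2r = integer(), n = integer(),
      oa = numeric(), s = numeric(), sp = numeric(), ce = numeric(),
      oe = numeric(), te = numeric())
  }

  overall <- if (nrow(annual) > 0) {
    annual |>
      dplyr::group_by(product = .data$product) |>
      dplyr::summarise(
        n_years = dplyr::n(),
        p_pct = 100 * sum(.data$bap_ha) / sum(.data$bar_ha),
        ce = stats::weighted.mean(.data$ce, .data$bar_ha),
        oe = stats::weighted.mean(.data$oe, .data$bar_ha),
        bar_ha = sum(.data$bar_ha),
        bap_ha = sum(.data$bap_ha),
        .groups = "drop"
      ) |>
      dplyr::mutate(te = total_error(.data$ce, .data$oe, .data$p_pct / 100))
  } else {
    tibble::tibble(product = character(), n_years = integer(),
                   bar_ha = numeric(), bap_ha = numeric(), p_pct = numeric(),
                   ce = numeric(), oe = numeric(), te = numeric())
  }

  pareto_rows <- purrr::map(years, function(yr) {
    ref <- reference[[as.character(yr)]]
    if (sum(ref$values) == 0) return(NULL)
    purrr::map(factors, function(f) {
      fg <- aggregate_fraction(ref, f, pad = pad)
      curve <- pareto_boundary(fg, n_steps = n_steps)
      tibble::tibble(year = yr, factor = as.integer(f),
                     resolution_m = fg$spec$pixel_size,
                     aupb = aupb(curve), n_points = nrow(curve),
                     curve = list(curve))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  aupb_tab <- if (nrow(pareto_rows) > 0) {
    dplyr::select(pareto_rows, !"curve")
  } else {
    tibble::tibble(year = integer(), factor = integer(),
                   resolution_m = numeric(), aupb = numeric(),
                   n_points = integer())
  }

  regressions <- tibble::tibble(product = character(), factor = integer(),
                                fit = list())
  if (!is.null(product_factors) && nrow(annual) > 0 && nrow(aupb_tab) > 0) {
    regressions <- purrr::imap(product_factors, function(f, prod) {
      pairs <- annual |>
        dplyr::filter(.data$product == prod) |>
        dplyr::inner_join(
          dplyr::filter(aupb_tab, .data$factor == as.integer(f)),
          by = "year"
        ) |>
        dplyr::select(year = "year", aupb = "aupb", te = "te")
      if (nrow(pairs) < 3 || stats::sd(pairs$aupb) == 0) {
        return(NULL)
      }
      tibble::tibble(product = prod, factor = as.integer(f),
                     fit = list(fit_te_vs_aupb(pairs)))
    }) |> purrr::compact() |> dplyr::bind_rows()
  }

  structure(
    list(annual = annual, overall = overall, aupb = aupb_tab,
         curves = pareto_rows, regressions = regressions,
         n_steps = n_steps, factors = as.integer(factors)),
    class = "ba_assessment"
  )
}

#' @export
print.ba_assessment <- function(x, ...) {
  cat(sprintf("<ba_assessment> %d product-year comparisons, %d products, %d Pareto curves\n",
              nrow(x$annual), nrow(x$overall), nrow(x$curves)))
  if (nrow(x$overall) > 0) print(x$overall)
  invisible(x)
}

#' @rdname run_assessment
#' @param x A `ba_assessment`.
#' @param ... Unused.
#' @export
tidy.ba_assessment <- function(x, ...) x$annual

#' @rdname run_assessment
#' @export
glance.ba_assessment <- function(x, ...) x$overall

#' Recompute total errors from a published accuracy table
#'
#' Given per-year commission errors, omission errors and detected
#' percentages (as printed in an assessment report, typically rounded to
#' 3 and 2 decimals), recomputes `TE = CE * P + OE` for every row and
#' reports the deviation from the printed TE where one is supplied. Used to
#' audit the internal consistency of published error tables.
#'
#' @param table A data frame with columns `ce`, `oe`, `p_pct` and optionally
#'   `te` (the printed total error).
#' @return The input with columns `te_recomputed` and, when `te` is present,
#'   `te_deviation = te_recomputed - te`.
#' @export
recompute_total_errors <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("ce", "oe", "p_pct") %in% names(table)))
  out <- dplyr::mutate(
    tibble::as_tibble(table),
    te_recomputed = total_error(.data$ce, .data$oe, .data$p_pct / 100)
  )
  if ("te" %in% names(table)) {
    out <- dplyr::mutate(out, te_deviation = .data$te_recomputed - .data$te)
  }
  out
}

#' Write assessment tables to disk
#'
#' Emits the assessment as publication-shaped CSVs plus one lossless JSON
#' bundle:
#' * `annual_percentages.csv` — year, reference ha, one column per product
#'   with the detected percentage (2 dp), and an all-years row;
#' * `annual_errors.csv` — per year and product CE/OE/TE (3 dp), with the
#'   weighted all-years row;
#' * `aupb.csv` — AUPB x 1000 (3 dp) per year and resolution;
#' * `regressions.csv` — slope, intercept, R^2, n per product;
#' * `assessment.json` — every table at full precision (the round-trippable
#'   record; see [read_assessment_json()]).
#'
#' @param x A `ba_assessment`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of written paths.
#' @export
report_tables <- function(x, dir) {
  stopifnot(inherits(x, "ba_assessment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  p_tab <- if (nrow(x$annual) > 0) {
    wide <- x$annual |>
      dplyr::transmute(year = .data$year, reference_ha = .data$bar_ha,
                       product = .data$product,
                       p_pct = round(.data$p_pct, 2)) |>
      tidyr::pivot_wider(names_from = "product", values_from = "p_pct") |>
      dplyr::arrange(.data$year)
    all_years <- dplyr::bind_cols(
      tibble::tibble(year = NA_integer_,
                     reference_ha = sum(dplyr::distinct(
                       x$annual, .data$year, .data$bar_ha)$bar_ha)),
      tidyr::pivot_wider(
        dplyr::transmute(x$overall, product = .data$product,
                         p_pct = round(.data$p_pct, 2)),
        names_from = "product", values_from = "p_pct")
    )
    dplyr::bind_rows(wide, all_years)
  } else {
    tibble::tibble(year = integer(), reference_ha = numeric())
  }
  f <- file.path(dir, "annual_percentages.csv")
  utils::write.csv(p_tab, f, row.names = FALSE, na = "")
  paths <- c(paths, f)

  err_tab <- dplyr::bind_rows(
    dplyr::transmute(x$annual, year = as.character(.data$year),
                     product = .data$product,
                     ce = round(.data$ce, 3), oe = round(.data$oe, 3),
                     te = round(.data$te, 3)),
    dplyr::transmute(x$overall, year = "all_years", product = .data$product,
                     ce = round(.data$ce, 3), oe = round(.data$oe, 3),
                     te = round(.data$te, 3))
  )
  f <- file.path(dir, "annual_errors.csv")
  utils::write.csv(err_tab, f, row.names = FALSE, na = "")
  paths <- c(paths, f)

  aupb_tab <- dplyr::transmute(
    x$aupb, year = .data$year, resolution_m = .data$resolution_m,
    aupb_x1000 = round(1000 * .data$aupb, 3))
  f <- file.path(dir, "aupb.csv")
  utils::write.csv(aupb_tab, f, row.names = FALSE, na = "")
  paths <- c(paths, f)

  reg_tab <- if (nrow(x$regressions) > 0) {
    dplyr::bind_cols(
      dplyr::select(x$regressions, "product", "factor"),
      dplyr::bind_rows(purrr::map(x$regressions$fit, glance))
    )
  } else {
    tibble::tibble(product = character(), factor = integer())
  }
  f <- file.path(dir, "regressions.csv")
  utils::write.csv(reg_tab, f, row.names = FALSE, na = "")
  paths <- c(paths, f)

  bundle <- list(
    annual = x$annual,
    overall = x$overall,
    aupb = x$aupb,
    curves = purrr::map(seq_len(nrow(x$curves)), function(i) {
      list(year = x$curves$year[i], factor = x$curves$factor[i],
           resolution_m = x$curves$resolution_m[i],
           aupb = x$curves$aupb[i],
           points = as.data.frame(x$curves$curve[[i]]))
    }),
    regressions = reg_tab,
    n_steps = x$n_steps, factors = x$factors
  )
  f <- file.path(dir, "assessment.json")
  jsonlite::write_json(bundle, f, auto_unbox = TRUE, digits = NA, na = "null")
  paths <- c(paths, f)
  invisible(paths)
}

#' @rdname report_tables
#' @param path Path to an `assessment.json` written by [report_tables()].
#' @return `read_assessment_json()`: the bundle as a list of tibbles with
#'   full-precision values.
#' @export
read_assessment_json <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(
    annual = tibble::as_tibble(b$annual),
    overall = tibble::as_tibble(b$overall),
    aupb = tibble::as_tibble(b$aupb),
    curves = purrr::map(seq_along(b$curves$year %||% integer(0)), function(i) {
      list(year = b$curves$year[i], factor = b$curves$factor[i],
           resolution_m = b$curves$resolution_m[i], aupb = b$curves$aupb[i],
           points = tibble::as_tibble(b$curves$points[[i]]))
    }),
    regressions = tibble::as_tibble(b$regressions),
    n_steps = b$n_steps, factors = b$factors
  )
}
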