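#' Binary burned/non-burned raster for one year
#'
#' A `burn_grid` wraps a 0/1 integer matrix on a [grid_spec()]: 0 is
#' Not Burned, 1 is Burned. One grid represents one annual map, either the
#' reference (rasterized fire perimeters) or a candidate burned-area product.
#'
#' @param values Matrix of 0/1 values with `spec$n_rows` rows and
#'   `spec$n_cols` columns (logical matrices are accepted and coerced).
#' @param spec A [grid_spec()].
#' @param year Integer year label (metadata).
#'
#' @return An object of class `burn_grid`.
#' @seealso [fraction_grid()], [burned_area_ha()], [union_grids()]
#' @export
burn_grid <- function(values, spec, year = NA_integer_) {
  stopifnot(inherits(spec, "grid_spec"), is.matrix(values))
  if (nrow(values) != spec$n_rows || ncol(values) != spec$n_cols) {
    rlang::abort("`values` dimensions do not match the grid geometry.")
  }
  if (is.logical(values)) values <- values * 1L
  storage.mode(values) <- "integer"
  if (anyNA(values) || !all(values == 0L | values == 1L)) {
    rlang::abort("`values` must contain only 0 (Not Burned) and 1 (Burned).")
  }
  structure(list(values = values, spec = spec, year = as.integer(year)),
            class = "burn_grid")
}

#' @export
print.burn_grid <- function(x, ...) {
  cat(sprintf("<burn_grid> year %s: %d / %d pixels burned (%.2f ha)\n",
              ifelse(is.na(x$year), "?", x$year),
              sum(x$values), length(x$values), burned_area_ha(x)))
  print(x$spec)
  invisible(x)
}

#' Coarse-resolution burned-area fraction raster
#'
#' A `fraction_grid` holds, for each coarse pixel, the fraction of its area
#' that is burned (values in \[0, 1\]), typically produced by
#' [aggregate_fraction()] from a fine binary map. Mixed pixels (fractions
#' strictly between 0 and 1) are the source of the unavoidable
#' commission/omission errors quantified by the Pareto boundary.
#'
#' @param values Numeric matrix in \[0, 1\].
#' @param spec The coarse [grid_spec()].
#' @param factor Integer aggregation ratio (coarse pixel size / fine pixel
#'   size), `>= 1`.
#' @param year Integer year label.
#' @param padded Optional logical matrix marking coarse pixels whose block was
#'   zero-padded during aggregation; such pixels are excluded from Pareto
#'   statistics.
#' @return An object of class `fraction_grid`.
#' @export
fraction_grid <- function(values, spec, factor = 1L, year = NA_integer_,
                          padded = NULL) {
  stopifnot(inherits(spec, "grid_spec"), is.matrix(values))
  if (nrow(values) != spec$n_rows || ncol(values) != spec$n_cols) {
    rlang::abort("`values` dimensions do not match the grid geometry.")
  }
  storage.mode(values) <- "double"
  if (anyNA(values) || any(values < -1e-12) || any(values > 1 + 1e-12)) {
    rlang::abort("Fraction values must lie in [0, 1].")
  }
  values <- pmin(pmax(values, 0), 1)
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) rlang::abort("`factor` must be an integer >= 1.")
  if (!is.null(padded)) {
    stopifnot(is.logical(padded), all(dim(padded) == dim(values)))
  }
  structure(list(values = values, spec = spec, factor = factor,
                 year = as.integer(year), padded = padded),
            class = "fraction_grid")
}

#' @export
print.fraction_grid <- function(x, ...) {
  mixed <- sum(x$values > 0 & x$values < 1)
  cat(sprintf("<fraction_grid> factor %d (%g m pixels): %d mixed of %d pixels\n",
              x$factor, x$spec$pixel_size, mixed, length(x$values)))
  invisible(x)
}

#' Total burned area of a binary map, in hectares
#'
#' Counts Burned pixels and multiplies by the pixel area. On the 50 m
#' reference grid each pixel represents 0.25 ha, so eight burned pixels make
#' 2 ha.
#'
#' @param grid A [burn_grid()].
#' @return Burned area in hectares (scalar).
#' @examples
#' spec <- grid_spec(n_rows = 4, n_cols = 4, pixel_size = 50)
#' m <- matrix(0L, 4, 4); m[1, 1:2] <- 1L
#' burned_area_ha(burn_grid(m, spec))  # 0.5
#' @export
burned_area_ha <- function(grid) {
  stopifnot(inherits(grid, "burn_grid"))
  sum(grid$values) * pixel_area_ha(grid$spec)
}

#' Combine binary maps by logical union
#'
#' A pixel of the result is Burned iff it is Burned in any input. Used to
#' combine monthly or per-fire layers into one annual map. All inputs must
#' share one grid geometry; year labels, where present, must agree.
#'
#' @param grids A list of [burn_grid()] objects (or several grids given as
#'   separate arguments).
#' @param ... Further `burn_grid`s when `grids` is a single grid.
#' @return A [burn_grid()].
#' @export
union_grids <- function(grids, ...) {
  if (inherits(grids, "burn_grid")) grids <- c(list(grids), list(...))
  stopifnot(is.list(grids), length(grids) >= 1)
  purrr::walk(grids, function(g) stopifnot(inherits(g, "burn_grid")))
  spec <- grids[[1]]$spec
  purrr::walk(grids, function(g) check_same_spec(spec, g$spec))
  years <- unique(stats::na.omit(purrr::map_int(grids, "year")))
  if (length(years) > 1) {
    rlang::abort("Cannot union grids labelled with different years.")
  }
  acc <- Reduce(`+`, purrr::map(grids, "values"))
  burn_grid((acc > 0L) * 1L, spec,
            year = if (length(years) == 1) years else NA_integer_)
}

#' Aggregate a fine binary map to a coarse burned-fraction map
#'
#' Each coarse pixel receives the mean of its `factor` x `factor` block of
#' fine pixels, i.e. the fraction of the coarse pixel's area that is burned.
#' Total burned area is conserved exactly: the fractions summed over coarse
#' pixels times the coarse pixel area equal the fine map's burned area.
#'
#' With `pad = FALSE` (default) the fine dimensions must be multiples of
#' `factor`. With `pad = TRUE`, partial edge blocks are completed with
#' Not-Burned pixels and the affected coarse pixels are flagged in the
#' result's `padded` matrix so Pareto statistics can exclude them (their
#' fractions would otherwise be biased low).
#'
#' @param fine A [burn_grid()].
#' @param factor Integer aggregation ratio >= 1.
#' @param pad Pad partial edge blocks with Not-Burned instead of erroring.
#' @return A [fraction_grid()] whose pixel size is `factor` times the fine
#'   pixel size.
#' @examples
#' spec <- grid_spec(n_rows = 2, n_cols = 2, pixel_size = 50)
#' checker <- burn_grid(matrix(c(1L, 0L, 0L, 1L), 2, 2), spec)
#' aggregate_fraction(checker, 2)$values  # single pixel, 0.5
#' @export
aggregate_fraction <- function(fine, factor, pad = FALSE) {
  stopifnot(inherits(fine, "burn_grid"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) rlang::abort("`factor` must be an integer >= 1.")
  v <- fine$values
  nr <- nrow(v); nc <- ncol(v)
  if ((nr %% factor != 0L || nc %% factor != 0L)) {
    if (!pad) {
      rlang::abort(sprintf(
        "Grid dimensions (%d x %d) are not multiples of factor %d; use `pad = TRUE` to zero-pad.",
        nr, nc, factor))
    }
    nr_p <- ceiling(nr / factor) * factor
    nc_p <- ceiling(nc / factor) * factor
    vp <- matrix(0L, nr_p, nc_p)
    vp[seq_len(nr), seq_len(nc)] <- v
    v <- vp
  }
  cr <- nrow(v) %/% factor
  cc <- ncol(v) %/% factor
  # block means via a dim-reshape: rows within block x coarse rows x (cols ...)
  a <- array(as.numeric(v), dim = c(factor, cr, factor, cc))
  coarse <- apply(a, c(2, 4), sum) / factor^2
  padded <- NULL
  if (nrow(v) != nr || ncol(v) != nc) {
    padded <- matrix(FALSE, cr, cc)
    if (nr %% factor != 0L) padded[cr, ] <- TRUE
    if (nc %% factor != 0L) padded[, cc] <- TRUE
  }
  cspec <- grid_spec(fine$spec$origin_x, fine$spec$origin_y,
                     pixel_size = fine$spec$pixel_size * factor,
                     n_rows = cr, n_cols = cc,
                     crs_label = fine$spec$crs_label)
  fraction_grid(coarse, cspec, factor = factor, year = fine$year,
                padded = padded)
}
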