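#' Define an equal-area raster geometry
#'
#' A `grid_spec` fixes the geometry shared by every map in an assessment: the
#' projected coordinates of the grid's upper-left corner, the (square) pixel
#' size in metres, and the raster dimensions. All burned-area maps compared in
#' a run must live on one common `grid_spec`.
#'
#' Pixel `(row, col)` (1-based) spans the half-open intervals
#' `[x0 + (col-1)*s, x0 + col*s)` in easting and `(y0 - row*s, y0 - (row-1)*s]`
#' in northing, with row 1 at the top. The coordinate reference system is
#' metadata only: no reprojection is performed, and inputs are assumed
#' co-registered in one projected equal-area frame so that pixel counts convert
#' to hectares exactly.
#'
#' @param origin_x,origin_y Projected coordinates (m) of the upper-left grid
#'   corner.
#' @param pixel_size Pixel edge length in metres; must be positive. A 50 m
#'   pixel covers 0.25 ha.
#' @param n_rows,n_cols Raster dimensions (>= 1).
#' @param crs_label Free-text label for the coordinate reference system
#'   (e.g. an Albers equal-area projection); carried as metadata.
#'
#' @return An object of class `grid_spec`.
#' @examples
#' spec <- grid_spec(0, 5000, pixel_size = 50, n_rows = 100, n_cols = 100)
#' pixel_area_ha(spec)  # 0.25
#' @export
grid_spec <- function(origin_x = 0, origin_y = 0, pixel_size = 50,
                      n_rows, n_cols, crs_label = "equal-area (unspecified)") {
  stopifnot(is.numeric(origin_x), is.numeric(origin_y), length(pixel_size) == 1)
  if (!is.numeric(pixel_size) || pixel_size <= 0) {
    rlang::abort("`pixel_size` must be a positive number of metres.")
  }
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L) {
    rlang::abort("`n_rows` and `n_cols` must be integers >= 1.")
  }
  structure(
    list(origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         pixel_size = as.numeric(pixel_size),
         n_rows = n_rows, n_cols = n_cols,
         crs_label = as.character(crs_label)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d pixels of %g m (%g ha each)\n",
              x$n_rows, x$n_cols, x$pixel_size, pixel_area_ha(x)))
  cat(sprintf("  origin (upper-left): (%g, %g)  crs: %s\n",
              x$origin_x, x$origin_y, x$crs_label))
  invisible(x)
}

#' @rdname grid_spec
#' @param spec A `grid_spec`.
#' @export
pixel_area_ha <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  spec$pixel_size^2 / 1e4
}

same_spec <- function(a, b) {
  isTRUE(all.equal(a$origin_x, b$origin_x)) &&
    isTRUE(all.equal(a$origin_y, b$origin_y)) &&
    isTRUE(all.equal(a$pixel_size, b$pixel_size)) &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols
}

check_same_spec <- function(a, b, what = "grids") {
  if (!same_spec(a, b)) {
    rlang::abort(sprintf("The %s do not share one grid geometry.", what))
  }
  invisible(TRUE)
}
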