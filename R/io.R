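#' Read and write rasters as ESRI ASCII grids
#'
#' Grids are exchanged in the ESRI ASCII grid format (`.asc`): a six-line
#' header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by rows of values from the top row down. It is a
#' plain-text, single-band raster format readable by any GIS. Binary maps are
#' written as 0/1 integers (nodata -9999), fraction maps as floats.
#'
#' @param grid A [burn_grid()] or [fraction_grid()].
#' @param path File path (`.asc`).
#' @param year Year label to attach on read (the format carries none).
#' @return `write_asc()` returns `path` invisibly; `read_burn_asc()` a
#'   [burn_grid()]; `read_fraction_asc()` a [fraction_grid()] (factor 1).
#' @export
write_asc <- function(grid, path) {
  stopifnot(inherits(grid, "burn_grid") || inherits(grid, "fraction_grid"))
  spec <- grid$spec
  hdr <- c(
    sprintf("ncols %d", spec$n_cols),
    sprintf("nrows %d", spec$n_rows),
    sprintf("xllcorner %.10g", spec$origin_x),
    sprintf("yllcorner %.10g", spec$origin_y - spec$n_rows * spec$pixel_size),
    sprintf("cellsize %.10g", spec$pixel_size),
    "NODATA_value -9999"
  )
  rows <- apply(grid$values, 1, paste, collapse = " ")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

read_asc_raw <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- strsplit(trimws(hdr), "\\s+")
  vals <- stats::setNames(purrr::map_chr(kv, 2), tolower(purrr::map_chr(kv, 1)))
  nc <- as.integer(vals[["ncols"]]); nr <- as.integer(vals[["nrows"]])
  cs <- as.numeric(vals[["cellsize"]])
  x0 <- as.numeric(vals[["xllcorner"]])
  y0 <- as.numeric(vals[["yllcorner"]]) + nr * cs
  m <- do.call(rbind, purrr::map(lines[-(1:6)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  stopifnot(nrow(m) == nr, ncol(m) == nc)
  list(values = m, spec = grid_spec(x0, y0, cs, nr, nc))
}

#' @rdname write_asc
#' @export
read_burn_asc <- function(path, year = NA_integer_) {
  raw <- read_asc_raw(path)
  v <- raw$values
  v[v == -9999] <- 0
  burn_grid(matrix(as.integer(v), nrow(v), ncol(v)), raw$spec, year = year)
}

#' @rdname write_asc
#' @param factor Aggregation factor to record on the read fraction grid.
#' @export
read_fraction_asc <- function(path, year = NA_integer_, factor = 1L) {
  raw <- read_asc_raw(path)
  v <- raw$values
  v[v == -9999] <- 0
  fraction_grid(v, raw$spec, factor = factor, year = year)
}

#' Read fire perimeters from GeoJSON
#'
#' Parses a GeoJSON `FeatureCollection` of `Polygon` / `MultiPolygon`
#' features into a [fire_events()] table. Coordinates must already be in a
#' projected equal-area frame (metres): no reprojection is performed.
#' Feature properties used: a fire id (property `id`, `fire_id` or `FIREID`),
#' the year (`year` or `FIREYEAR`), and optionally a recorded area in
#' hectares (`area_ha`); when absent, ids are generated and areas computed
#' from the geometry. A MultiPolygon becomes several rows sharing one id.
#'
#' @param path Path to a `.geojson` file.
#' @return A [fire_events()] tibble.
#' @export
read_fire_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) rlang::abort("Expected a GeoJSON FeatureCollection.")
  prop <- function(ft, keys, default) {
    for (k in keys) if (!is.null(ft$properties[[k]])) return(ft$properties[[k]])
    default
  }
  ids <- character(0); yrs <- integer(0); areas <- numeric(0)
  geoms <- list()
  for (i in seq_along(gj$features)) {
    ft <- gj$features[[i]]
    gtype <- ft$geometry$type
    coords <- ft$geometry$coordinates
    polys <- switch(gtype,
                    Polygon = list(coords),
                    MultiPolygon = coords,
                    rlang::abort(sprintf("Unsupported geometry type '%s'.", gtype)))
    id <- as.character(prop(ft, c("id", "fire_id", "FIREID"), sprintf("feature_%03d", i)))
    yr <- as.integer(prop(ft, c("year", "FIREYEAR"), NA))
    ar <- prop(ft, "area_ha", NA_real_)
    for (pg in polys) {
      rings <- purrr::map(pg, function(ring) {
        do.call(rbind, purrr::map(ring, function(xy) c(xy[[1]], xy[[2]])))
      })
      ids <- c(ids, id); yrs <- c(yrs, yr)
      areas <- c(areas, as.numeric(ar))
      geoms <- c(geoms, list(rings))
    }
  }
  if (all(is.na(areas))) areas <- NULL
  fire_events(ids, yrs, geoms, area_ha = areas)
}

#' Export per-year burned-area totals to CSV
#'
#' @param grids A list of [burn_grid()] objects (one per year).
#' @param path Output CSV path.
#' @return The written tibble (`year`, `burned_area_ha`), invisibly.
#' @export
write_annual_totals_csv <- function(grids, path) {
  tab <- tibble::tibble(
    year = purrr::map_int(grids, "year"),
    burned_area_ha = purrr::map_dbl(grids, burned_area_ha)
  )
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
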