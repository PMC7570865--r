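#' Build a table of reference fire events
#'
#' Fire events are kept in a tibble with one row per fire: an id, the fire
#' year, the perimeter geometry, the burned area in hectares and the size
#' category (see [fire_size_category()]). The geometry of each fire is a list
#' of rings; each ring is a two-column matrix of projected `(x, y)` vertices
#' (metres, equal-area frame), the first ring being the outer perimeter and
#' any further rings holes (unburned islands). Rings must be simple: a
#' self-intersecting ring is rejected.
#'
#' @param id Character vector of fire identifiers.
#' @param year Integer vector of fire years.
#' @param geometry List of geometries (each a list of ring matrices, or a
#'   single ring matrix which is promoted to a one-ring list).
#' @param area_ha Optional recorded burned areas (ha); when omitted, computed
#'   from the polygon geometry (outer ring area minus holes).
#' @return A tibble of class `fire_events` with columns `id`, `year`,
#'   `area_ha`, `category`, `geometry`.
#' @export
fire_events <- function(id, year, geometry, area_ha = NULL) {
  stopifnot(length(id) == length(year), length(id) == length(geometry))
  geometry <- purrr::map(geometry, function(g) {
    if (is.matrix(g)) g <- list(g)
    purrr::map(g, check_ring)
  })
  if (is.null(area_ha)) {
    area_ha <- purrr::map_dbl(geometry, polygon_area_m2) / 1e4
  } else if (anyNA(area_ha)) {
    # recorded areas may be patchy; fall back to the geometry where absent
    miss <- is.na(area_ha)
    area_ha[miss] <- purrr::map_dbl(geometry[miss], polygon_area_m2) / 1e4
  }
  if (any(area_ha <= 0)) {
    rlang::abort("Every fire must have a positive burned area.")
  }
  tibble::new_tibble(
    tibble::tibble(id = as.character(id), year = as.integer(year),
                   area_ha = as.numeric(area_ha),
                   category = fire_size_category(area_ha),
                   geometry = geometry),
    class = "fire_events"
  )
}

# Validate one ring: >= 3 distinct vertices, numeric, simple (no proper
# self-intersection). Returns the ring unclosed (last vertex != first).
check_ring <- function(ring) {
  if (!is.matrix(ring) || ncol(ring) != 2 || !is.numeric(ring)) {
    rlang::abort("Each ring must be a numeric matrix with two columns (x, y).")
  }
  n <- nrow(ring)
  if (n >= 2 && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  if (nrow(ring) < 3) rlang::abort("A ring needs at least three distinct vertices.")
  if (ring_self_intersects(ring)) {
    rlang::abort("Self-intersecting ring: fix the perimeter geometry before rasterizing.")
  }
  ring
}

# Proper-crossing test between non-adjacent edges of a closed ring.
ring_self_intersects <- function(ring) {
  n <- nrow(ring)
  a <- ring
  b <- ring[c(2:n, 1), , drop = FALSE]
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    if (i == 1) js <- js[js != n]            # edge n is adjacent to edge 1
    for (j in js) {
      d1 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[j, 1], a[j, 2])
      d2 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[j, 1], b[j, 2])
      d3 <- cross(a[j, 1], a[j, 2], b[j, 1], b[j, 2], a[i, 1], a[i, 2])
      d4 <- cross(a[j, 1], a[j, 2], b[j, 1], b[j, 2], b[i, 1], b[i, 2])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

# Shoelace area of one unclosed ring (m^2), absolute value.
ring_area_m2 <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Area of a polygon given as list(outer, holes...) in m^2.
polygon_area_m2 <- function(rings) {
  a <- ring_area_m2(rings[[1]])
  if (length(rings) > 1) {
    a <- a - sum(purrr::map_dbl(rings[-1], ring_area_m2))
  }
  max(a, 0)
}

# Sutherland-Hodgman clip of an unclosed ring to an axis-aligned rectangle.
# The clip window is convex, so the clipped shoelace area is exact for any
# simple subject ring (degenerate bridge edges contribute zero area).
clip_ring_rect <- function(ring, xmin, xmax, ymin, ymax) {
  clip_half <- function(pts, inside, intersect) {
    n <- nrow(pts)
    if (n == 0) return(pts)
    out_x <- numeric(2 * n); out_y <- numeric(2 * n); k <- 0
    ins <- inside(pts[, 1], pts[, 2])
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      if (ins[i]) {
        k <- k + 1; out_x[k] <- pts[i, 1]; out_y[k] <- pts[i, 2]
        if (!ins[j]) {
          p <- intersect(pts[i, ], pts[j, ])
          k <- k + 1; out_x[k] <- p[1]; out_y[k] <- p[2]
        }
      } else if (ins[j]) {
        p <- intersect(pts[i, ], pts[j, ])
        k <- k + 1; out_x[k] <- p[1]; out_y[k] <- p[2]
      }
    }
    cbind(out_x[seq_len(k)], out_y[seq_len(k)])
  }
  at_x <- function(v) function(p, q) {
    t <- (v - p[1]) / (q[1] - p[1]); c(v, p[2] + t * (q[2] - p[2]))
  }
  at_y <- function(v) function(p, q) {
    t <- (v - p[2]) / (q[2] - p[2]); c(p[1] + t * (q[1] - p[1]), v)
  }
  pts <- ring
  pts <- clip_half(pts, function(x, y) x >= xmin, at_x(xmin))
  pts <- clip_half(pts, function(x, y) x <= xmax, at_x(xmax))
  pts <- clip_half(pts, function(x, y) y >= ymin, at_y(ymin))
  pts <- clip_half(pts, function(x, y) y <= ymax, at_y(ymax))
  pts
}

clipped_area <- function(ring, xmin, xmax, ymin, ymax) {
  pts <- clip_ring_rect(ring, xmin, xmax, ymin, ymax)
  if (nrow(pts) < 3) return(0)
  ring_area_m2(pts)
}

#' Burned-cover fraction of each pixel under a set of fire perimeters
#'
#' Computes, by exact polygon-pixel intersection (polygon clipping against
#' each pixel rectangle and the shoelace formula), the fraction of every
#' pixel's area covered by the fire perimeters. Fires are assumed
#' non-overlapping, so contributions from separate fires add; accumulated
#' fractions are capped at 1.
#'
#' @param events A [fire_events()] table (all rows from one year).
#' @param spec The target [grid_spec()].
#' @return A [fraction_grid()] on `spec` (aggregation factor 1).
#' @export
cover_fraction <- function(events, spec) {
  stopifnot(inherits(events, "fire_events") || inherits(events, "data.frame"),
            inherits(spec, "grid_spec"))
  years <- unique(events$year)
  if (length(years) > 1) {
    rlang::abort("Rasterize one year at a time (split the events by year).")
  }
  s <- spec$pixel_size
  x0 <- spec$origin_x; y0 <- spec$origin_y
  x1 <- x0 + spec$n_cols * s; y1 <- y0 - spec$n_rows * s
  frac <- matrix(0, spec$n_rows, spec$n_cols)
  parea <- s * s
  for (gi in seq_along(events$geometry)) {
    rings <- purrr::map(events$geometry[[gi]], check_ring)
    bb <- apply(do.call(rbind, rings), 2, range)
    if (bb[2, 1] <= x0 || bb[1, 1] >= x1 || bb[2, 2] <= y1 || bb[1, 2] >= y0) {
      rlang::warn(sprintf("Fire '%s' lies entirely outside the grid; it contributes nothing.",
                          events$id[[gi]]))
      next
    }
    c_lo <- max(1L, floor((bb[1, 1] - x0) / s) + 1L)
    c_hi <- min(spec$n_cols, ceiling((bb[2, 1] - x0) / s))
    r_lo <- max(1L, floor((y0 - bb[2, 2]) / s) + 1L)
    r_hi <- min(spec$n_rows, ceiling((y0 - bb[1, 2]) / s))
    for (r in r_lo:r_hi) {
      ytop <- y0 - (r - 1) * s; ybot <- y0 - r * s
      for (cc in c_lo:c_hi) {
        xl <- x0 + (cc - 1) * s; xr <- xl + s
        a <- clipped_area(rings[[1]], xl, xr, ybot, ytop)
        if (length(rings) > 1 && a > 0) {
          a <- a - sum(purrr::map_dbl(rings[-1], clipped_area, xl, xr, ybot, ytop))
        }
        if (a > 0) frac[r, cc] <- frac[r, cc] + a / parea
      }
    }
  }
  fraction_grid(pmin(frac, 1), spec, factor = 1L,
                year = if (length(years) == 1) years else NA_integer_)
}

#' Rasterize fire perimeters with the maximum-area rule
#'
#' Assigns each pixel the class occupying the larger share of its footprint:
#' a pixel is labelled Burned iff the burned fraction of its area is at least
#' 0.5. The tie at exactly one half goes to Burned; the rule is applied with a
#' 1e-9 tolerance so that exact half-covers computed in floating point label
#' deterministically. This is the standard construction of a binary reference
#' map from vector fire perimeters on an equal-area grid.
#'
#' @inheritParams cover_fraction
#' @return A [burn_grid()] on `spec`.
#' @examples
#' spec <- grid_spec(0, 100, pixel_size = 50, n_rows = 2, n_cols = 2)
#' sq <- rbind(c(0, 100), c(50, 100), c(50, 50), c(0, 50))  # one full pixel
#' ev <- fire_events("f1", 2005L, list(sq))
#' rasterize_fires(ev, spec)$values
#' @export
rasterize_fires <- function(events, spec) {
  frac <- cover_fraction(events, spec)
  burn_grid((frac$values >= 0.5 - 1e-9) * 1L, spec, year = frac$year)
}
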