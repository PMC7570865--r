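# Independent oracles used by the tests. These deliberately re-derive results
# by brute force / first principles, separately from the package's own code
# paths.

# Even-odd ray-casting point-in-polygon (single unclosed ring).
pip <- function(px, py, ring) {
  n <- nrow(ring)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if ((yi > py) != (yj > py)) {
      xint <- xi + (py - yi) / (yj - yi) * (xj - xi)
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Point in polygon-with-holes: inside outer ring and outside every hole.
pip_poly <- function(px, py, rings) {
  if (!pip(px, py, rings[[1]])) return(FALSE)
  if (length(rings) > 1) {
    for (h in rings[-1]) if (pip(px, py, h)) return(FALSE)
  }
  TRUE
}

# Supersampling rasterizer: label each pixel by majority vote over a 10 x 10
# lattice of sample points (subcell centres). Reference semantics for the
# maximum-area rule.
supersample_rasterize <- function(events, spec, k = 10L) {
  s <- spec$pixel_size
  frac <- matrix(0, spec$n_rows, spec$n_cols)
  off <- (seq_len(k) - 0.5) / k * s
  for (gi in seq_along(events$geometry)) {
    rings <- events$geometry[[gi]]
    for (r in seq_len(spec$n_rows)) {
      ytop <- spec$origin_y - (r - 1) * s
      for (cc in seq_len(spec$n_cols)) {
        xl <- spec$origin_x + (cc - 1) * s
        hits <- 0L
        for (dx in off) for (dy in off) {
          if (pip_poly(xl + dx, ytop - dy, rings)) hits <- hits + 1L
        }
        frac[r, cc] <- frac[r, cc] + hits / (k * k)
      }
    }
  }
  list(frac = frac, labels = (frac >= 0.5) * 1L)
}

# Exhaustive Pareto sweep oracle: evaluate the area-based CE/OE at the given
# thresholds by direct loops, then drop dominated points by pairwise
# comparison (O(n^2), independent of the package's sort-based filter).
brute_pareto <- function(f, thresholds) {
  tot <- sum(f)
  pts <- t(vapply(thresholds, function(p) {
    in_b <- if (p > 0) f >= p else f > 0
    nb <- sum(in_b)
    ce <- if (nb > 0) sum(1 - f[in_b]) / nb else 0
    oe <- sum(f[!in_b]) / tot
    c(ce, oe)
  }, numeric(2)))
  pts <- unique(round(pts, 14))
  n <- nrow(pts)
  dominated <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j &&
          pts[j, 1] <= pts[i, 1] && pts[j, 2] <= pts[i, 2] &&
          (pts[j, 1] < pts[i, 1] || pts[j, 2] < pts[i, 2])) {
        dominated[i] <- TRUE
        break
      }
    }
  }
  pts <- pts[!dominated, , drop = FALSE]
  pts[order(pts[, 1]), , drop = FALSE]
}

# Trapezoid integral of the oracle curve.
brute_aupb <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum((pts[-1, 2] + pts[-nrow(pts), 2]) / 2 * diff(pts[, 1]))
}

# Closed-form OLS via the normal equations.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  yhat <- X %*% beta
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(intercept = beta[1], slope = beta[2], r_squared = r2)
}

# Random binary burn grid on a fresh spec.
random_burn_grid <- function(nr, nc, p_burn = 0.3, pixel = 50, year = 2000L) {
  spec <- grid_spec(0, nr * pixel, pixel, nr, nc)
  burn_grid(matrix(rbinom(nr * nc, 1, p_burn), nr, nc), spec, year = year)
}

# One contiguous synthetic scar of exactly `px` pixels.
scar_grid <- function(px, nr, nc, seed, pixel = 50) {
  spec <- grid_spec(0, nr * pixel, pixel, nr, nc)
  cfg <- landscape_config(spec, sizes_ha = px * pixel_area_ha(spec), seed = seed)
  generate_landscape(cfg, year = 2000L)$grid
}
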