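#' Configure a synthetic fire landscape
#'
#' The generator emulates the statistical structure of a boreal fire season
#' as seen in long reference records: a handful of fire-size categories whose
#' counts are heavily skewed (many very small fires, area dominated by the few
#' large and very large ones), contiguous irregular scar shapes, and strong
#' year-on-year variability when used through [generate_multiyear()].
#'
#' Fire sizes are drawn log-uniformly within their category's `[lower,
#' upper)` bounds (see [fire_size_breaks_ha()]); the very small category is
#' bounded below by one pixel and the very large category above by
#' 1,000,000 ha. Log-uniform keeps every category reachable while letting the
#' configured counts set the heavy tail; the size-frequency law inside a
#' category is not asserted beyond that and can be overridden fire by fire
#' with `sizes_ha`.
#'
#' @param spec A [grid_spec()] large enough to host the requested total area.
#' @param n_fires Named integer vector of fire counts per category; names
#'   among `very_small`, `small`, `medium`, `large`, `very_large`.
#' @param annual_total_target_ha Optional total burned-area target (ha);
#'   drawn sizes are rescaled multiplicatively to meet it, keeping counts and
#'   category proportions.
#' @param sizes_ha Optional explicit vector of fire sizes (ha), overriding
#'   `n_fires` and the size draw entirely.
#' @param seed Integer seed; the whole landscape is deterministic given the
#'   config.
#' @return A `landscape_config` list.
#' @export
landscape_config <- function(spec, n_fires = c(very_small = 4, small = 3,
                                               medium = 2, large = 1,
                                               very_large = 0),
                             annual_total_target_ha = NULL,
                             sizes_ha = NULL, seed = 1L) {
  stopifnot(inherits(spec, "grid_spec"))
  cats <- c("very_small", "small", "medium", "large", "very_large")
  if (is.null(sizes_ha)) {
    if (is.null(names(n_fires)) || !all(names(n_fires) %in% cats)) {
      rlang::abort("`n_fires` must be named with fire size categories.")
    }
    if (any(n_fires < 0)) rlang::abort("Fire counts must be >= 0.")
    full <- stats::setNames(rep(0L, 5), cats)
    full[names(n_fires)] <- as.integer(n_fires)
    n_fires <- full
  } else {
    if (any(sizes_ha <= 0)) rlang::abort("Explicit fire sizes must be positive.")
    n_fires <- NULL
  }
  structure(list(spec = spec, n_fires = n_fires,
                 annual_total_target_ha = annual_total_target_ha,
                 sizes_ha = sizes_ha, seed = as.integer(seed)),
            class = "landscape_config")
}

# Draw one size (ha) log-uniformly within a category's [lower, upper) bounds.
draw_sizes_ha <- function(n_fires, pixel_ha) {
  lows <- c(pixel_ha, fire_size_breaks_ha())
  highs <- c(fire_size_breaks_ha(), 1e6)
  cats <- names(n_fires)
  unlist(purrr::map(seq_along(cats), function(k) {
    if (n_fires[k] == 0) return(numeric(0))
    exp(stats::runif(n_fires[k], log(lows[k]), log(highs[k])))
  }))
}

# Grow one 4-connected blob of `size` pixels by random boundary accretion on
# the free pixels of `occupied`. Returns pixel indices or NULL if stuck.
grow_blob <- function(occupied, size, nr, nc) {
  free <- which(!occupied)
  if (length(free) == 0) return(NULL)
  start <- free[sample.int(length(free), 1)]
  cells <- integer(size)
  cells[1] <- start
  occ <- occupied
  occ[start] <- TRUE
  frontier <- neighbours4(start, nr, nc)
  k <- 1L
  while (k < size) {
    frontier <- frontier[!occ[frontier]]
    if (length(frontier) == 0) return(NULL)
    pick <- frontier[sample.int(length(frontier), 1)]
    occ[pick] <- TRUE
    k <- k + 1L
    cells[k] <- pick
    frontier <- c(frontier, neighbours4(pick, nr, nc))
  }
  cells
}

# 4-neighbour linear indices of cells (column-major), dropping off-grid moves.
neighbours4 <- function(cells, nr, nc) {
  r <- ((cells - 1L) %% nr) + 1L
  cl <- ((cells - 1L) %/% nr) + 1L
  up <- cells[r > 1L] - 1L
  dn <- cells[r < nr] + 1L
  lf <- cells[cl > 1L] - nr
  rt <- cells[cl < nc] + nr
  c(up, dn, lf, rt)
}

#' Generate a synthetic annual fire landscape
#'
#' Draws fire sizes per the configuration, converts each to a whole pixel
#' count, and grows each fire as a contiguous 4-connected blob by seeded
#' random boundary accretion, largest first, without overlaps. Blob growth
#' produces irregular perimeters, so edge-biased product degradation
#' ([perturb_product()]) and sub-pixel fragmentation behave non-trivially.
#'
#' @param config A [landscape_config()].
#' @param year Year label for the returned maps.
#' @return A list with `events` (a [fire_events()]-shaped tibble of realized
#'   fires: id, year, area_ha, category, n_pixels; no vector geometry) and
#'   `grid` (the union [burn_grid()]).
#' @export
generate_landscape <- function(config, year = NA_integer_) {
  stopifnot(inherits(config, "landscape_config"))
  spec <- config$spec
  px_ha <- pixel_area_ha(spec)
  withr::with_seed(config$seed, {
    sizes_ha <- config$sizes_ha %||% draw_sizes_ha(config$n_fires, px_ha)
    if (!is.null(config$annual_total_target_ha) && length(sizes_ha) > 0) {
      sizes_ha <- sizes_ha * config$annual_total_target_ha / sum(sizes_ha)
    }
    sizes_px <- pmax(1L, as.integer(round(sizes_ha / px_ha)))
    n_px_total <- sum(sizes_px)
    n_grid <- spec$n_rows * spec$n_cols
    if (n_px_total > 0.5 * n_grid) {
      rlang::abort(sprintf(
        "Requested %d burned pixels exceed half the %d-pixel grid; enlarge the grid.",
        n_px_total, n_grid))
    }
    occupied <- matrix(FALSE, spec$n_rows, spec$n_cols)
    ord <- order(sizes_px, decreasing = TRUE)
    cells_by_fire <- vector("list", length(sizes_px))
    for (i in ord) {
      got <- NULL
      for (try in seq_len(25)) {
        got <- grow_blob(occupied, sizes_px[i], spec$n_rows, spec$n_cols)
        if (!is.null(got)) break
      }
      if (is.null(got)) {
        rlang::abort(sprintf(
          "Could not pack fire of %d pixels after 25 attempts (achieved %d of %d requested pixels).",
          sizes_px[i], sum(occupied), n_px_total))
      }
      occupied[got] <- TRUE
      cells_by_fire[[i]] <- got
    }
  })
  realized_ha <- sizes_px * px_ha
  events <- tibble::tibble(
    id = sprintf("fire_%03d", seq_along(sizes_px)),
    year = as.integer(year),
    area_ha = realized_ha,
    category = fire_size_category(realized_ha),
    n_pixels = sizes_px
  )
  list(events = events,
       grid = burn_grid(occupied * 1L, spec, year = year))
}

#' Configure a synthetic product degradation
#'
#' @param target_ce Target commission error in `[0, 1)`: the fraction of the
#'   product's burned pixels that are not burned in the reference.
#' @param target_oe Target omission error in `[0, 1]`: the fraction of
#'   reference burned pixels the product misses.
#' @param spatial_mode `"uniform"` removes/adds pixels at random anywhere
#'   (statistically clean; exact rate recovery); `"perimeter_first"` erodes
#'   omissions from scar edges inward and commits adjacent to scars,
#'   mimicking real products that miss scar margins.
#' @param seed Integer seed.
#' @return A `perturb_config` list.
#' @export
perturb_config <- function(target_ce = 0, target_oe = 0,
                           spatial_mode = c("uniform", "perimeter_first"),
                           seed = 1L) {
  if (target_ce < 0 || target_ce >= 1) {
    rlang::abort("`target_ce` must lie in [0, 1): a map that is all commission is unreachable.")
  }
  if (target_oe < 0 || target_oe > 1) rlang::abort("`target_oe` must lie in [0, 1].")
  structure(list(target_ce = target_ce, target_oe = target_oe,
                 spatial_mode = match.arg(spatial_mode),
                 seed = as.integer(seed)),
            class = "perturb_config")
}

# Peel the reference scar into edge layers (distance-to-unburned rings).
# Returns an integer matrix: 0 outside, k = layer index from the edge.
edge_layers <- function(values) {
  nr <- nrow(values); nc <- ncol(values)
  layer <- matrix(0L, nr, nc)
  remaining <- values == 1L
  k <- 0L
  while (any(remaining)) {
    k <- k + 1L
    padded <- rbind(FALSE, cbind(FALSE, remaining, FALSE), FALSE)
    inner <- padded[2:(nr + 1), 2:(nc + 1)] &
      padded[1:nr, 2:(nc + 1)] & padded[3:(nr + 2), 2:(nc + 1)] &
      padded[2:(nr + 1), 1:nc] & padded[2:(nr + 1), 3:(nc + 2)]
    edge <- remaining & !inner
    if (!any(edge)) edge <- remaining    # safety: solid torus-free core
    layer[edge] <- k
    remaining <- remaining & !edge
  }
  layer
}

#' Degrade a reference map into a synthetic product with known error rates
#'
#' Builds a product map whose measured commission and omission errors (by the
#' pixel-level confusion matrix) match the configured targets to the nearest
#' achievable pixel count. First, `round(target_oe * n_burned)` reference
#' pixels are removed (omission); then false-burned pixels are added until
#' `added / (kept + added)` reaches `target_ce` (commission). In
#' `"uniform"` mode removals and additions are sampled uniformly; in
#' `"perimeter_first"` mode removals erode whole edge layers (random within
#' the last partial layer) and additions grow outward rings around the scars.
#'
#' @param reference A [burn_grid()]; must contain burned pixels unless
#'   `target_oe = 1`.
#' @param cfg A [perturb_config()].
#' @return A [burn_grid()] product map on the same geometry.
#' @examples
#' spec <- grid_spec(n_rows = 40, n_cols = 40, pixel_size = 50)
#' ref <- generate_landscape(landscape_config(spec, sizes_ha = 25, seed = 7))$grid
#' prod <- perturb_product(ref, perturb_config(0.1, 0.4, seed = 7))
#' accuracy_metrics(confusion_counts(prod, ref))[, c("ce", "oe")]
#' @export
perturb_product <- function(reference, cfg) {
  stopifnot(inherits(reference, "burn_grid"), inherits(cfg, "perturb_config"))
  v <- reference$values
  burned <- which(v == 1L)
  nb <- length(burned)
  if (nb == 0 && cfg$target_oe < 1) {
    rlang::abort("Empty reference: only `target_oe = 1` is representable.")
  }
  out <- v
  withr::with_seed(cfg$seed, {
    n_omit <- round(cfg$target_oe * nb)
    if (n_omit > 0) {
      if (cfg$spatial_mode == "uniform") {
        drop <- sample(burned, n_omit)
      } else {
        lay <- edge_layers(v)
        drop <- integer(0)
        k <- 1L
        while (length(drop) < n_omit) {
          ring <- which(lay == k)
          need <- n_omit - length(drop)
          if (length(ring) <= need) {
            drop <- c(drop, ring)
          } else {
            drop <- c(drop, sample(ring, need))
          }
          k <- k + 1L
        }
      }
      out[drop] <- 0L
    }
    kept <- nb - n_omit
    n_add <- round(cfg$target_ce * kept / (1 - cfg$target_ce))
    if (n_add > 0) {
      candidates <- which(v == 0L & out == 0L)
      if (cfg$spatial_mode == "uniform") {
        if (n_add > length(candidates)) {
          rlang::abort("Not enough unburned pixels to reach the commission target.")
        }
        add <- sample(candidates, n_add)
      } else {
        add <- integer(0)
        cur <- out
        nr <- nrow(v); nc <- ncol(v)
        while (length(add) < n_add) {
          scar <- which(cur == 1L)
          halo <- unique(neighbours4(scar, nr, nc))
          halo <- halo[cur[halo] == 0L & v[halo] == 0L]
          if (length(halo) == 0) {
            # no scar to grow from (or it is walled in): fall back to uniform
            pool <- which(cur == 0L & v == 0L)
            if (length(pool) == 0) rlang::abort("Grid exhausted while adding commission pixels.")
            halo <- pool
          }
          need <- n_add - length(add)
          picked <- if (length(halo) <= need) halo else sample(halo, need)
          cur[picked] <- 1L
          add <- c(add, picked)
        }
      }
      out[add] <- 1L
    }
  })
  burn_grid(out, reference$spec, year = reference$year)
}

#' Generate a multi-year series of reference and product maps
#'
#' Applies [generate_landscape()] and [perturb_product()] year by year, with
#' per-year seeds derived deterministically from one master seed so that
#' years are statistically independent yet the whole series is reproducible.
#' Year-to-year variability (e.g. annual totals spanning an order of
#' magnitude) is controlled entirely by the per-year configs.
#'
#' @param years Integer vector of year labels.
#' @param landscape_configs A single [landscape_config()] (recycled) or a
#'   list, one per year. A config with zero fires yields an empty reference
#'   and product for that year.
#' @param perturb_configs A single [perturb_config()] (recycled) or a list,
#'   one per year.
#' @param seed Master integer seed; per-year seeds are an arithmetic mix of
#'   it and the year.
#' @return A tibble with one row per year: `year`, `reference` and `product`
#'   ([burn_grid()] list-columns), `events` (list-column of realized-fire
#'   tibbles), `bar_ha`, `bap_ha`.
#' @export
generate_multiyear <- function(years, landscape_configs, perturb_configs,
                               seed = 1L) {
  years <- as.integer(years)
  n <- length(years)
  if (inherits(landscape_configs, "landscape_config")) {
    landscape_configs <- rep(list(landscape_configs), n)
  }
  if (inherits(perturb_configs, "perturb_config")) {
    perturb_configs <- rep(list(perturb_configs), n)
  }
  stopifnot(length(landscape_configs) == n, length(perturb_configs) == n)
  rows <- purrr::map(seq_len(n), function(i) {
    yr <- years[i]
    lc <- landscape_configs[[i]]
    pc <- perturb_configs[[i]]
    lc$seed <- derive_seed(seed, yr, 0L)
    pc$seed <- derive_seed(seed, yr, 1L)
    empty <- (!is.null(lc$n_fires) && sum(lc$n_fires) == 0) ||
      (!is.null(lc$sizes_ha) && length(lc$sizes_ha) == 0)
    if (empty) {
      z <- burn_grid(matrix(0L, lc$spec$n_rows, lc$spec$n_cols), lc$spec, year = yr)
      return(tibble::tibble(year = yr, reference = list(z), product = list(z),
                            events = list(tibble::tibble()),
                            bar_ha = 0, bap_ha = 0))
    }
    ls <- generate_landscape(lc, year = yr)
    prod <- perturb_product(ls$grid, pc)
    tibble::tibble(year = yr, reference = list(ls$grid), product = list(prod),
                   events = list(ls$events),
                   bar_ha = burned_area_ha(ls$grid),
                   bap_ha = burned_area_ha(prod))
  })
  dplyr::bind_rows(rows)
}

# 32-bit-safe deterministic seed mix; `slot` separates generator stages.
derive_seed <- function(master, year, slot = 0L) {
  as.integer(((master %% 2^20) * 1000003 + year * 7919 + slot * 104729) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
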