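test_that("a forced-size fire is one 4-connected blob with exact bookkeeping", {
  spec <- grid_spec(n_rows = 40, n_cols = 40, origin_y = 2000, pixel_size = 50)
  ls <- generate_landscape(landscape_config(spec, sizes_ha = 25, seed = 3),
                           year = 2004L)
  expect_equal(sum(ls$grid$values), 100)            # 25 ha = 100 pixels
  expect_equal(ls$events$area_ha, 25)
  expect_equal(ls$events$n_pixels, 100L)
  expect_equal(burned_area_ha(ls$grid), 25)
  # 4-connectivity: the burned set is one connected component
  v <- ls$grid$values
  comp <- matrix(0L, nrow(v), ncol(v))
  start <- which(v == 1L)[1]
  queue <- start; comp[start] <- 1L
  nr <- nrow(v); nc <- ncol(v)
  while (length(queue) > 0) {
    cur <- queue[1]; queue <- queue[-1]
    r <- ((cur - 1) %% nr) + 1; cc <- ((cur - 1) %/% nr) + 1
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; c2 <- cc + d[2]
      if (rr >= 1 && rr <= nr && c2 >= 1 && c2 <= nc) {
        idx <- (c2 - 1) * nr + rr
        if (v[idx] == 1L && comp[idx] == 0L) {
          comp[idx] <- 1L; queue <- c(queue, idx)
        }
      }
    }
  }
  expect_equal(sum(comp), sum(v))
})

test_that("landscape generation is deterministic for a fixed seed", {
  spec <- grid_spec(n_rows = 60, n_cols = 60, origin_y = 3000, pixel_size = 50)
  cfg <- landscape_config(spec, n_fires = c(very_small = 3, small = 2),
                          annual_total_target_ha = 300, seed = 99)
  a <- generate_landscape(cfg)
  b <- generate_landscape(cfg)
  expect_identical(a$grid$values, b$grid$values)
  expect_identical(a$events, b$events)
  cfg2 <- cfg; cfg2$seed <- 100L
  expect_false(identical(a$grid$values, generate_landscape(cfg2)$grid$values))
})

test_that("skewed category mixes put most burned area in the top categories", {
  # category counts (60, 20, 10, 8, 2) with representative sizes per
  # category, on a 500 m grid so the very large fires fit
  spec <- grid_spec(n_rows = 400, n_cols = 400, origin_y = 2e5, pixel_size = 500)
  cfg <- landscape_config(
    spec,
    sizes_ha = rep(c(50, 300, 3000, 30000, 150000),
                   times = c(60, 20, 10, 8, 2)),
    seed = 5)
  ls <- generate_landscape(cfg)
  shares <- categorize_fires(ls$events)
  top <- sum(shares$area_share_pct[shares$category %in% c("large", "very_large", "medium")])
  top2 <- sum(shares$area_share_pct[shares$category %in% c("large", "very_large")])
  expect_gte(top, 70)
  expect_equal(sum(shares$n_fires), nrow(ls$events))
  # realized categories always match the realized areas
  expect_identical(ls$events$category, fire_size_category(ls$events$area_ha))
  expect_gt(top2, 0)
})

test_that("infeasible packing errors with achieved-vs-requested context", {
  spec <- grid_spec(n_rows = 10, n_cols = 10, origin_y = 500, pixel_size = 50)
  cfg <- landscape_config(spec, sizes_ha = 25, seed = 1)  # 100 px on a 100-px grid
  expect_error(generate_landscape(cfg), "half the")
})

test_that("perturbation with zero targets is the identity", {
  g <- scar_grid(400, 50, 50, seed = 21)
  out <- perturb_product(g, perturb_config(0, 0, seed = 1))
  expect_identical(out$values, g$values)
})

test_that("full omission yields the empty map and the empty-detection metrics", {
  g <- scar_grid(400, 50, 50, seed = 22)
  out <- perturb_product(g, perturb_config(0, 1, seed = 1))
  expect_equal(sum(out$values), 0)
  m <- accuracy_metrics(confusion_counts(out, g))
  expect_equal(m$oe, 1)
  expect_equal(m$ce, 0)
})

test_that("perturbation recovers injected rates on large scars, both modes", {
  g <- scar_grid(6000, 150, 150, seed = 23)
  for (mode in c("uniform", "perimeter_first")) {
    out <- perturb_product(g, perturb_config(0.15, 0.40, mode, seed = 31))
    m <- accuracy_metrics(confusion_counts(out, g))
    expect_lt(abs(m$ce - 0.15), 0.01)
    expect_lt(abs(m$oe - 0.40), 0.01)
  }
})

test_that("perturbation is deterministic per seed and validates its config", {
  g <- scar_grid(500, 60, 60, seed = 24)
  cfg <- perturb_config(0.2, 0.3, seed = 77)
  expect_identical(perturb_product(g, cfg)$values, perturb_product(g, cfg)$values)
  expect_error(perturb_config(1, 0), "unreachable|\\[0, 1\\)")
  empty <- burn_grid(matrix(0L, 4, 4), grid_spec(n_rows = 4, n_cols = 4, pixel_size = 50))
  expect_error(perturb_product(empty, perturb_config(0, 0.5, seed = 1)), "Empty reference")
})

test_that("perimeter-first omission removes edge pixels before interior ones", {
  g <- scar_grid(2000, 100, 100, seed = 25)
  out <- perturb_product(g, perturb_config(0, 0.25, "perimeter_first", seed = 1))
  dropped <- g$values == 1L & out$values == 0L
  # interior pixels (all 4 neighbours burned) should survive a modest erosion
  v <- g$values
  nr <- nrow(v); nc <- ncol(v)
  pad <- rbind(0L, cbind(0L, v, 0L), 0L)
  interior <- v == 1L &
    pad[1:nr, 2:(nc + 1)] == 1L & pad[3:(nr + 2), 2:(nc + 1)] == 1L &
    pad[2:(nr + 1), 1:nc] == 1L & pad[2:(nr + 1), 3:(nc + 2)] == 1L
  deep <- interior
  # pixels whose neighbours are all interior: at least 2 layers from the edge
  padi <- rbind(FALSE, cbind(FALSE, interior, FALSE), FALSE)
  deep2 <- interior &
    padi[1:nr, 2:(nc + 1)] & padi[3:(nr + 2), 2:(nc + 1)] &
    padi[2:(nr + 1), 1:nc] & padi[2:(nr + 1), 3:(nc + 2)]
  if (sum(deep2) > 0 && sum(!deep & v == 1L) >= sum(dropped)) {
    expect_equal(sum(dropped & deep2), 0)
  }
  m <- accuracy_metrics(confusion_counts(out, g))
  expect_lt(abs(m$oe - 0.25), 0.01)
})

test_that("multi-year series are deterministic, year-decoupled and support zero-fire years", {
  spec <- grid_spec(n_rows = 80, n_cols = 80, origin_y = 4000, pixel_size = 50)
  lc <- landscape_config(spec, n_fires = c(very_small = 4, small = 2),
                         annual_total_target_ha = 400, seed = 1)
  pc <- perturb_config(0.1, 0.3, seed = 1)
  s1 <- generate_multiyear(2001:2003, lc, pc, seed = 7)
  s2 <- generate_multiyear(2001:2003, lc, pc, seed = 7)
  expect_identical(purrr::map(s1$reference, "values"),
                   purrr::map(s2$reference, "values"))
  # distinct years give distinct maps
  expect_false(identical(s1$reference[[1]]$values, s1$reference[[2]]$values))
  expect_false(identical(s1$reference[[2]]$values, s1$reference[[3]]$values))
  # zero-fire year
  lc0 <- landscape_config(spec, n_fires = c(very_small = 0), seed = 1)
  s3 <- generate_multiyear(2001L, lc0, pc, seed = 7)
  expect_equal(s3$bar_ha, 0)
  expect_equal(s3$bap_ha, 0)
})

test_that("per-year totals spanning a wide range are achieved within 10%", {
  spec <- grid_spec(n_rows = 300, n_cols = 300, origin_y = 15000, pixel_size = 50)
  targets <- c(150, 600, 2400)   # 16x range, ha
  lcs <- purrr::map(targets, function(t) {
    landscape_config(spec, n_fires = c(very_small = 4, small = 3),
                     annual_total_target_ha = t, seed = 1)
  })
  s <- generate_multiyear(2001:2003, lcs,
                          perturb_config(0, 0, seed = 1), seed = 13)
  expect_true(all(abs(s$bar_ha - targets) / targets <= 0.10))
})
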