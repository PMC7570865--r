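test_that("grid_spec validates geometry and reports pixel area", {
  spec <- grid_spec(0, 5000, pixel_size = 50, n_rows = 100, n_cols = 80)
  expect_equal(pixel_area_ha(spec), 0.25)
  expect_equal(pixel_area_ha(grid_spec(0, 0, 500, 1, 1)), 25)
  expect_error(grid_spec(0, 0, -50, 10, 10), "positive")
  expect_error(grid_spec(0, 0, 50, 0, 10), ">= 1")
})

test_that("burn_grid rejects non-binary values and mismatched dims", {
  spec <- grid_spec(n_rows = 2, n_cols = 2, pixel_size = 50)
  expect_error(burn_grid(matrix(2L, 2, 2), spec), "0.*1")
  expect_error(burn_grid(matrix(0L, 3, 2), spec), "dimensions")
  g <- burn_grid(matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2), spec)
  expect_identical(sum(g$values), 2L)
})

test_that("burned_area_ha converts pixel counts at the grid's pixel size", {
  spec50 <- grid_spec(n_rows = 4, n_cols = 4, pixel_size = 50)
  m <- matrix(0L, 4, 4); m[1:2, 1:4] <- 1L
  expect_equal(burned_area_ha(burn_grid(m, spec50)), 8 * 0.25)  # 2 ha
  expect_equal(burned_area_ha(burn_grid(matrix(0L, 4, 4), spec50)), 0)
  spec500 <- grid_spec(n_rows = 10, n_cols = 10, pixel_size = 500)
  expect_equal(burned_area_ha(burn_grid(matrix(1L, 10, 10), spec500)), 2500)
})

test_that("union_grids is idempotent, commutative, associative, with identity", {
  set.seed(42)
  spec <- grid_spec(n_rows = 8, n_cols = 8, pixel_size = 50)
  gs <- replicate(3, burn_grid(matrix(rbinom(64, 1, 0.4), 8, 8), spec),
                  simplify = FALSE)
  zero <- burn_grid(matrix(0L, 8, 8), spec)
  expect_identical(union_grids(list(gs[[1]], gs[[1]]))$values, gs[[1]]$values)
  expect_identical(union_grids(list(gs[[1]], zero))$values, gs[[1]]$values)
  expect_identical(union_grids(list(gs[[1]], gs[[2]]))$values,
                   union_grids(list(gs[[2]], gs[[1]]))$values)
  expect_identical(
    union_grids(list(union_grids(list(gs[[1]], gs[[2]])), gs[[3]]))$values,
    union_grids(list(gs[[1]], union_grids(list(gs[[2]], gs[[3]]))))$values)
  m <- matrix(0L, 8, 8); m[1, 1] <- 1L
  m2 <- matrix(0L, 8, 8); m2[8, 8] <- 1L
  expect_equal(sum(union_grids(list(burn_grid(m, spec), burn_grid(m2, spec)))$values), 2)
  other <- grid_spec(n_rows = 8, n_cols = 8, pixel_size = 100)
  expect_error(union_grids(list(gs[[1]], burn_grid(matrix(0L, 8, 8), other))),
               "geometry")
})

test_that("aggregation reproduces an independent per-block mean and conserves area", {
  set.seed(7)
  g <- random_burn_grid(30, 30, 0.4)
  fg <- aggregate_fraction(g, 5)
  # direct per-block loop oracle
  for (r in 1:6) for (cc in 1:6) {
    block <- g$values[((r - 1) * 5 + 1):(r * 5), ((cc - 1) * 5 + 1):(cc * 5)]
    expect_identical(fg$values[r, cc], mean(block))
  }
  expect_equal(sum(fg$values) * pixel_area_ha(fg$spec), burned_area_ha(g))
  # trivial cases
  all1 <- burn_grid(matrix(1L, 10, 10), grid_spec(n_rows = 10, n_cols = 10, pixel_size = 50))
  expect_equal(aggregate_fraction(all1, 10)$values, matrix(1, 1, 1))
  checker <- burn_grid(matrix(c(1L, 0L, 0L, 1L), 2, 2),
                       grid_spec(n_rows = 2, n_cols = 2, pixel_size = 50))
  expect_equal(aggregate_fraction(checker, 2)$values, matrix(0.5, 1, 1))
})

test_that("aggregation at factor 1 is the identity and errors on bad factors", {
  set.seed(8)
  g <- random_burn_grid(6, 9, 0.5)
  fg <- aggregate_fraction(g, 1)
  expect_equal(fg$values, g$values + 0)
  expect_error(aggregate_fraction(g, 0), ">= 1")
  expect_error(aggregate_fraction(g, 4), "pad")
})

test_that("zero-padded aggregation flags partial blocks and still conserves area", {
  set.seed(9)
  g <- random_burn_grid(7, 11, 0.5)
  fg <- aggregate_fraction(g, 4, pad = TRUE)
  expect_equal(dim(fg$values), c(2, 3))
  expect_true(all(fg$padded[2, ]))   # padded bottom row
  expect_true(all(fg$padded[, 3]))   # padded right column
  expect_false(fg$padded[1, 1])
  expect_equal(sum(fg$values) * pixel_area_ha(fg$spec), burned_area_ha(g))
})

test_that("full-cover and part-cover rectangles follow the maximum-area rule", {
  spec <- grid_spec(0, 100, pixel_size = 50, n_rows = 2, n_cols = 2)
  full <- rbind(c(0, 100), c(50, 100), c(50, 50), c(0, 50))
  g <- rasterize_fires(fire_events("f", 1L, list(full)), spec)
  expect_identical(g$values, matrix(c(1L, 0L, 0L, 0L), 2, 2))
  r60 <- rbind(c(0, 100), c(30, 100), c(30, 50), c(0, 50))  # 60% of pixel 1
  r40 <- rbind(c(0, 100), c(20, 100), c(20, 50), c(0, 50))  # 40% of pixel 1
  r50 <- rbind(c(0, 100), c(25, 100), c(25, 50), c(0, 50))  # exact tie
  expect_equal(rasterize_fires(fire_events("a", 1L, list(r60)), spec)$values[1, 1], 1L)
  expect_equal(rasterize_fires(fire_events("b", 1L, list(r40)), spec)$values[1, 1], 0L)
  expect_equal(rasterize_fires(fire_events("c", 1L, list(r50)), spec)$values[1, 1], 1L)
})

test_that("exact rasterization agrees with a supersampling oracle away from ties", {
  set.seed(11)
  spec <- grid_spec(0, 20 * 50, pixel_size = 50, n_rows = 20, n_cols = 20)
  # irregular star-shaped polygon around the grid centre
  n_v <- 12
  ang <- sort(runif(n_v, 0, 2 * pi))
  rad <- runif(n_v, 150, 450)
  ring <- cbind(500 + rad * cos(ang), 500 + rad * sin(ang))
  ev <- fire_events("star", 1L, list(ring))
  exact_frac <- cover_fraction(ev, spec)$values
  g <- rasterize_fires(ev, spec)
  oracle <- supersample_rasterize(ev, spec)
  away_from_tie <- abs(exact_frac - 0.5) > 0.05
  expect_true(sum(away_from_tie) > 300)  # the comparison is not vacuous
  expect_identical(g$values[away_from_tie], oracle$labels[away_from_tie])
  # the exact fractions themselves match the sampled ones closely
  expect_lt(max(abs(exact_frac - oracle$frac)), 0.06)
})

test_that("rasterization is monotone under polygon growth", {
  spec <- grid_spec(0, 500, pixel_size = 50, n_rows = 10, n_cols = 10)
  set.seed(12)
  for (i in 1:5) {
    cx <- runif(1, 100, 400); cy <- runif(1, 100, 400)
    r1 <- runif(1, 40, 120)
    ang <- seq(0, 2 * pi, length.out = 13)[-13]
    small <- cbind(cx + r1 * cos(ang), cy + r1 * sin(ang))
    big <- cbind(cx + (r1 + 80) * cos(ang), cy + (r1 + 80) * sin(ang))
    gs <- rasterize_fires(fire_events("s", 1L, list(small)), spec)$values
    gb <- rasterize_fires(fire_events("b", 1L, list(big)), spec)$values
    expect_true(all(gb[gs == 1L] == 1L))
  }
})

test_that("holes reduce cover and invalid or out-of-grid polygons are handled", {
  spec <- grid_spec(0, 100, pixel_size = 50, n_rows = 2, n_cols = 2)
  outer <- rbind(c(0, 100), c(50, 100), c(50, 50), c(0, 50))
  hole <- rbind(c(10, 90), c(40, 90), c(40, 60), c(10, 60))  # 36% hole
  g <- rasterize_fires(fire_events("h", 1L, list(list(outer, hole))), spec)
  expect_equal(g$values[1, 1], 1L)  # 64% cover still burned
  bighole <- rbind(c(2, 98), c(48, 98), c(48, 52), c(2, 52)) # 84.64% hole
  g2 <- rasterize_fires(fire_events("h2", 1L, list(list(outer, bighole))), spec)
  expect_equal(g2$values[1, 1], 0L)
  # entirely outside the grid: warning, empty grid
  far <- rbind(c(1e4, 1e4), c(1.1e4, 1e4), c(1.1e4, 1.1e4))
  expect_warning(g3 <- rasterize_fires(fire_events("far", 1L, list(far)), spec),
                 "outside")
  expect_equal(sum(g3$values), 0)
  # self-intersecting bow-tie is rejected
  bow <- rbind(c(0, 0), c(50, 50), c(50, 0), c(0, 50))
  expect_error(fire_events("bow", 1L, list(bow)), "Self-intersecting")
})

test_that("fire_events computes areas from geometry, holes subtracted", {
  sq <- rbind(c(0, 1000), c(1000, 1000), c(1000, 0), c(0, 0))  # 100 ha
  hole <- rbind(c(100, 900), c(900, 900), c(900, 100), c(100, 100))  # 64 ha
  ev <- fire_events(c("a", "b"), c(1L, 1L), list(sq, list(sq, hole)))
  expect_equal(ev$area_ha, c(100, 36))
  expect_equal(as.character(ev$category), c("small", "very_small"))
})
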