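test_that("generated stacks honour the target cross-correlation", {
  mk <- function(R, seed = 7) {
    sc <- synthetic_scenario(predictors = list(a = c(0, 1), b = c(5, 9)),
                             correlation = R, nrow = 100, ncol = 100,
                             seed = seed)
    st <- generate_env_stack(sc)
    cor(as.vector(st$a$values), as.vector(st$b$values))
  }
  expect_lt(abs(mk(diag(2))), 0.1)
  expect_lt(abs(mk(matrix(c(1, 0.9, 0.9, 1), 2)) - 0.9), 0.1)
})

test_that("generated fields hit their target ranges and are reproducible", {
  sc <- synthetic_scenario(predictors = list(Bio12 = c(100, 1200)),
                           nrow = 60, ncol = 50, seed = 3)
  st1 <- generate_env_stack(sc)
  st2 <- generate_env_stack(sc)
  expect_identical(st1$Bio12$values, st2$Bio12$values)
  expect_equal(range(st1$Bio12$values), c(100, 1200))
})

test_that("invalid correlation matrices are rejected with explanation", {
  bad <- matrix(c(1, 0.99, 0.2, 0.99, 1, 0.99, 0.2, 0.99, 1), 3)
  expect_error(
    synthetic_scenario(predictors = list(a = 0:1, b = 0:1, c = 0:1),
                       correlation = bad, nrow = 50, ncol = 50),
    "positive semi-definite")
  expect_error(
    synthetic_scenario(predictors = list(a = 0:1, b = 0:1),
                       correlation = matrix(c(1, .2, .4, 1), 2),
                       nrow = 50, ncol = 50),
    "symmetric")
})

test_that("suitability surfaces follow the closed-form response", {
  g1 <- raster_grid(matrix(c(600, 675, 525, 300), 2, 2))
  g2 <- raster_grid(matrix(30, 2, 2))
  st <- predictor_stack(list(Bio12 = g1, Bio5 = g2))
  sp <- virtual_species(list(
    Bio12 = list(kind = "gaussian", optimum = 600, width = 75),
    Bio5 = list(kind = "gaussian", optimum = 30, width = 8)))
  su <- suitability_surface(sp, st)
  # at the joint optimum the product of gaussians is exactly 1
  expect_equal(su$values[1, 1], 1)
  # one sigma away on a single predictor: exp(-1/2)
  expect_equal(su$values[2, 1], exp(-0.5), tolerance = 1e-12)
  # symmetric displacements give equal suitability
  expect_equal(su$values[2, 1], su$values[1, 2], tolerance = 1e-12)
  expect_true(all(su$values >= 0 & su$values <= 1))
})

test_that("suitability propagates nodata and rejects missing predictors", {
  g <- raster_grid(matrix(c(NA, 600, 700, 500), 2, 2))
  st <- predictor_stack(list(Bio12 = g))
  sp <- virtual_species(list(
    Bio12 = list(kind = "gaussian", optimum = 600, width = 75)))
  su <- suitability_surface(sp, st)
  expect_true(is.na(su$values[1, 1]))
  sp2 <- virtual_species(list(
    Bio5 = list(kind = "gaussian", optimum = 30, width = 8)))
  expect_error(suitability_surface(sp2, st), "missing")
})

test_that("presence sampling is proportional to suitability", {
  # uniform suitability: cell counts consistent with uniform occupancy
  su <- raster_grid(matrix(1, 10, 10))
  occ <- sample_presences(su, 5000, seed = 9)
  cc <- cell_from_xy(su, occ$x, occ$y)
  counts <- tabulate(cc$cell, nbins = 100)
  expect_gt(chisq.test(counts)$p.value, 0.01)

  # zero-suitability region receives no presences
  v <- matrix(1, 10, 10); v[, 1:5] <- 0
  occ2 <- sample_presences(raster_grid(v), 2000, seed = 10)
  expect_true(all(occ2$x >= 5))  # left half is x in [0, 5)

  # determinism and error on an all-zero surface
  occ3 <- sample_presences(su, 50, seed = 11)
  occ4 <- sample_presences(su, 50, seed = 11)
  expect_identical(occ3$x, occ4$x)
  expect_error(sample_presences(raster_grid(matrix(0, 5, 5)), 10, seed = 1),
               "no cell")
})

test_that("presence density increases with true suitability decile", {
  sc <- synthetic_scenario(predictors = list(a = c(0, 1)),
                           nrow = 100, ncol = 100, seed = 12)
  st <- generate_env_stack(sc)
  sp <- virtual_species(list(
    a = list(kind = "gaussian", optimum = 0.7, width = 0.15)))
  su <- suitability_surface(sp, st)
  occ <- sample_presences(su, 8000, seed = 13)
  cc <- cell_from_xy(su, occ$x, occ$y)
  suit_at <- su$values[cc$cell]
  dec <- cut(as.vector(su$values),
             quantile(su$values, 0:10 / 10), include.lowest = TRUE)
  land_per_dec <- table(dec)
  pres_per_dec <- table(cut(suit_at, quantile(su$values, 0:10 / 10),
                            include.lowest = TRUE))
  dens <- as.numeric(pres_per_dec / land_per_dec)
  # monotone non-decreasing in expectation; allow small sampling wiggles
  expect_true(all(diff(dens) > -0.02 * max(dens)))
  expect_gt(dens[10], dens[1])
})

test_that("background sampling is uniform, exclusive, and exhaustive", {
  st <- tiny_stack()
  n_valid <- length(st$a$values)
  bg_all <- sample_background(st, n_valid, seed = 2)
  cc <- cell_from_xy(st$a, bg_all$x, bg_all$y)
  expect_setequal(cc$cell, seq_len(n_valid))  # exhaustive draw, no repeats

  excl <- occurrence_set(500, 500, crs = "projected")  # cell (row 6, col 1)
  bg <- sample_background(st, n_valid - 1, seed = 3, exclude = excl)
  cc2 <- cell_from_xy(st$a, bg$x, bg$y)
  excl_cell <- cell_from_xy(st$a, 500, 500)$cell
  expect_false(excl_cell %in% cc2$cell)

  expect_error(sample_background(st, n_valid + 1, seed = 1), "valid cells")
  b1 <- sample_background(st, 10, seed = 4)
  b2 <- sample_background(st, 10, seed = 5)
  expect_false(identical(b1$x, b2$x))
})
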