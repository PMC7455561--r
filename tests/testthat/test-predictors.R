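test_that("Horn slope matches the analytic gradient of a plane", {
  nr <- 12; nc <- 15; cs <- 30
  xs <- (seq_len(nc) - 0.5) * cs
  # plane z = 0.1 * x: interior slope is atan(0.1) everywhere
  z <- matrix(rep(0.1 * xs, each = nr), nr, nc)
  sl <- compute_slope(raster_grid(z, cellsize = cs))
  interior <- sl$values[2:(nr - 1), 2:(nc - 1)]
  expect_equal(max(abs(interior - atan(0.1) * 180 / pi)), 0, tolerance = 1e-6)
  # border cells are masked
  expect_true(all(is.na(sl$values[1, ])))
  expect_true(all(is.na(sl$values[, nc])))

  # the same plane rotated 90 degrees has the same slope magnitude
  ys <- (seq_len(nr) - 0.5) * cs
  z2 <- matrix(rep(0.1 * ys, times = nc), nr, nc)
  sl2 <- compute_slope(raster_grid(z2, cellsize = cs))
  expect_equal(sl2$values[5, 5], sl$values[5, 5], tolerance = 1e-9)

  # flat terrain has zero slope; degenerate rasters are rejected
  flat <- compute_slope(raster_grid(matrix(7, 5, 5), cellsize = cs))
  expect_equal(flat$values[3, 3], 0)
  expect_error(compute_slope(raster_grid(matrix(1:5, 1, 5))), "2 x 2")
})

test_that("slope masks cells adjacent to nodata", {
  z <- matrix(100, 6, 6); z[3, 3] <- NA
  sl <- compute_slope(raster_grid(z, cellsize = 10))
  expect_true(all(is.na(sl$values[2:4, 2:4])))
  expect_equal(sl$values[5, 5], 0)
})

test_that("topographic heterogeneity is the blockwise sample SD", {
  # block of half 0 m and half 100 m: sd = 50 * sqrt(n/(n-1))
  z <- matrix(0, 10, 10); z[, 6:10] <- 100
  th <- compute_topographic_heterogeneity(raster_grid(z, cellsize = 90), 10)
  expect_equal(dim(th$values), c(1L, 1L))
  expect_equal(th$values[1, 1], 50 * sqrt(100 / 99), tolerance = 1e-12)
  expect_equal(th$values[1, 1], sd(z), tolerance = 1e-12)  # oracle

  # constant elevation: zero everywhere; SD is scale-equivariant and
  # shift-invariant
  zc <- matrix(250, 12, 12)
  thc <- compute_topographic_heterogeneity(raster_grid(zc), 4)
  expect_true(all(thc$values == 0))
  set.seed(5)
  zr <- matrix(rnorm(144, 500, 80), 12, 12)
  th1 <- compute_topographic_heterogeneity(raster_grid(zr), 4)
  th2 <- compute_topographic_heterogeneity(raster_grid(2 * zr), 4)
  th3 <- compute_topographic_heterogeneity(raster_grid(zr + 1000), 4)
  expect_equal(th2$values, 2 * th1$values, tolerance = 1e-12)
  expect_equal(th3$values, th1$values, tolerance = 1e-9)

  # partial edge blocks use the available cells; block validation
  th_part <- compute_topographic_heterogeneity(raster_grid(zr[1:10, ]), 4)
  expect_equal(th_part$values[3, 1], sd(zr[9:10, 1:4]), tolerance = 1e-12)
  expect_error(compute_topographic_heterogeneity(raster_grid(zr), 1), ">= 2")
  expect_error(compute_topographic_heterogeneity(raster_grid(zr), 20),
               "exceeds")
})

test_that("stepwise VIF matches the brute-force OLS oracle", {
  set.seed(11)
  n <- 300
  x1 <- rnorm(n); x2 <- rnorm(n); x4 <- rnorm(n); x5 <- rnorm(n)
  x3 <- x1 + x2 + rnorm(n, sd = 0.05)   # near-collinear triple
  df <- data.frame(x1 = x1, x2 = x2, x3 = x3, x4 = x4, x5 = x5)
  oracle <- brute_force_vif(df)
  rep <- vif_stepwise(df, threshold = 10)
  expect_equal(rep$steps[[1]], oracle, tolerance = 1e-8)
  # x3 carries the largest VIF and is removed first
  expect_identical(rep$removed[1], "x3")
  expect_true(all(rep$vif < 10))
  # after removing x3 nothing else is collinear
  expect_equal(length(rep$removed), 1)
})

test_that("VIF handles orthogonal, duplicated, and constant columns", {
  # exactly uncorrelated design (principal component scores): VIF is 1
  set.seed(1)
  X <- prcomp(matrix(rnorm(80), 20, 4))$x
  df <- as.data.frame(X)
  expect_equal(unname(vif_stepwise(df)$vif), rep(1, 4), tolerance = 1e-10)

  # duplicated column: infinite VIF, the later-listed copy dropped first
  set.seed(2)
  d2 <- data.frame(a = rnorm(30), b = rnorm(30))
  d2$a_copy <- d2$a
  rep2 <- vif_stepwise(d2)
  expect_identical(rep2$removed[1], "a_copy")
  expect_true(all(is.finite(rep2$vif)))

  expect_error(vif_stepwise(data.frame(a = rnorm(20), b = rep(1, 20))),
               "constant")
})

test_that("stepwise VIF terminates with a passing set", {
  set.seed(21)
  n <- 200
  base <- matrix(rnorm(3 * n), n, 3)
  # many mutually collinear combinations
  df <- as.data.frame(cbind(base,
                            base %*% c(1, 1, 0) + rnorm(n, sd = .1),
                            base %*% c(0, 1, 1) + rnorm(n, sd = .1),
                            base %*% c(1, 0, 1) + rnorm(n, sd = .1)))
  rep <- vif_stepwise(df, threshold = 5)
  expect_lte(length(rep$removed), ncol(df) - 1)
  expect_true(all(rep$vif < 5))
})

test_that("alignment resamples onto the reference grid with a union mask", {
  a <- raster_grid(matrix(1:24, 4, 6), xmin = 0, ymin = 0, cellsize = 10)
  b <- raster_grid(matrix(101:124, 4, 6), xmin = 0, ymin = 0, cellsize = 10)
  st <- align_stack(list(a = a, b = b))
  expect_equal(st$a$values, a$values)   # already aligned: unchanged

  # one-cell shift: values shift, overlap crops to 5 columns
  b2 <- raster_grid(matrix(101:124, 4, 6), xmin = 10, ymin = 0,
                    cellsize = 10)
  st2 <- align_stack(list(a = a, b = b2))
  expect_equal(dim(st2$a$values), c(4L, 5L))
  expect_equal(st2$a$values, a$values[, 2:6])
  expect_equal(st2$b$values, matrix(101:124, 4, 6)[, 1:5])

  # nodata in one layer masks all layers at that cell
  a3 <- a; a3$values[2, 2] <- NA
  st3 <- align_stack(list(a = a3, b = b))
  expect_true(is.na(st3$b$values[2, 2]))

  # disjoint extents are rejected
  far <- raster_grid(matrix(1:24, 4, 6), xmin = 1000, ymin = 1000,
                     cellsize = 10)
  expect_error(align_stack(list(a = a, far = far)), "disjoint")
})
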