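test_that("train/test splitting partitions with rounded sizes", {
  occ <- occurrence_set(runif(45, 0, 1000), runif(45, 0, 1000),
                        crs = "projected")
  parts <- split_train_test(occ, 0.8, seed = 4)
  expect_equal(nrow(parts$train), 36)
  expect_equal(nrow(parts$test), 9)
  # disjoint exhaustive partition
  joined <- rbind(as.data.frame(parts$train), as.data.frame(parts$test))
  expect_setequal(paste(joined$x, joined$y), paste(occ$x, occ$y))
  expect_equal(nrow(merge(as.data.frame(parts$train),
                          as.data.frame(parts$test))), 0)
  # seeded determinism
  parts2 <- split_train_test(occ, 0.8, seed = 4)
  expect_identical(parts$train$x, parts2$train$x)
  expect_error(split_train_test(occ[1:5, ], train_fraction = 0.05),
               "empty partition")
})

test_that("AUC matches pair enumeration and is rank-invariant", {
  expect_equal(auc_mw(c(0.9, 0.8), c(0.7, 0.4)), 1)
  expect_equal(auc_mw(c(0.5, 0.5), c(0.5, 0.5)), 0.5)
  # 4 pairs: (.9>.5),(.9>.1),(.3<.5),(.3>.1) -> 3/4
  expect_equal(auc_mw(c(0.9, 0.3), c(0.5, 0.1)), 0.75)
  # invariance under a strictly monotone transform
  set.seed(8)
  p <- runif(50); b <- runif(80)
  expect_equal(auc_mw(p, b), auc_mw(exp(3 * p), exp(3 * b)))
  expect_equal(auc_mw(p, b), auc_mw(rank(c(p, b))[1:50],
                                    rank(c(p, b))[51:130]))
  expect_error(auc_mw(numeric(0), b), "non-empty")
})

test_that("threshold metrics maximize TSS over the exhaustive scan", {
  tm <- threshold_metrics(c(0.9, 0.6, 0.3), c(0.5, 0.2))
  expect_equal(tm$threshold, 0.6)
  expect_equal(tm$sensitivity, 2 / 3)
  expect_equal(tm$specificity, 1)
  expect_equal(tm$tss, 2 / 3)

  # perfect separation and exchangeable scores
  perf <- threshold_metrics(c(0.8, 0.9), c(0.1, 0.2))
  expect_equal(c(perf$sensitivity, perf$specificity, perf$tss), c(1, 1, 1))
  same <- threshold_metrics(rep(0.4, 5), rep(0.4, 5))
  expect_equal(same$tss, 0)

  # brute-force oracle on random small fixtures; TSS identity holds
  set.seed(13)
  for (i in 1:20) {
    p <- round(runif(sample(3:10, 1)), 2)
    b <- round(runif(sample(3:10, 1)), 2)
    tm <- threshold_metrics(p, b)
    expect_equal(tm$tss, brute_force_max_tss(p, b), tolerance = 1e-12)
    expect_equal(tm$tss, tm$sensitivity + tm$specificity - 1)
  }
})

test_that("Boyce index recovers monotone, reversed, and null profiles", {
  set.seed(1)
  land <- runif(20000)
  pres_mono <- sample(land, 1000, prob = land^3)
  expect_gt(boyce_index(pres_mono, land), 0.9)
  # reversed concentration
  pres_rev <- sample(land, 1000, prob = (1 - land)^3)
  expect_lt(boyce_index(pres_rev, land), -0.9)
  # presences in the top / bottom decile: strong positive / negative
  pres_top <- land[land >= 0.9][1:1000]
  expect_gt(boyce_index(pres_top, land), 0.4)
  expect_lt(boyce_index(1 - pres_top, 1 - land), -0.4)
  # affine rescaling of all scores leaves the index unchanged
  expect_equal(boyce_index(pres_mono, land),
               boyce_index(7 * pres_mono + 3, 7 * land + 3))
  # null case: unbiased around 0 (individual draws are noisy by design)
  nulls <- vapply(1:10, function(s) {
    set.seed(s)
    l <- runif(20000)
    boyce_index(sample(l, 5000), l)
  }, numeric(1))
  expect_lt(abs(mean(nulls)), 0.25)
  # degenerate inputs
  expect_warning(b0 <- boyce_index(rep(0.5, 10), rep(0.5, 100)),
                 "degenerate")
  expect_equal(b0, 0)
})

test_that("ensemble combination is a convex cellwise mean", {
  m1 <- raster_grid(matrix(0.2, 4, 4))
  m2 <- raster_grid(matrix(0.6, 4, 4))
  em <- ensemble_combine(list(m1, m2))
  expect_equal(em$values[1, 1], 0.4)
  # identical members are a fixed point; degenerate weights select members
  expect_equal(ensemble_combine(list(m1, m1, m1))$values, m1$values)
  expect_equal(ensemble_combine(list(m1, m2), weights = c(1, 0))$values,
               m1$values)
  # bounded by the pointwise member envelope
  set.seed(3)
  maps <- lapply(1:5, function(i) raster_grid(matrix(runif(16), 4, 4)))
  em2 <- ensemble_combine(maps, tss = c(0.5, 0.1, 0, 0.9, 0.3))
  lo <- Reduce(pmin, lapply(maps, `[[`, "values"))
  hi <- Reduce(pmax, lapply(maps, `[[`, "values"))
  expect_true(all(em2$values >= lo - 1e-12 & em2$values <= hi + 1e-12))
  # negative TSS members are clipped out of the weighting
  em3 <- ensemble_combine(list(m1, m2), tss = c(-0.2, 0.5))
  expect_equal(em3$values[1, 1], 0.6)
  expect_error(ensemble_combine(list(m1, m2), tss = c(-1, -2)), "zero")
  bad <- raster_grid(matrix(0.5, 3, 3))
  expect_error(ensemble_combine(list(m1, bad)), "aligned")
})

test_that("permutation importance separates signal from noise", {
  tr <- toy_training(n_pres = 150, n_bg = 400, seed = 77)
  m <- fit_sdm("glm", tr$pres, tr$bg, seed = 1)
  dat <- rbind(tr$pres, tr$bg)
  imp <- variable_importance(m, dat, n_repeats = 10, seed = 5)
  expect_gt(imp[["x1"]], imp[["x2"]])
  expect_lt(imp[["x2"]], 0.2)
  expect_true(all(imp >= 0 & imp <= 1))
  # in every repeat the informative predictor dominates
  reps <- vapply(1:10, function(s)
    variable_importance(m, dat, n_repeats = 1, seed = s)[["x1"]] >
      variable_importance(m, dat, n_repeats = 1, seed = s)[["x2"]],
    logical(1))
  expect_true(all(reps))
})

test_that("binarization counts per-cell areas correctly", {
  v <- matrix(c(0.9, 0.8, 0.7, 0.6, 0.2, 0.1, NA, 0.05, 0.3, 0.95), 2, 5)
  m <- raster_grid(v, cellsize = 1000, crs = "projected")
  ba <- binarize_and_area(m, 0.6)
  expect_equal(ba$area_km2, 5)           # 5 of the 9 valid 1-km2 cells
  expect_equal(ba$binary$values[1, 1], 1)
  expect_true(is.na(ba$binary$values[1, 4]))
  # threshold 0 marks every valid cell
  expect_equal(binarize_and_area(m, 0)$area_km2, 9)

  # geographic cells shrink with cos(latitude): equator vs 60N
  g_eq <- raster_grid(matrix(1, 1, 1), xmin = 0, ymin = -0.05,
                      cellsize = 0.1, crs = "geographic")
  g_60 <- raster_grid(matrix(1, 1, 1), xmin = 0, ymin = 59.95,
                      cellsize = 0.1, crs = "geographic")
  a_eq <- binarize_and_area(g_eq, 0.5)$area_km2
  a_60 <- binarize_and_area(g_60, 0.5)$area_km2
  expect_equal(a_60 / a_eq, cos(60 * pi / 180), tolerance = 0.01)
})
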