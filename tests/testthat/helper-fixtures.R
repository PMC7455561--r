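# shared fixtures and independent oracles, built in code at test time

# small flat stack with a known constant layer pattern
tiny_stack <- function(nr = 6, nc = 8, cellsize = 1000) {
  a <- raster_grid(matrix(seq_len(nr * nc), nr, nc), cellsize = cellsize)
  b <- raster_grid(matrix(rev(seq_len(nr * nc)), nr, nc),
                   cellsize = cellsize)
  predictor_stack(list(a = a, b = b))
}

# exhaustive maximum-independent-set oracle for thinning fixtures (<= 15 pts)
brute_force_thin_optimum <- function(occ, min_dist) {
  d <- occurrence_distances(occ)
  n <- nrow(occ)
  best <- 0
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) <= best) next
    if (length(idx) < 2 ||
        all(d[idx, idx][upper.tri(diag(length(idx)))] >= min_dist))
      best <- length(idx)
  }
  best
}

# brute-force VIF oracle: explicit OLS of each column on the others
brute_force_vif <- function(df) {
  vapply(names(df), function(nm) {
    others <- as.matrix(df[setdiff(names(df), nm)])
    X <- cbind(1, others)
    y <- df[[nm]]
    beta <- solve(crossprod(X), crossprod(X, y))
    res <- y - X %*% beta
    r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
    1 / (1 - r2)
  }, numeric(1))
}

# exhaustive threshold scan oracle for TSS
brute_force_max_tss <- function(pres, bg) {
  cand <- sort(unique(c(pres, bg)))
  max(vapply(cand, function(t)
    mean(pres >= t) + mean(bg < t) - 1, numeric(1)))
}

# small seeded presence/background training tables with one informative
# predictor (x1) and one pure-noise predictor (x2)
toy_training <- function(n_pres = 100, n_bg = 400, seed = 42,
                         optimum = 0.5, width = 0.12) {
  set.seed(seed)
  bg <- data.frame(x1 = runif(n_bg), x2 = runif(n_bg))
  cand <- data.frame(x1 = runif(n_pres * 50), x2 = runif(n_pres * 50))
  suit <- exp(-0.5 * ((cand$x1 - optimum) / width)^2)
  keep <- sample(nrow(cand), n_pres, prob = suit)
  list(pres = cand[keep, ], bg = bg)
}

# fit the five-algorithm ensemble for one virtual species on a stack,
# following the packaged study conditions (200 presences, 10k background,
# 80/20 split)
fit_species_ensemble <- function(st, species, seed, n_pres = 200,
                                 n_bg = 10000) {
  suit <- suitability_surface(species, st)
  occ <- sample_presences(suit, n_pres, seed = derive_seed(seed, "pres"))
  bg <- sample_background(st, n_bg, seed = derive_seed(seed, "bg"),
                          exclude = occ)
  sp <- split_train_test(occ, 0.8, seed = derive_seed(seed, "split"))
  sb <- split_train_test(bg, 0.8, seed = derive_seed(seed, "splitbg"))
  tab <- list(ptr = extract_env_values(sp$train, st),
              pte = extract_env_values(sp$test, st),
              btr = extract_env_values(sb$train, st),
              bte = extract_env_values(sb$test, st),
              pall = extract_env_values(occ, st))
  algos <- c("glm", "gam", "gbm", "maxent", "rf")
  models <- lapply(algos, function(a)
    fit_sdm(a, tab$ptr, tab$btr, seed = derive_seed(seed, a)))
  names(models) <- algos
  ens <- sdm_ensemble(models)
  map <- predict_suitability(ens, st)
  list(models = models, ensemble = ens, map = map, tables = tab)
}
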