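#' Random train/test split of occurrence records
#'
#' Single random partition: `round(n * train_fraction)` records go to the
#' training set, the rest to the test set; disjoint and exhaustive, seeded.
#'
#' @param occ An `occurrence_set` (or any data.frame of records).
#' @param train_fraction Fraction in (0, 1), default 0.8.
#' @param seed Integer RNG seed.
#' @return List with elements `train` and `test`.
#' @export
split_train_test <- function(occ, train_fraction = 0.8, seed = 1L) {
  n <- nrow(occ)
  if (n < 5) stop("need at least 5 records to split")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must lie in (0, 1)")
  n_train <- round(n * train_fraction)
  if (n_train == 0 || n_train == n)
    stop("`train_fraction` leaves an empty partition at n = ", n)
  local_rng(seed)
  idx <- sample.int(n, n_train)
  keep <- rep(FALSE, n); keep[idx] <- TRUE
  if (inherits(occ, "occurrence_set")) {
    list(train = rebuild_occ(occ, keep, attr(occ, "stage")),
         test = rebuild_occ(occ, !keep, attr(occ, "stage")))
  } else {
    list(train = occ[keep, , drop = FALSE],
         test = occ[!keep, , drop = FALSE])
  }
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Fraction of (presence, background) score pairs in which the presence
#' scores higher, ties counted one half — computed via average ranks, so it
#' is exact and invariant under strictly monotone transforms of the scores.
#'
#' @param presence_scores,background_scores Non-empty numeric vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc_mw <- function(presence_scores, background_scores) {
  np <- length(presence_scores); nb <- length(background_scores)
  if (np == 0 || nb == 0) stop("score vectors must be non-empty")
  r <- rank(c(presence_scores, background_scores), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Threshold, sensitivity, specificity and TSS at max sensitivity+specificity
#'
#' Scans every observed score as a candidate threshold and picks the one
#' maximizing sensitivity + specificity (the max-TSS threshold; ties go to
#' the lowest threshold). Sensitivity is the fraction of presence scores
#' `>=` the threshold; specificity the fraction of background scores below
#' it; TSS = sensitivity + specificity - 1.
#'
#' @param presence_scores,background_scores Non-empty numeric vectors.
#' @return List with `threshold`, `sensitivity`, `specificity`, `tss`.
#' @export
threshold_metrics <- function(presence_scores, background_scores) {
  if (!length(presence_scores) || !length(background_scores))
    stop("score vectors must be non-empty")
  cand <- sort(unique(c(presence_scores, background_scores)))
  best <- NULL
  for (t in cand) {
    sens <- mean(presence_scores >= t)
    spec <- mean(background_scores < t)
    if (is.null(best) || sens + spec > best$sensitivity + best$specificity +
          1e-12)
      best <- list(threshold = t, sensitivity = sens, specificity = spec)
  }
  best$tss <- best$sensitivity + best$specificity - 1
  best
}

#' Continuous Boyce index
#'
#' Slides `n_windows` overlapping windows of width
#' `window_width_fraction * (score range)` across the score range; in each,
#' P is the fraction of presence scores and E the fraction of landscape
#' scores inside. The index is the Spearman rank correlation between the
#' predicted-to-expected ratio F = P/E and the window midpoint, over
#' windows with E > 0. A good presence-only model concentrates presences
#' in high-suitability windows, giving a monotone F profile and an index
#' near +1; random placement gives ~0.
#'
#' @param presence_scores Numeric vector (>= 10 values).
#' @param landscape_scores Numeric vector of scores over the whole
#'   landscape (>= 100 values).
#' @param n_windows Number of window positions (default 101).
#' @param window_width_fraction Window width as a fraction of the score
#'   range (default 0.1).
#' @return Boyce index in `[-1, 1]`; 0 (with a warning) when the score
#'   range is degenerate, fewer than 3 windows are usable, or F is
#'   constant.
#' @export
boyce_index <- function(presence_scores, landscape_scores,
                        n_windows = 101, window_width_fraction = 0.1) {
  if (length(presence_scores) < 10)
    stop("need at least 10 presence scores")
  if (length(landscape_scores) < 100)
    stop("need at least 100 landscape scores")
  lo <- min(landscape_scores, presence_scores)
  hi <- max(landscape_scores, presence_scores)
  if (hi - lo <= 0) {
    warning("degenerate score range; Boyce index undefined, returning 0")
    return(0)
  }
  w <- window_width_fraction * (hi - lo)
  mids <- seq(lo + w / 2, hi - w / 2, length.out = n_windows)
  P <- E <- numeric(n_windows)
  for (k in seq_len(n_windows)) {
    a <- mids[k] - w / 2; b <- mids[k] + w / 2
    P[k] <- mean(presence_scores >= a & presence_scores <= b)
    E[k] <- mean(landscape_scores >= a & landscape_scores <= b)
  }
  use <- E > 0
  if (sum(use) < 3) {
    warning("fewer than 3 usable windows; returning 0")
    return(0)
  }
  F_ <- P[use] / E[use]
  if (stats::sd(F_) == 0) {
    warning("constant P/E profile; returning 0")
    return(0)
  }
  stats::cor(F_, mids[use], method = "spearman")
}

#' Evaluate suitability scores against presence/background data
#'
#' Bundles the five presence-only evaluation metrics: AUC, sensitivity,
#' specificity and TSS at the max-TSS threshold, and the continuous Boyce
#' index (computed against landscape scores when supplied, else against
#' the background scores). Background points stand in for absences in the
#' binary metrics, as is standard in presence/background designs.
#'
#' @param presence_scores,background_scores Numeric score vectors.
#' @param landscape_scores Optional scores over the full landscape for the
#'   Boyce index.
#' @return An `evaluation_result`: list with `auc`, `sensitivity`,
#'   `specificity`, `tss`, `boyce`, `threshold`.
#' @export
evaluate_scores <- function(presence_scores, background_scores,
                            landscape_scores = NULL) {
  tm <- threshold_metrics(presence_scores, background_scores)
  land <- if (is.null(landscape_scores)) background_scores
          else landscape_scores
  boyce <- if (length(presence_scores) >= 10 && length(land) >= 100)
    boyce_index(presence_scores, land) else NA_real_
  structure(list(auc = auc_mw(presence_scores, background_scores),
                 sensitivity = tm$sensitivity,
                 specificity = tm$specificity,
                 tss = tm$tss, boyce = boyce,
                 threshold = tm$threshold),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf(paste0("AUC %.3f | sens %.3f | spec %.3f | TSS %.3f | ",
                     "Boyce %s (threshold %.3f)\n"),
              x$auc, x$sensitivity, x$specificity, x$tss,
              ifelse(is.na(x$boyce), "NA", sprintf("%.3f", x$boyce)),
              x$threshold))
  invisible(x)
}

#' Combine member suitability maps into an ensemble map
#'
#' Cellwise weighted mean of aligned suitability rasters. Weights may be
#' `"uniform"` (default), an explicit non-negative numeric vector, or TSS
#' weighting via `tss =` (member TSS values clipped at 0 and renormalized).
#'
#' @param maps List of aligned suitability `raster_grid`s.
#' @param weights `"uniform"`, or a numeric vector, one weight per map.
#' @param tss Optional numeric vector of member TSS values; overrides
#'   `weights` with max(tss, 0) renormalized.
#' @return A `raster_grid`, bounded by the pointwise min and max of the
#'   members.
#' @export
ensemble_combine <- function(maps, weights = "uniform", tss = NULL) {
  if (!length(maps)) stop("need at least one member map")
  ref <- maps[[1]]
  for (m in maps) if (!same_geometry(m, ref))
    stop("member maps are not aligned")
  k <- length(maps)
  w <- if (!is.null(tss)) {
    pmax(as.numeric(tss), 0)
  } else if (identical(weights, "uniform")) {
    rep(1, k)
  } else {
    as.numeric(weights)
  }
  if (length(w) != k) stop("need one weight per map")
  if (any(w < 0)) stop("weights must be non-negative")
  if (sum(w) == 0) stop("all weights are zero")
  w <- w / sum(w)
  acc <- ref$values * w[1]
  if (k > 1) for (j in 2:k) acc <- acc + maps[[j]]$values * w[j]
  ref$values <- acc
  attr(ref, "weights") <- w
  ref
}

#' Ensemble of fitted models
#'
#' Wraps fitted member models with combination weights so the ensemble can
#' be used anywhere a single model can (prediction on tables, rasters,
#' response curves, importance).
#'
#' @param members List of `sdm_model`s.
#' @param weights `"uniform"` or a numeric vector; or supply `tss`.
#' @param tss Optional member TSS values for TSS weighting.
#' @return An object of class `sdm_ensemble`.
#' @export
sdm_ensemble <- function(members, weights = "uniform", tss = NULL) {
  if (!length(members)) stop("need at least one member model")
  k <- length(members)
  w <- if (!is.null(tss)) pmax(as.numeric(tss), 0)
       else if (identical(weights, "uniform")) rep(1, k)
       else as.numeric(weights)
  if (length(w) != k) stop("need one weight per member")
  if (sum(w) == 0) stop("all weights are zero")
  w <- w / sum(w)
  structure(list(members = members, weights = w), class = "sdm_ensemble")
}

#' @export
predict_sdm.sdm_ensemble <- function(model, newdata) {
  preds <- lapply(model$members, predict_sdm, newdata = newdata)
  Reduce(`+`, Map(`*`, preds, model$weights))
}

#' Permutation variable importance
#'
#' For each predictor, the column is permuted and importance is
#' `1 - cor(predictions on the original table, predictions on the permuted
#' table)`, averaged over repeats and clipped to `[0, 1]`. A predictor the
#' model ignores scores 0 up to Monte-Carlo noise.
#'
#' @param model An `sdm_model` or `sdm_ensemble`.
#' @param data Data.frame covering the model predictors (>= 30 rows).
#' @param n_repeats Number of permutations per predictor (default 10).
#' @param seed Integer RNG seed.
#' @return An `importance_result`: named numeric vector of importances
#'   with attributes `n_repeats` and `seed`.
#' @export
variable_importance <- function(model, data, n_repeats = 10, seed = 1L) {
  data <- as.data.frame(data)
  preds <- if (inherits(model, "sdm_ensemble"))
    unique(unlist(lapply(model$members, `[[`, "predictors")))
  else model$predictors
  if (!all(preds %in% names(data)))
    stop("`data` must cover all model predictors")
  if (nrow(data) < 30) stop("need at least 30 rows")
  base <- predict_sdm(model, data)
  local_rng(seed)
  imp <- stats::setNames(numeric(length(preds)), preds)
  if (stats::sd(base) == 0) {
    warning("constant predictions; importance undefined, reporting 0")
    return(structure(imp, n_repeats = n_repeats, seed = seed,
                     class = "importance_result"))
  }
  for (nm in preds) {
    vals <- numeric(n_repeats)
    for (r in seq_len(n_repeats)) {
      d2 <- data
      d2[[nm]] <- d2[[nm]][sample.int(nrow(d2))]
      p2 <- predict_sdm(model, d2)
      vals[r] <- if (stats::sd(p2) == 0) 1 else
        1 - stats::cor(base, p2)
    }
    imp[nm] <- min(max(mean(vals), 0), 1)
  }
  structure(imp, n_repeats = n_repeats, seed = seed,
            class = "importance_result")
}

#' Binary suitability map and suitable area
#'
#' Cells with suitability `>=` threshold are marked suitable (1), the rest
#' 0; nodata propagates. The suitable area sums per-cell areas: projected
#' grids use cellsize squared, geographic grids the per-row
#' cosine-corrected cell area on a sphere of radius 6,371.0088 km.
#'
#' @param map A suitability `raster_grid`.
#' @param threshold Threshold in `[0, 1]`.
#' @return List with `binary` (a `raster_grid` of 0/1), `area_km2`, and
#'   `threshold`.
#' @export
binarize_and_area <- function(map, threshold) {
  stopifnot(inherits(map, "raster_grid"))
  if (threshold < 0 || threshold > 1)
    stop("`threshold` must lie in [0, 1]")
  bin <- map
  bin$values <- (map$values >= threshold) * 1
  suit <- bin$values == 1
  suit[is.na(suit)] <- FALSE
  if (map$crs == "projected") {
    cell_km2 <- (map$cellsize / 1000)^2
    area <- sum(suit) * cell_km2
  } else {
    km_per_deg <- pi / 180 * 6371.0088
    lat <- row_latitudes(map)
    row_area <- (map$cellsize * km_per_deg)^2 * cos(lat * pi / 180)
    area <- sum(rowSums(suit) * row_area)
  }
  list(binary = bin, area_km2 = area, threshold = threshold)
}
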