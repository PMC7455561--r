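#' Fit a presence/background suitability model
#'
#' Fits one of five algorithms to presence (1) versus background (0)
#' predictor tables behind a single contract: every fitted model predicts
#' suitability in `[0, 1]`, deterministically, from a table of predictor
#' values or a raster stack.
#'
#' Algorithms:
#' \describe{
#'   \item{glm}{Logistic regression with linear + quadratic terms per
#'     predictor (quadratic terms allow unimodal niche responses);
#'     predictors are standardized internally. Non-convergence falls back
#'     to a small-ridge fit via `glmnet`, logged on the model.}
#'   \item{gam}{Logistic additive model on penalized spline bases
#'     (`mgcv`, ~4 effective df per predictor).}
#'   \item{gbm}{Stochastic gradient-boosted trees on the Bernoulli
#'     objective (defaults: 2000 trees, learning rate 0.01, interaction
#'     depth 3, bag fraction 0.5).}
#'   \item{maxent}{Presence/background maximum entropy: an L1-regularized
#'     exponential model over linear, quadratic and (with >= 80 presences)
#'     product and hinge features, fitted by infinitely-weighted logistic
#'     regression and normalized over the background sample; output is the
#'     complementary log-log transform with the standard entropy-based
#'     intercept.}
#'   \item{rf}{Random-forest class probability on a class-balanced
#'     bootstrap (500 trees).}
#' }
#'
#' @param algorithm One of `"glm"`, `"gam"`, `"gbm"`, `"maxent"`, `"rf"`.
#' @param presences Data.frame of predictor values at presence points.
#' @param background Data.frame of predictor values at background points;
#'   same columns as `presences`.
#' @param params Named list of per-algorithm hyperparameter overrides
#'   (see Details defaults).
#' @param seed Integer seed for the stochastic algorithms.
#' @return An object of class `sdm_model`.
#' @export
fit_sdm <- function(algorithm = c("glm", "gam", "gbm", "maxent", "rf"),
                    presences, background, params = list(), seed = 1L) {
  algorithm <- match.arg(algorithm)
  presences <- as.data.frame(presences)
  background <- as.data.frame(background)
  if (nrow(presences) < 10 || nrow(background) < 10)
    stop("need at least 10 presence and 10 background rows")
  if (!identical(sort(names(presences)), sort(names(background))))
    stop("presence and background tables must share predictor columns")
  background <- background[names(presences)]
  X <- rbind(presences, background)
  if (anyNA(X)) stop("NA predictor values in training data")
  y <- c(rep(1L, nrow(presences)), rep(0L, nrow(background)))

  const <- vapply(X, function(x) stats::sd(x) == 0, logical(1))
  if (any(const)) {
    warning("dropping constant predictor(s): ",
            paste(names(X)[const], collapse = ", "))
    X <- X[!const]
  }
  if (ncol(X) == 0) stop("no non-constant predictors left")
  preds <- names(X)

  centre <- vapply(X, mean, numeric(1))
  scale_ <- vapply(X, stats::sd, numeric(1))
  ranges <- vapply(X, range, numeric(2))
  means <- centre

  model <- structure(
    list(algorithm = algorithm, params = params, seed = as.integer(seed),
         predictors = preds, centre = centre, scale = scale_,
         ranges = ranges, train_means = means,
         n_presence = nrow(presences), n_background = nrow(background),
         usable = TRUE, notes = character(0)),
    class = "sdm_model")

  Z <- as.data.frame(scale(X, center = centre, scale = scale_))
  fitter <- switch(algorithm,
                   glm = fit_glm_sdm, gam = fit_gam_sdm,
                   gbm = fit_gbm_sdm, maxent = fit_maxent_sdm,
                   rf = fit_rf_sdm)
  fitter(model, X, Z, y)
}

quad_formula <- function(preds) {
  stats::as.formula(paste("y ~",
    paste(sprintf("%s + I(%s^2)", preds, preds), collapse = " + ")))
}

fit_glm_sdm <- function(model, X, Z, y) {
  d <- cbind(y = y, Z)
  fit <- suppressWarnings(
    stats::glm(quad_formula(model$predictors), family = stats::binomial(),
               data = d))
  if (!fit$converged || any(is.na(stats::coef(fit)))) {
    # small-ridge fallback keeps the same feature set
    model$notes <- c(model$notes, "glm did not converge; ridge fallback")
    mm <- as.matrix(cbind(Z, Z^2))
    colnames(mm) <- c(model$predictors, paste0(model$predictors, "^2"))
    fit <- glmnet::glmnet(mm, y, family = "binomial", alpha = 0,
                          lambda = 1e-3)
    model$fit_kind <- "glm_ridge"
  } else {
    model$fit_kind <- "glm"
  }
  model$fit <- fit
  model
}

fit_gam_sdm <- function(model, X, Z, y) {
  d <- cbind(y = y, Z)
  k <- if (!is.null(model$params$k)) model$params$k else 5
  terms <- vapply(model$predictors, function(p) {
    if (length(unique(Z[[p]])) > k) sprintf("s(%s, k = %d)", p, k) else p
  }, character(1))
  f <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
  fit <- try(mgcv::gam(f, family = stats::binomial(), data = d,
                       method = "REML"), silent = TRUE)
  if (inherits(fit, "try-error")) {
    model$usable <- FALSE
    model$notes <- c(model$notes, "gam fit failed")
    return(model)
  }
  model$fit_kind <- "gam"
  model$fit <- fit
  model
}

fit_gbm_sdm <- function(model, X, Z, y) {
  p <- model$params
  nrounds <- if (!is.null(p$n_trees)) p$n_trees else 2000
  pars <- list(objective = "binary:logistic",
               eta = if (!is.null(p$learning_rate)) p$learning_rate else 0.01,
               max_depth = if (!is.null(p$depth)) p$depth else 3,
               subsample = if (!is.null(p$bag_fraction)) p$bag_fraction else 0.5,
               nthread = 1, seed = model$seed)
  d <- xgboost::xgb.DMatrix(as.matrix(X), label = y)
  model$fit <- xgboost::xgb.train(params = pars, data = d,
                                  nrounds = nrounds, verbose = 0)
  model$fit_kind <- "gbm"
  model
}

fit_rf_sdm <- function(model, X, Z, y) {
  ntree <- if (!is.null(model$params$n_trees)) model$params$n_trees else 500
  yf <- factor(y, levels = c(0, 1))
  m <- min(table(yf))
  set.seed(model$seed)
  model$fit <- randomForest::randomForest(
    x = X, y = yf, ntree = ntree, strata = yf,
    sampsize = c(`0` = m, `1` = m))
  model$fit_kind <- "rf"
  model
}

# ---- maximum entropy ------------------------------------------------------

# hinge knots spread over the (standardized) training range
maxent_feature_spec <- function(Z, n_pres, params) {
  use_hp <- if (!is.null(params$hinge)) params$hinge else n_pres >= 80
  n_knots <- if (!is.null(params$n_knots)) params$n_knots else 15
  knots <- lapply(Z, function(x)
    seq(min(x), max(x), length.out = n_knots + 2)[2:(n_knots + 1)])
  zrange <- lapply(Z, range)
  list(use_hinge_product = use_hp, knots = knots, zrange = zrange,
       names = names(Z))
}

maxent_features <- function(Z, fs) {
  Z <- Z[fs$names]
  cols <- list()
  reg <- numeric(0)
  for (nm in fs$names) {
    cols[[paste0("lin_", nm)]] <- Z[[nm]];      reg <- c(reg, 1)
    cols[[paste0("quad_", nm)]] <- Z[[nm]]^2;   reg <- c(reg, 1)
  }
  if (fs$use_hinge_product) {
    nms <- fs$names
    if (length(nms) > 1) {
      for (i in seq_len(length(nms) - 1)) for (j in (i + 1):length(nms)) {
        cols[[paste0("prod_", nms[i], "_", nms[j])]] <-
          Z[[nms[i]]] * Z[[nms[j]]]
        reg <- c(reg, 1)
      }
    }
    for (nm in nms) {
      rng <- fs$zrange[[nm]]
      for (t in fs$knots[[nm]]) {
        cols[[sprintf("hingef_%s_%.4g", nm, t)]] <-
          pmax(0, (Z[[nm]] - t)) / (rng[2] - t)
        cols[[sprintf("hinger_%s_%.4g", nm, t)]] <-
          pmax(0, (t - Z[[nm]])) / (t - rng[1])
        reg <- c(reg, 0.5, 0.5)
      }
    }
  }
  mm <- do.call(cbind, cols)
  list(mm = mm, reg = reg)
}

fit_maxent_sdm <- function(model, X, Z, y) {
  fs <- maxent_feature_spec(Z, sum(y), model$params)
  ft <- maxent_features(Z, fs)
  w <- ifelse(y == 1, 1, 100)
  rm_mult <- if (!is.null(model$params$reg_multiplier))
    model$params$reg_multiplier else 1
  lambdas <- 10^seq(4, 0, length.out = 200) *
    mean(ft$reg) * rm_mult * sum(y) / sum(w)
  fit <- glmnet::glmnet(ft$mm, y, family = "binomial", weights = w,
                        alpha = 1, standardize = TRUE,
                        penalty.factor = ft$reg, lambda = lambdas)
  beta <- as.numeric(fit$beta[, ncol(fit$beta)])
  eta_bg <- as.numeric(ft$mm[y == 0, , drop = FALSE] %*% beta)
  # normalize the exponential model over the background sample
  log_norm <- log_sum_exp(eta_bg)
  q_bg <- exp(eta_bg - log_norm)
  entropy <- -sum(q_bg * log(pmax(q_bg, 1e-300)))
  model$fit <- list(beta = beta, feature_spec = fs, log_norm = log_norm,
                    entropy = entropy)
  model$fit_kind <- "maxent"
  model
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# raw maxent density over a (standardized) table; sums to 1 on the training
# background by construction
maxent_raw <- function(model, Z) {
  ft <- maxent_features(Z, model$fit$feature_spec)
  eta <- as.numeric(ft$mm %*% model$fit$beta)
  exp(eta - model$fit$log_norm)
}

# ---- prediction -----------------------------------------------------------

#' Predict suitability from a fitted model
#'
#' @param model An `sdm_model` or `sdm_ensemble`.
#' @param newdata Data.frame containing the model's predictor columns.
#' @return Numeric vector of suitabilities in `[0, 1]` (NA rows propagate).
#' @export
predict_sdm <- function(model, newdata) UseMethod("predict_sdm")

#' @export
predict_sdm.sdm_model <- function(model, newdata) {
  if (!model$usable) stop("model was flagged unusable at fit time")
  newdata <- as.data.frame(newdata)
  missing <- setdiff(model$predictors, names(newdata))
  if (length(missing))
    stop("missing predictor(s): ", paste(missing, collapse = ", "))
  X <- newdata[model$predictors]
  ok <- stats::complete.cases(X)
  out <- rep(NA_real_, nrow(X))
  if (!any(ok)) return(out)
  Xo <- X[ok, , drop = FALSE]
  Z <- as.data.frame(scale(Xo, center = model$centre, scale = model$scale))
  p <- switch(model$fit_kind,
    glm = as.numeric(stats::predict(model$fit, newdata = Z,
                                    type = "response")),
    glm_ridge = {
      mm <- as.matrix(cbind(Z, Z^2))
      as.numeric(stats::predict(model$fit, newx = mm, type = "response"))
    },
    gam = as.numeric(mgcv::predict.gam(model$fit, newdata = Z,
                                       type = "response")),
    gbm = stats::predict(model$fit, as.matrix(Xo)),
    rf = stats::predict(model$fit, newdata = Xo, type = "prob")[, "1"],
    maxent = {
      # clamp to the training range (standard maxent projection behaviour)
      for (nm in names(Z)) {
        zr <- (model$ranges[, nm] - model$centre[nm]) / model$scale[nm]
        Z[[nm]] <- pmin(pmax(Z[[nm]], zr[1]), zr[2])
      }
      raw <- maxent_raw(model, Z)
      1 - exp(-exp(model$fit$entropy) * raw)
    },
    stop("unknown fit kind"))
  out[ok] <- pmin(pmax(as.numeric(p), 0), 1)
  out
}

#' Predict a suitability raster from a fitted model
#'
#' Applies the model cellwise over a predictor stack; nodata propagates.
#' Identical to predicting on the table of the cells' values.
#'
#' @param model An `sdm_model` or `sdm_ensemble`.
#' @param stack A `predictor_stack` holding all model predictors.
#' @return A `raster_grid` of suitability in `[0, 1]`.
#' @export
predict_suitability <- function(model, stack) {
  stopifnot(inherits(stack, "predictor_stack"))
  preds <- if (inherits(model, "sdm_ensemble"))
    unique(unlist(lapply(model$members, `[[`, "predictors")))
  else model$predictors
  missing <- setdiff(preds, names(stack))
  if (length(missing))
    stop("stack lacks predictor layer(s): ",
         paste(missing, collapse = ", "))
  vals <- as.data.frame(stack_values(stack))
  p <- predict_sdm(model, vals)
  g <- stack[[1]]
  g$values <- matrix(p, nrow(g$values), ncol(g$values))
  g
}

#' Response curve of a fitted model
#'
#' Varies one predictor over an even grid across its training range while
#' holding every other predictor at its mean over the training data
#' (presences + background), and records the predicted suitability — the
#' standard marginal response curve display.
#'
#' @param model An `sdm_model` or `sdm_ensemble`.
#' @param predictor Name of the focal predictor.
#' @param grid_size Number of evaluation points (default 100).
#' @return A data.frame of class `response_curve` with columns `value` and
#'   `suitability`, plus attributes `predictor` and `held_at`.
#' @export
response_curve <- function(model, predictor, grid_size = 100) {
  preds <- if (inherits(model, "sdm_ensemble"))
    model$members[[1]]$predictors else model$predictors
  if (!predictor %in% preds)
    stop("unknown predictor '", predictor, "'")
  ranges <- if (inherits(model, "sdm_ensemble"))
    model$members[[1]]$ranges else model$ranges
  means <- if (inherits(model, "sdm_ensemble"))
    model$members[[1]]$train_means else model$train_means
  grid <- seq(ranges[1, predictor], ranges[2, predictor],
              length.out = grid_size)
  nd <- as.data.frame(lapply(means, rep, grid_size))
  nd[[predictor]] <- grid
  suit <- predict_sdm(model, nd)
  structure(data.frame(value = grid, suitability = suit),
            predictor = predictor,
            held_at = means[setdiff(preds, predictor)],
            class = c("response_curve", "data.frame"))
}

#' Peak of a response curve
#'
#' @param curve A `response_curve`.
#' @return The predictor value with maximum predicted suitability.
#' @export
response_peak <- function(curve) curve$value[which.max(curve$suitability)]
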