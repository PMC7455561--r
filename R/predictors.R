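#' Slope from elevation (Horn's method)
#'
#' Computes terrain slope in degrees from an elevation raster using Horn's
#' 8-neighbour weighted finite differences, the standard method of terrain
#' analysis toolchains. Border cells and cells adjacent to nodata are
#' masked rather than estimated from fewer neighbours. Geographic grids
#' convert the degree spacing to metres per row using the local
#' metres-per-degree at each row's latitude (sphere radius 6,371.0088 km).
#'
#' @param elevation A `raster_grid` of elevation in metres.
#' @return A `raster_grid` of slope in degrees on the same grid.
#' @export
compute_slope <- function(elevation) {
  stopifnot(inherits(elevation, "raster_grid"))
  z <- elevation$values
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 2 || nc < 2)
    stop("slope needs at least a 2 x 2 raster")
  # 3x3 neighbourhood around interior cells: rows 2..nr-1, cols 2..nc-1
  ri <- 2:(nr - 1); ci <- 2:(nc - 1)
  nb <- function(dr, dc) z[ri + dr, ci + dc, drop = FALSE]
  a <- nb(-1, -1); b <- nb(-1, 0); c_ <- nb(-1, 1)
  d <- nb(0, -1);                  f <- nb(0, 1)
  g <- nb(1, -1);  h <- nb(1, 0);  i_ <- nb(1, 1)

  if (elevation$crs == "projected") {
    dx <- matrix(elevation$cellsize, length(ri), length(ci))
    dy <- dx
  } else {
    m_per_deg <- pi / 180 * 6371008.8
    lat <- row_latitudes(elevation)[ri]
    dx <- matrix(elevation$cellsize * m_per_deg * cos(lat * pi / 180),
                 length(ri), length(ci))
    dy <- matrix(elevation$cellsize * m_per_deg, length(ri), length(ci))
  }
  dzdx <- ((c_ + 2 * f + i_) - (a + 2 * d + g)) / (8 * dx)
  dzdy <- ((g + 2 * h + i_) - (a + 2 * b + c_)) / (8 * dy)
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  # Horn's differences ignore the centre cell; mask nodata cells themselves
  slope[is.na(nb(0, 0))] <- NA

  out <- matrix(NA_real_, nr, nc)
  out[ri, ci] <- slope
  elevation$values <- out
  elevation
}

#' Topographic heterogeneity (block standard deviation of elevation)
#'
#' Aggregates a fine-resolution elevation raster into blocks of
#' `block x block` cells and returns, per coarse cell, the sample standard
#' deviation (denominator n - 1) of the constituent fine-cell elevations —
#' a ruggedness measure. Partial edge blocks are computed from the
#' available cells when at least 2 are valid, otherwise masked.
#'
#' @param elevation_fine A `raster_grid` of elevation.
#' @param block Number of fine cells per coarse cell side (>= 2); e.g. a
#'   1 km coarse grid from 90 m elevation uses `block = 11`.
#' @return A coarse `raster_grid` (cellsize multiplied by `block`) sharing
#'   the fine grid's top-left corner.
#' @export
compute_topographic_heterogeneity <- function(elevation_fine, block) {
  stopifnot(inherits(elevation_fine, "raster_grid"))
  block <- as.integer(block)
  z <- elevation_fine$values
  if (block < 2) stop("`block` must be >= 2")
  if (block > nrow(z) || block > ncol(z))
    stop("`block` exceeds the raster dimensions")
  nr_c <- ceiling(nrow(z) / block)
  nc_c <- ceiling(ncol(z) / block)
  out <- matrix(NA_real_, nr_c, nc_c)
  for (i in seq_len(nr_c)) {
    rows <- ((i - 1) * block + 1):min(i * block, nrow(z))
    for (j in seq_len(nc_c)) {
      cols <- ((j - 1) * block + 1):min(j * block, ncol(z))
      v <- z[rows, cols]
      v <- v[!is.na(v)]
      if (length(v) >= 2) out[i, j] <- stats::sd(v)
    }
  }
  cs <- elevation_fine$cellsize * block
  # coarse grid anchored at the fine grid's top-left corner
  raster_grid(out,
              xmin = elevation_fine$xmin,
              ymin = grid_ymax(elevation_fine) - nr_c * cs,
              cellsize = cs, crs = elevation_fine$crs)
}

#' Stepwise variance-inflation-factor predictor selection
#'
#' VIF_j = 1 / (1 - R²_j), with R²_j from the ordinary-least-squares
#' regression (with intercept) of predictor j on all the others. While any
#' VIF meets or exceeds the threshold, the predictor with the largest VIF
#' is dropped (for exactly collinear groups, the later-listed member) and
#' the VIFs recomputed — the usual stepwise collinearity filter for
#' distribution modelling.
#'
#' @param values Data.frame (or matrix) of predictor columns; at least two
#'   columns and `ncol + 2` rows, no constant column.
#' @param threshold Removal threshold (default 10, the conventional
#'   stepwise-VIF default).
#' @return A `vif_report`: list with `vif` (final named VIF vector),
#'   `removed` (removal order, possibly empty), `threshold`, and `steps`
#'   (per-iteration VIF tables).
#' @export
vif_stepwise <- function(values, threshold = 10) {
  df <- as.data.frame(values)
  if (ncol(df) < 2) stop("need at least 2 predictor columns")
  if (nrow(df) < ncol(df) + 2)
    stop("need at least ncol + 2 rows to estimate VIFs")
  if (any(!vapply(df, is.numeric, logical(1))))
    stop("all columns must be numeric")
  const <- vapply(df, function(x) stats::sd(x) == 0, logical(1))
  if (any(const))
    stop("constant column(s): ", paste(names(df)[const], collapse = ", "))
  if (threshold <= 1) stop("`threshold` must exceed 1")

  removed <- character(0)
  steps <- list()
  repeat {
    v <- vif_values(df)
    steps[[length(steps) + 1]] <- v
    if (ncol(df) == 1 || max(v) < threshold) break
    worst <- max(v)
    cand <- which(v == worst)
    drop_nm <- names(df)[cand[length(cand)]]  # later-listed member on ties
    removed <- c(removed, drop_nm)
    df <- df[setdiff(names(df), drop_nm)]
  }
  structure(list(vif = v, removed = removed, threshold = threshold,
                 steps = steps),
            class = "vif_report")
}

# per-column VIF by explicit OLS of column j on the others
vif_values <- function(df) {
  nms <- names(df)
  if (length(nms) == 1) return(stats::setNames(1, nms))
  vapply(nms, function(nm) {
    fit <- stats::lm(stats::reformulate(nms[nms != nm], response = nm),
                     data = df)
    # summary.lm warns on exactly collinear fits; R^2 = 1 is the answer
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' @export
print.vif_report <- function(x, ...) {
  cat("Stepwise VIF (threshold", x$threshold, ")\n")
  if (length(x$removed))
    cat("removed:", paste(x$removed, collapse = " -> "), "\n")
  else cat("removed: none\n")
  print(round(x$vif, 3))
  invisible(x)
}

#' Serialize a VIF report to JSON
#'
#' @param report A `vif_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vif_report <- function(report, path) {
  jsonlite::write_json(
    list(vif = as.list(report$vif), removed = report$removed,
         threshold = report$threshold),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Align raster layers onto a common grid
#'
#' Resamples every layer (nearest neighbour: each target cell takes the
#' value of the source cell containing its centre) onto the grid of a
#' reference layer, cropped to the common overlapping extent snapped to the
#' reference lattice, and applies the union-of-nodata mask.
#'
#' @param layers Named list of `raster_grid`s with overlapping extents and
#'   a shared CRS kind.
#' @param reference Name or index of the layer whose grid defines the
#'   target lattice (default: the first).
#' @return A `predictor_stack`.
#' @export
align_stack <- function(layers, reference = 1) {
  if (!is.list(layers) || is.null(names(layers)))
    stop("`layers` must be a named list of raster_grid objects")
  ref <- layers[[reference]]
  if (length(unique(vapply(layers, function(g) g$crs, character(1)))) != 1)
    stop("layers have mixed CRS kinds")
  xmin <- max(vapply(layers, function(g) g$xmin, numeric(1)))
  xmax <- min(vapply(layers, grid_xmax, numeric(1)))
  ymin <- max(vapply(layers, function(g) g$ymin, numeric(1)))
  ymax <- min(vapply(layers, grid_ymax, numeric(1)))
  if (xmax - xmin < ref$cellsize || ymax - ymin < ref$cellsize)
    stop("layer extents are disjoint (no common cell)")
  # snap the common extent inward to the reference lattice
  cs <- ref$cellsize
  x0 <- ref$xmin + ceiling((xmin - ref$xmin) / cs - 1e-9) * cs
  y1 <- grid_ymax(ref) - ceiling((grid_ymax(ref) - ymax) / cs - 1e-9) * cs
  nc <- floor((xmax - x0) / cs + 1e-9)
  nr <- floor((y1 - ymin) / cs + 1e-9)
  if (nc < 1 || nr < 1) stop("layer extents are disjoint (no common cell)")
  cx <- x0 + (seq_len(nc) - 0.5) * cs
  cy <- y1 - (seq_len(nr) - 0.5) * cs
  pts_x <- rep(cx, each = nr)
  pts_y <- rep(cy, times = nc)
  out <- lapply(layers, function(g) {
    cc <- cell_from_xy(g, pts_x, pts_y)
    vals <- rep(NA_real_, nr * nc)
    ok <- !is.na(cc$cell)
    vals[ok] <- g$values[cbind(cc$row[ok], cc$col[ok])]
    raster_grid(matrix(vals, nr, nc), xmin = x0, ymin = y1 - nr * cs,
                cellsize = cs, crs = g$crs)
  })
  predictor_stack(out)
}
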