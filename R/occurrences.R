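#' Georeferenced presence records
#'
#' A data.frame of point records (`x`, `y`) carrying a species label, a
#' processing stage flag (`raw`, `deduplicated`, or `thinned`), and the CRS
#' kind of the coordinates. For geographic sets `x` is longitude and `y`
#' latitude in decimal degrees; for projected sets both are metres.
#'
#' @param x,y Coordinate vectors (finite).
#' @param species Species label.
#' @param stage Processing stage flag.
#' @param crs `"geographic"` or `"projected"`.
#' @return An object of class `occurrence_set` (also a data.frame).
#' @export
occurrence_set <- function(x, y, species = "species",
                           stage = c("raw", "deduplicated", "thinned"),
                           crs = c("projected", "geographic")) {
  stage <- match.arg(stage)
  crs <- match.arg(crs)
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("coordinates must be finite")
  structure(data.frame(x = as.numeric(x), y = as.numeric(y)),
            species = species, stage = stage, crs = crs,
            class = c("occurrence_set", "data.frame"))
}

occ_meta <- function(occ, stage = NULL) {
  list(species = attr(occ, "species"),
       stage = if (is.null(stage)) attr(occ, "stage") else stage,
       crs = attr(occ, "crs"))
}

rebuild_occ <- function(occ, keep, stage) {
  m <- occ_meta(occ, stage)
  occurrence_set(occ$x[keep], occ$y[keep], species = m$species,
                 stage = stage, crs = m$crs)
}

#' @export
`[.occurrence_set` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("x", "y") %in% names(out))) {
    attr(out, "species") <- attr(x, "species")
    attr(out, "stage") <- attr(x, "stage")
    attr(out, "crs") <- attr(x, "crs")
    class(out) <- class(x)
  }
  out
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("occurrence_set: %d records of '%s' (stage %s, %s)\n",
              nrow(x), attr(x, "species"), attr(x, "stage"), attr(x, "crs")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Read occurrence records from delimited text
#'
#' Parses a CSV (or other single-character-delimited) file of point records.
#' Rows with missing, non-numeric or out-of-range coordinates (|lat| > 90 or
#' |lon| > 180 for geographic data) are skipped with a warning that reports
#' the count; duplicates are preserved (reading is not a filter).
#'
#' @param path Path to the delimited file.
#' @param x_col,y_col Names of the coordinate columns (defaults `"lon"`,
#'   `"lat"`; for projected data conventionally `"x"`, `"y"`).
#' @param species Species label; defaults to the value of a `species` column
#'   if one exists, else the file name.
#' @param crs CRS kind of the coordinates.
#' @param sep Field delimiter.
#' @return An `occurrence_set` with stage `"raw"`.
#' @export
read_occurrences <- function(path, x_col = "lon", y_col = "lat",
                             species = NULL,
                             crs = c("geographic", "projected"),
                             sep = ",") {
  crs <- match.arg(crs)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("no records in ", path)
  if (!all(c(x_col, y_col) %in% names(df)))
    stop("coordinate columns '", x_col, "'/'", y_col, "' not found in ",
         path, " (columns: ", paste(names(df), collapse = ", "), ")")
  x <- suppressWarnings(as.numeric(df[[x_col]]))
  y <- suppressWarnings(as.numeric(df[[y_col]]))
  bad <- !is.finite(x) | !is.finite(y)
  if (crs == "geographic") bad <- bad | abs(y) > 90 | abs(x) > 180
  if (any(bad))
    warning(sum(bad), " malformed row(s) skipped while reading ", path)
  if (all(bad)) stop("no valid coordinate rows in ", path)
  if (is.null(species)) {
    species <- if ("species" %in% names(df) && !all(bad))
      as.character(df$species[!bad][1]) else basename(path)
  }
  occurrence_set(x[!bad], y[!bad], species = species, stage = "raw",
                 crs = crs)
}

#' Write an occurrence set to CSV
#'
#' Columns `species`, `x`, `y`, `stage`. For geographic sets the coordinate
#' columns are named `lon`, `lat`.
#'
#' @param occ An `occurrence_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path) {
  m <- occ_meta(occ)
  df <- data.frame(species = m$species, x = occ$x, y = occ$y,
                   stage = m$stage)
  if (m$crs == "geographic") names(df)[2:3] <- c("lon", "lat")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Collapse records to one per grid cell
#'
#' Keeps the first record in each grid cell of side `cell_size` (by default
#' the cell grid of a supplied reference raster, so de-duplication operates
#' at the predictor resolution). Exact coordinate duplicates always collapse.
#'
#' @param occ An `occurrence_set` (stage `"raw"`).
#' @param cell_size Cell side in map units; ignored when `grid` is given.
#' @param grid Optional `raster_grid` (or `predictor_stack`) whose cells
#'   define the de-duplication lattice.
#' @return An `occurrence_set` with stage `"deduplicated"`.
#' @export
deduplicate <- function(occ, cell_size = NULL, grid = NULL) {
  stopifnot(inherits(occ, "occurrence_set"))
  if (inherits(grid, "predictor_stack")) grid <- grid[[1]]
  if (!is.null(grid)) {
    cc <- cell_from_xy(grid, occ$x, occ$y)
    key <- paste(cc$row, cc$col)
  } else {
    if (is.null(cell_size) || cell_size <= 0)
      stop("provide `cell_size` > 0 or a reference `grid`")
    key <- paste(floor(occ$x / cell_size), floor(occ$y / cell_size))
  }
  keep <- !duplicated(key)
  rebuild_occ(occ, keep, "deduplicated")
}

#' Pairwise distances between occurrence points
#'
#' Great-circle (haversine, sphere radius 6,371.0088 km) for geographic
#' sets; Euclidean for projected sets. Always in metres.
#'
#' @param occ An `occurrence_set`.
#' @return A symmetric matrix of distances in metres.
#' @export
occurrence_distances <- function(occ) {
  p <- cbind(occ$x, occ$y)
  if (attr(occ, "crs") == "geographic") {
    geosphere::distm(p, fun = function(a, b)
      geosphere::distHaversine(a, b, r = 6371008.8))
  } else {
    as.matrix(stats::dist(p))
  }
}

#' Spatially thin occurrence records to a minimum distance
#'
#' Enforces a minimum pairwise distance between records (the standard
#' autocorrelation filter for presence-only modelling). Uses randomized
#' greedy removal: while any pair is closer than `min_dist`, delete a point
#' with the maximum number of conflicts, breaking ties by seeded RNG; the
#' procedure is repeated `n_repeats` times and the run retaining the most
#' points is returned, approximating maximum-retention thinning.
#'
#' @param occ An `occurrence_set`.
#' @param min_dist Minimum pairwise distance in metres (default 5 km).
#' @param seed Integer RNG seed (tie-breaking).
#' @param n_repeats Number of randomized greedy runs (default 100).
#' @return An `occurrence_set` with stage `"thinned"`; all pairwise
#'   distances are `>= min_dist`.
#' @export
spatial_thin <- function(occ, min_dist = 5000, seed = 1L, n_repeats = 100) {
  stopifnot(inherits(occ, "occurrence_set"))
  if (min_dist <= 0) stop("`min_dist` must be > 0")
  n <- nrow(occ)
  if (n <= 1) return(rebuild_occ(occ, rep(TRUE, n), "thinned"))
  d <- occurrence_distances(occ)
  conflict <- d < min_dist
  diag(conflict) <- FALSE
  if (!any(conflict)) return(rebuild_occ(occ, rep(TRUE, n), "thinned"))
  local_rng(seed)
  best <- NULL
  for (rep_i in seq_len(n_repeats)) {
    alive <- rep(TRUE, n)
    repeat {
      deg <- rowSums(conflict[, alive, drop = FALSE])
      deg[!alive] <- 0L
      if (max(deg) == 0) break
      cand <- which(deg == max(deg))
      drop_i <- if (length(cand) == 1) cand else sample(cand, 1L)
      alive[drop_i] <- FALSE
    }
    if (is.null(best) || sum(alive) > sum(best)) best <- alive
  }
  rebuild_occ(occ, best, "thinned")
}

#' Extract predictor values at occurrence points
#'
#' Looks up the containing cell of each point (no interpolation, half-open
#' cell convention) in every layer of the stack. Points outside the raster
#' extent or in nodata cells are excluded with a warning; the counts are
#' attached as attributes `n_outside` and `n_nodata`, and the indices of the
#' retained points as `kept`.
#'
#' @param occ An `occurrence_set`; must share `crs` with the stack.
#' @param stack A `predictor_stack`.
#' @return A data.frame, one row per retained point, one column per
#'   predictor.
#' @export
extract_env_values <- function(occ, stack) {
  stopifnot(inherits(occ, "occurrence_set"),
            inherits(stack, "predictor_stack"))
  if (attr(occ, "crs") != stack[[1]]$crs)
    stop("occurrence set and stack have different CRS kinds")
  cc <- cell_from_xy(stack[[1]], occ$x, occ$y)
  outside <- is.na(cc$cell)
  vals <- stack_values(stack)
  out <- matrix(NA_real_, nrow(occ), ncol(vals),
                dimnames = list(NULL, colnames(vals)))
  out[!outside, ] <- vals[cc$cell[!outside], , drop = FALSE]
  nodata <- !outside & apply(out, 1, function(r) any(is.na(r)))
  if (any(outside))
    warning(sum(outside), " point(s) outside the raster extent excluded")
  if (any(nodata))
    warning(sum(nodata), " point(s) in nodata cells excluded")
  keep <- !outside & !nodata
  res <- as.data.frame(out[keep, , drop = FALSE])
  attr(res, "n_outside") <- sum(outside)
  attr(res, "n_nodata") <- sum(nodata)
  attr(res, "kept") <- which(keep)
  res
}
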