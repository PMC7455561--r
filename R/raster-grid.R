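#' Gridded raster layer
#'
#' A minimal in-memory single-band raster: a numeric matrix with a regular
#' grid transform. Row 1 is the top (northernmost) row of the grid, matching
#' the row order of the ESRI ASCII grid interchange format. `NA` cells are
#' nodata.
#'
#' @param values Numeric matrix of cell values; `NA` marks nodata.
#' @param xmin,ymin Coordinates of the lower-left corner of the grid, in map
#'   units (metres for projected grids, decimal degrees for geographic).
#' @param cellsize Cell side length in map units; must be positive. Cells are
#'   square.
#' @param crs Either `"projected"` (metre units) or `"geographic"` (degree
#'   units). Controls how distances and cell areas are computed downstream.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, xmin = 0, ymin = 0, cellsize = 1,
                        crs = c("projected", "geographic")) {
  crs <- match.arg(crs)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (!is.finite(cellsize) || cellsize <= 0)
    stop("`cellsize` must be a positive number")
  if (any(!is.finite(values) & !is.na(values)))
    stop("non-finite values present outside the nodata mask")
  structure(
    list(values = values, xmin = xmin, ymin = ymin,
         cellsize = cellsize, crs = crs),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("raster_grid: %d x %d cells, cellsize %g (%s)\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$crs))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]; %d nodata cells\n",
              x$xmin, grid_xmax(x), x$ymin, grid_ymax(x),
              sum(is.na(x$values))))
  invisible(x)
}

grid_xmax <- function(g) g$xmin + ncol(g$values) * g$cellsize
grid_ymax <- function(g) g$ymin + nrow(g$values) * g$cellsize

#' @export
dim.raster_grid <- function(x) dim(x$values)

same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymin - b$ymin) < tol &&
    abs(a$cellsize - b$cellsize) < tol && a$crs == b$crs
}

#' Cell indices containing points
#'
#' Maps coordinates to (row, col) using half-open cells: a cell includes its
#' left and top edges, so a point on a shared vertical edge belongs to the
#' cell on its right, and a point on a shared horizontal edge to the cell
#' below. Row 1 is the top row. Points outside the extent get `NA`.
#'
#' @param grid A `raster_grid`.
#' @param x,y Coordinate vectors in the grid's map units.
#' @return A data.frame with columns `row`, `col`, `cell` (column-major cell
#'   index into `grid$values`), `NA` where the point falls outside.
#' @export
cell_from_xy <- function(grid, x, y) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  col <- floor((x - grid$xmin) / grid$cellsize) + 1L
  row <- floor((grid_ymax(grid) - y) / grid$cellsize) + 1L
  bad <- !is.finite(x) | !is.finite(y) |
    col < 1L | col > nc | row < 1L | row > nr
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col),
             cell = as.integer(row + (col - 1L) * nr))
}

#' Coordinates of cell centres
#'
#' @param grid A `raster_grid`.
#' @param row,col Integer vectors of cell indices (row 1 = top).
#' @return A data.frame with columns `x`, `y`.
#' @export
xy_from_cell <- function(grid, row, col) {
  data.frame(x = grid$xmin + (col - 0.5) * grid$cellsize,
             y = grid_ymax(grid) - (row - 0.5) * grid$cellsize)
}

# latitude of each row's cell centre (geographic grids)
row_latitudes <- function(grid) {
  grid_ymax(grid) - (seq_len(nrow(grid$values)) - 0.5) * grid$cellsize
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text georeferenced raster interchange format (readable by GDAL and
#' QGIS). Nodata cells are written as the `nodata` sentinel.
#'
#' @param grid A `raster_grid`.
#' @param path Output file path (conventionally `.asc`).
#' @param nodata Sentinel value for nodata cells.
#' @param digits Significant digits used when formatting cell values.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999, digits = 10) {
  v <- grid$values
  header <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", grid$xmin),
    sprintf("yllcorner %.10g", grid$ymin),
    sprintf("cellsize %.10g", grid$cellsize),
    sprintf("NODATA_value %.10g", nodata)
  )
  v[is.na(v)] <- nodata
  body <- apply(v, 1, function(r) paste(formatC(r, digits = digits, format = "g"),
                                        collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path Path to an `.asc` file.
#' @param crs CRS kind of the grid (not stored in the format itself).
#' @return A `raster_grid`.
#' @export
read_ascii_grid <- function(path, crs = c("projected", "geographic")) {
  crs <- match.arg(crs)
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$nrows * hdr$ncols)
    stop("cell count does not match header in ", path)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  raster_grid(m, xmin = hdr$xllcorner, ymin = hdr$yllcorner,
              cellsize = hdr$cellsize, crs = crs)
}

#' Bundle aligned raster layers into a predictor stack
#'
#' All layers must share grid geometry. The stack's nodata mask is the union
#' of the member masks: a cell that is nodata in any layer is set to nodata
#' in all of them.
#'
#' @param layers Named list of `raster_grid` objects.
#' @return An object of class `predictor_stack` (a named list of aligned
#'   `raster_grid`s).
#' @export
predictor_stack <- function(layers) {
  if (!is.list(layers) || length(layers) == 0 || is.null(names(layers)) ||
      any(names(layers) == ""))
    stop("`layers` must be a non-empty named list of raster_grid objects")
  if (!all(vapply(layers, inherits, logical(1), "raster_grid")))
    stop("all layers must be raster_grid objects")
  ref <- layers[[1]]
  for (nm in names(layers)) {
    if (!same_geometry(layers[[nm]], ref))
      stop("layer '", nm, "' does not share the reference grid geometry; ",
           "use align_stack() first")
  }
  mask <- Reduce(`|`, lapply(layers, function(g) is.na(g$values)))
  for (nm in names(layers)) layers[[nm]]$values[mask] <- NA
  structure(layers, class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  g <- x[[1]]
  cat(sprintf("predictor_stack: %d layers (%s), %d x %d cells (%s)\n",
              length(x), paste(names(x), collapse = ", "),
              nrow(g$values), ncol(g$values), g$crs))
  invisible(x)
}

# matrix of valid-cell values, one column per layer
stack_values <- function(stack, cells = NULL) {
  m <- vapply(stack, function(g) as.vector(g$values),
              numeric(length(stack[[1]]$values)))
  colnames(m) <- names(stack)
  if (!is.null(cells)) m <- m[cells, , drop = FALSE]
  m
}

valid_cells <- function(stack) which(!is.na(stack[[1]]$values))
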