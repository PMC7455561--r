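#' Normalize a suitability map to a probability surface
#'
#' Divides the valid-cell values by their sum so the surface integrates to
#' one — the distribution form that niche-overlap metrics compare.
#' Idempotent and invariant to positive rescaling of the input.
#'
#' @param map A suitability `raster_grid` with at least one valid cell > 0.
#' @return A `raster_grid` whose valid cells sum to 1 (within 1e-9).
#' @export
normalize_suitability <- function(map) {
  stopifnot(inherits(map, "raster_grid"))
  v <- map$values
  s <- sum(v, na.rm = TRUE)
  if (!is.finite(s) || s <= 0)
    stop("map has no positive valid cell; cannot normalize")
  map$values <- v / s
  map
}

#' Schoener's D niche overlap
#'
#' D = 1 - 0.5 * sum |p_i - q_i| over the shared cells of two probability
#' surfaces. Ranges from 0 (disjoint niches) to 1 (identical niches);
#' symmetric in its arguments.
#'
#' @param p,q Probability-surface `raster_grid`s on the same grid and mask
#'   (each summing to 1 over valid cells).
#' @return D in `[0, 1]`.
#' @export
schoeners_d <- function(p, q) {
  check_probability_pair(p, q)
  1 - 0.5 * sum(abs(p$values - q$values), na.rm = TRUE)
}

#' Hellinger-based niche overlap (I statistic)
#'
#' I = 1 - 0.5 * sum (sqrt(p_i) - sqrt(q_i))^2, the companion overlap
#' statistic based on Hellinger distance; same 0-1 semantics as Schoener's
#' D and symmetric.
#'
#' @inheritParams schoeners_d
#' @return I in `[0, 1]`.
#' @export
hellinger_i <- function(p, q) {
  check_probability_pair(p, q)
  1 - 0.5 * sum((sqrt(p$values) - sqrt(q$values))^2, na.rm = TRUE)
}

check_probability_pair <- function(p, q) {
  stopifnot(inherits(p, "raster_grid"), inherits(q, "raster_grid"))
  if (!same_geometry(p, q)) stop("surfaces are on different grids")
  if (!identical(is.na(p$values), is.na(q$values)))
    stop("surfaces have different nodata masks")
  for (s in list(p, q))
    if (abs(sum(s$values, na.rm = TRUE) - 1) > 1e-6)
      stop("inputs must be normalized probability surfaces ",
           "(see normalize_suitability)")
  invisible(TRUE)
}

#' Niche overlap between two suitability maps
#'
#' Restricts both maps to their common valid support (cells nodata in
#' either are dropped from both), renormalizes each over that support, and
#' computes Schoener's D and the Hellinger-based I.
#'
#' @param map1,map2 Suitability `raster_grid`s on the same grid.
#' @return An `overlap_result`: list with `schoener_d`, `hellinger_i`, and
#'   `n_cells` (cells compared).
#' @export
niche_overlap <- function(map1, map2) {
  stopifnot(inherits(map1, "raster_grid"), inherits(map2, "raster_grid"))
  if (!same_geometry(map1, map2)) stop("maps are on different grids")
  mask <- is.na(map1$values) | is.na(map2$values)
  map1$values[mask] <- NA
  map2$values[mask] <- NA
  p <- normalize_suitability(map1)
  q <- normalize_suitability(map2)
  structure(list(schoener_d = schoeners_d(p, q),
                 hellinger_i = hellinger_i(p, q),
                 n_cells = sum(!mask)),
            class = "overlap_result")
}

#' Pairwise niche-overlap matrix
#'
#' All pairwise Schoener's D (and Hellinger I) values between a set of
#' aligned suitability maps; both matrices are symmetric with unit
#' diagonal.
#'
#' @param maps Named list (>= 2) of aligned suitability `raster_grid`s.
#' @return List with matrices `schoener_d` and `hellinger_i`, and
#'   `n_cells` (pairwise cell counts).
#' @export
overlap_matrix <- function(maps) {
  if (length(maps) < 2 || is.null(names(maps)))
    stop("need a named list of at least 2 maps")
  k <- length(maps); nms <- names(maps)
  D <- I <- N <- matrix(NA_real_, k, k, dimnames = list(nms, nms))
  diag(D) <- diag(I) <- 1
  for (i in seq_len(k)) {
    N[i, i] <- sum(!is.na(maps[[i]]$values))
    if (i < k) for (j in (i + 1):k) {
      ov <- niche_overlap(maps[[i]], maps[[j]])
      D[i, j] <- D[j, i] <- ov$schoener_d
      I[i, j] <- I[j, i] <- ov$hellinger_i
      N[i, j] <- N[j, i] <- ov$n_cells
    }
  }
  list(schoener_d = D, hellinger_i = I, n_cells = N)
}

#' Write an overlap matrix to CSV and JSON
#'
#' @param ov Result of [overlap_matrix()].
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_overlap <- function(ov, csv_path = NULL, json_path = NULL) {
  nms <- rownames(ov$schoener_d)
  pairs <- utils::combn(nms, 2)
  df <- data.frame(
    species_a = pairs[1, ], species_b = pairs[2, ],
    schoener_d = ov$schoener_d[t(pairs)],
    hellinger_i = ov$hellinger_i[t(pairs)],
    n_cells = ov$n_cells[t(pairs)])
  if (!is.null(csv_path)) utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(df, json_path, dataframe = "rows", digits = NA)
  invisible(c(csv_path, json_path))
}
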