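#' Level a surface by least squares
#'
#' Subtracts the best-fit plane (ordinary least squares over unmasked cells).
#' After levelling, the residuals are orthogonal to the constant, x and y
#' basis functions. Idempotent.
#'
#' @param map a [height_map()].
#' @return The levelled height map.
#' @export
level_surface <- function(map) {
  remove_form(map, degree = 1L)
}

#' Remove polynomial form
#'
#' Subtracts the least-squares polynomial of total degree `degree` in (x, y)
#' (degree 3 by default: the 10-monomial cubic form operator; degree 1 is
#' plane levelling; degree 0 is mean centring). Residuals are orthogonal to
#' every retained monomial. Idempotent.
#'
#' @param map a [height_map()].
#' @param degree total polynomial degree (>= 0).
#' @return The detrended height map.
#' @export
remove_form <- function(map, degree = 3L) {
  assert_heightmap(map)
  degree <- as.integer(degree)
  stopifnot(degree >= 0)
  ok <- which(map$mask)
  n_basis <- (degree + 1) * (degree + 2) / 2
  if (length(ok) < n_basis) {
    stop("not enough unmasked cells for a degree-", degree, " polynomial")
  }
  g <- hm_xy_grids(map)
  # centre/scale coordinates for conditioning
  xs <- (g$X[ok] - mean(g$X[ok]))
  ys <- (g$Y[ok] - mean(g$Y[ok]))
  sc <- max(stats::sd(xs), stats::sd(ys), 1e-12)
  xs <- xs / sc; ys <- ys / sc
  cols <- list()
  for (d in 0:degree) for (i in 0:d) cols[[length(cols) + 1]] <- xs^(d - i) * ys^i
  A <- do.call(cbind, cols)
  qrA <- qr(A)
  if (qrA$rank < ncol(A)) stop("rank-deficient polynomial design (collinear cells?)")
  fit <- qr.fitted(qrA, map$heights[ok])
  out <- map
  out$heights[ok] <- map$heights[ok] - fit
  out$heights[!map$mask] <- NA_real_
  out$mask <- map$mask
  log_event(out, "remove_form", list(degree = degree))
}

#' Split a map into non-overlapping square sub-areas
#'
#' Tiles the map with `n` non-overlapping square tiles of side `tile` mm in a
#' centred grid layout (3 x 3 for the default nine tiles). Each tile can be
#' flagged worked/unworked from an optional logical mask on the parent grid,
#' so unworked tiles can be excluded downstream.
#'
#' @param map a [height_map()].
#' @param tile tile side, mm.
#' @param n number of tiles; must be a perfect square for the grid layout.
#' @param worked_mask optional logical matrix on the parent grid marking
#'   worked cells; a tile is flagged worked when more than half its cells are.
#' @return List of [height_map()] tiles, each with `meta$window`
#'   (row0, col0, rows, cols) and `meta$worked`.
#' @export
subdivide <- function(map, tile = 10, n = 9, worked_mask = NULL) {
  assert_heightmap(map)
  k <- as.integer(round(sqrt(n)))
  if (k * k != n) stop("n must be a perfect square for the grid layout")
  cells <- as.integer(round(tile / map$spacing))
  nr <- nrow(map$heights); nc <- ncol(map$heights)
  need <- k * cells
  if (need > nr || need > nc) {
    feasible <- (min(nr, nc) %/% cells)^2
    stop(sprintf("map too small for %d tiles of %g mm; at most %d tiles fit",
                 n, tile, feasible))
  }
  row_off <- (nr - need) %/% 2L
  col_off <- (nc - need) %/% 2L
  tiles <- list()
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      r0 <- row_off + (i - 1L) * cells + 1L
      c0 <- col_off + (j - 1L) * cells + 1L
      rr <- r0:(r0 + cells - 1L); cc <- c0:(c0 + cells - 1L)
      worked <- if (is.null(worked_mask)) TRUE else
        mean(worked_mask[rr, cc]) > 0.5
      sub <- height_map(
        map$heights[rr, cc, drop = FALSE], map$spacing,
        origin = c(map$origin[1] + (c0 - 1L) * map$spacing,
                   map$origin[2] + (r0 - 1L) * map$spacing),
        mask = map$mask[rr, cc, drop = FALSE],
        meta = c(map$meta,
                 list(window = c(row0 = r0, col0 = c0,
                                 rows = cells, cols = cells),
                      worked = worked))
      )
      tiles[[length(tiles) + 1L]] <- sub
    }
  }
  tiles
}
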