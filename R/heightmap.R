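#' Create a height map
#'
#' A height map is the substrate of all texture computation: a regular grid of
#' surface heights (mm) with a lateral sample spacing (mm), an origin, and a
#' per-cell validity mask. Rows run along y (upwards), columns along x
#' (rightwards); heights are measured along +z.
#'
#' @param heights numeric matrix of heights in mm; `NA` cells are masked out.
#' @param spacing lateral sample spacing in mm (> 0).
#' @param origin length-2 numeric, (x0, y0) of the first grid node in mm.
#' @param mask logical matrix of the same dimension; `TRUE` marks valid cells.
#'   Defaults to `!is.na(heights)`.
#' @param meta named list of provenance information.
#' @return An object of class `heightmap`.
#' @export
height_map <- function(heights, spacing, origin = c(0, 0), mask = NULL,
                       meta = list()) {
  heights <- as.matrix(heights)
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0) {
    stop("`spacing` must be a single positive number (mm)")
  }
  if (is.null(mask)) mask <- !is.na(heights)
  mask <- mask & !is.na(heights)
  storage.mode(heights) <- "double"
  structure(
    list(heights = heights, spacing = spacing, origin = as.numeric(origin),
         mask = mask, meta = meta),
    class = "heightmap"
  )
}

is_heightmap <- function(x) inherits(x, "heightmap")

assert_heightmap <- function(x) {
  if (!is_heightmap(x)) stop("expected a `heightmap` object")
  invisible(x)
}

#' @export
print.heightmap <- function(x, ...) {
  d <- dim(x$heights)
  cat(sprintf(
    "<heightmap> %d x %d cells @ %g mm (%.2f x %.2f mm), %d masked\n",
    d[1], d[2], x$spacing, (d[2] - 1) * x$spacing, (d[1] - 1) * x$spacing,
    sum(!x$mask)
  ))
  z <- hm_values(x)
  if (length(z)) {
    cat(sprintf("  z range [%.4g, %.4g] mm, Sq = %.4g mm\n",
                min(z), max(z), sqrt(mean(z^2))))
  }
  invisible(x)
}

#' @export
dim.heightmap <- function(x) dim(x$heights)

# x (column) coordinates in mm
hm_x <- function(map) map$origin[1] + (seq_len(ncol(map$heights)) - 1) * map$spacing

# y (row) coordinates in mm
hm_y <- function(map) map$origin[2] + (seq_len(nrow(map$heights)) - 1) * map$spacing

# valid heights as a vector
hm_values <- function(map) map$heights[map$mask]

# physical extent (x, y) in mm, node-to-node
hm_extent <- function(map) {
  d <- dim(map$heights)
  c((d[2] - 1) * map$spacing, (d[1] - 1) * map$spacing)
}

# projected area of the valid region, one cell per node (mm^2)
hm_area <- function(map) sum(map$mask) * map$spacing^2

# replace masked cells by the mean of valid cells (for FFT-based operators),
# after cropping fully-masked border rows/columns
hm_filled <- function(map) {
  m <- hm_trim(map)
  z <- m$heights
  if (any(!m$mask)) z[!m$mask] <- mean(z[m$mask])
  list(z = z, spacing = m$spacing)
}

# crop away border rows/columns that contain no valid cell
hm_trim <- function(map) {
  rows <- which(rowSums(map$mask) > 0)
  cols <- which(colSums(map$mask) > 0)
  if (length(rows) == 0L) stop("height map has no valid cells")
  r <- rows[1]:rows[length(rows)]
  c <- cols[1]:cols[length(cols)]
  if (length(r) == nrow(map$heights) && length(c) == ncol(map$heights)) {
    return(map)
  }
  height_map(map$heights[r, c, drop = FALSE], map$spacing,
             origin = c(map$origin[1] + (c[1] - 1) * map$spacing,
                        map$origin[2] + (r[1] - 1) * map$spacing),
             mask = map$mask[r, c, drop = FALSE], meta = map$meta)
}

# bilinear interpolation of heights at arbitrary (x, y) positions (mm);
# positions outside the grid return NA
hm_interp <- function(map, x, y) {
  gx <- (x - map$origin[1]) / map$spacing + 1
  gy <- (y - map$origin[2]) / map$spacing + 1
  nr <- nrow(map$heights); nc <- ncol(map$heights)
  j0 <- floor(gx); i0 <- floor(gy)
  tx <- gx - j0; ty <- gy - i0
  # clamp the upper edge so x == max(x) stays in range
  at_right <- j0 == nc & tx < 1e-9
  at_top <- i0 == nr & ty < 1e-9
  j0[at_right] <- nc - 1L; tx[at_right] <- 1
  i0[at_top] <- nr - 1L; ty[at_top] <- 1
  ok <- j0 >= 1 & j0 <= nc - 1 & i0 >= 1 & i0 <= nr - 1
  out <- rep(NA_real_, length(x))
  if (!any(ok)) return(out)
  i0k <- i0[ok]; j0k <- j0[ok]; txk <- tx[ok]; tyk <- ty[ok]
  z <- map$heights
  idx <- function(i, j) (j - 1L) * nr + i
  z00 <- z[idx(i0k, j0k)];     z01 <- z[idx(i0k, j0k + 1L)]
  z10 <- z[idx(i0k + 1L, j0k)]; z11 <- z[idx(i0k + 1L, j0k + 1L)]
  out[ok] <- (1 - tyk) * ((1 - txk) * z00 + txk * z01) +
    tyk * ((1 - txk) * z10 + txk * z11)
  out
}

# evaluate and restore RNG state, so generators are reproducible under seed
# without disturbing the caller's random stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}
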