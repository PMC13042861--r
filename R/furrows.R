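#' Angular power spectrum of surface texture
#'
#' 2-D FFT power integrated over radial frequency per angular bin (DC
#' excluded). Reported angles follow the groove convention: the direction of
#' the surface structures themselves (perpendicular to the spectral energy),
#' folded to [0, 180) degrees, and the binned power is normalised to sum 1.
#'
#' @param map a levelled [height_map()].
#' @param bin angular bin width, degrees.
#' @return A `direction_spectrum` object: `angles` (bin centres, degrees) and
#'   `power` (normalised).
#' @export
direction_spectrum <- function(map, bin = 1) {
  assert_heightmap(map)
  f <- hm_filled(map)
  z <- f$z - mean(f$z)
  n1 <- nrow(z); n2 <- ncol(z)
  P <- Mod(stats::fft(z))^2
  fy <- c(0:(n1 %/% 2), -((n1 - n1 %/% 2 - 1):1)) / (n1 * f$spacing)
  fx <- c(0:(n2 %/% 2), -((n2 - n2 %/% 2 - 1):1)) / (n2 * f$spacing)
  FY <- matrix(fy, n1, n2); FX <- matrix(fx, n1, n2, byrow = TRUE)
  keep <- !(FX == 0 & FY == 0)
  # spectral energy lies along the normal to the grooves: rotate 90 degrees
  ang <- (atan2(FY[keep], FX[keep]) * 180 / pi + 90) %% 180
  edges <- seq(0, 180, by = bin)
  centres <- edges[-length(edges)] + bin / 2
  idx <- pmin(length(centres), floor(ang / bin) + 1L)
  fidx <- factor(idx, levels = seq_along(centres))
  # mean power per bin: the number of frequency samples per angular bin is
  # uneven on a square grid, so sums would bias the diagonal directions
  pow <- as.vector(tapply(P[keep], fidx, sum, default = 0))
  cnt <- as.vector(tapply(P[keep], fidx, length, default = 0))
  pow <- ifelse(cnt > 0, pow / pmax(cnt, 1), 0)
  tot <- sum(pow)
  if (tot <= 0) pow <- rep(1 / length(pow), length(pow)) else pow <- pow / tot
  structure(list(angles = centres, power = pow, bin = bin),
            class = "direction_spectrum")
}

#' Texture isotropy and dominant directions
#'
#' First/Second/Third directions are the three highest non-adjacent local
#' maxima of the angular spectrum (minimum separation 5 degrees, circular on
#' the 180-degree axis). Isotropy = 100 x mean bin power / max bin power, so a
#' flat spectrum scores 100% and a single-line spectrum approaches 0%.
#'
#' @param spec a [direction_spectrum()].
#' @return List with `Isotropy` (%), `First`, `Second`, `Third` (degrees;
#'   `NA` flagged when fewer than three local maxima exist).
#' @export
texture_direction_params <- function(spec) {
  stopifnot(inherits(spec, "direction_spectrum"))
  a <- spec$angles
  n <- length(spec$power)
  # circular boxcar smoothing over ~5 degrees stabilises the maximum against
  # bin-level noise before the mean/max isotropy ratio is formed
  w <- max(1L, round(5 / spec$bin))
  if (w %% 2 == 0) w <- w + 1L
  half <- (w - 1L) %/% 2L
  p <- vapply(seq_len(n), function(i) {
    mean(spec$power[((i - half - 1L):(i + half - 1L)) %% n + 1L])
  }, numeric(1))
  iso <- 100 * mean(p) / max(p)
  # circular local maxima
  left <- p[c(n, seq_len(n - 1))]; right <- p[c(seq_len(n - 1) + 1, 1)]
  locmax <- which(p >= left & p >= right & p > 0)
  locmax <- locmax[order(p[locmax], decreasing = TRUE)]
  sep <- max(1, ceiling(5 / spec$bin))
  chosen <- integer(0)
  for (i in locmax) {
    if (length(chosen) == 3) break
    dist <- vapply(chosen, function(j) {
      d <- abs(i - j); min(d, n - d)
    }, numeric(1))
    if (all(dist > sep)) chosen <- c(chosen, i)
  }
  dirs <- c(a[chosen], rep(NA_real_, 3 - length(chosen)))
  list(Isotropy = iso, First = dirs[1], Second = dirs[2], Third = dirs[3],
       n_maxima = length(chosen))
}

#' Detect the furrow network
#'
#' Dales are segmented by watershed on the inverted surface with prominence
#' pruning; the furrow skeleton is the set of valley-line cells (cells that
#' are strict 1-D local minima along at least one grid axis) inside retained
#' dales, restricted to cells lying at least `min_depth_frac` of the pruning
#' threshold below their local rim. The depth at a skeleton cell is the local
#' rim height minus the cell height, where the local rim is the lower of the
#' two height maxima found within `rim_window` mm on either side of the cell
#' along the scan axis.
#'
#' @param map a levelled [height_map()].
#' @param pruning prominence pruning threshold, percent of Sz.
#' @param min_depth_frac minimum depth, as a fraction of the pruning
#'   threshold, for a valley cell to count as furrow.
#' @param seg optional precomputed [segment_features()] result for this map.
#' @param rim_window half-width of the local rim search, mm.
#' @return A `furrow_network` object: `cells` (data frame with row, col,
#'   depth), `total_length` (mm), `area` (mm^2).
#' @export
detect_furrows <- function(map, pruning = 5, min_depth_frac = 0.5,
                           seg = NULL, rim_window = 1) {
  assert_heightmap(map)
  f <- hm_filled(map)
  z <- f$z
  area <- length(z) * f$spacing^2
  empty <- structure(list(cells = data.frame(row = integer(0), col = integer(0),
                                             depth = numeric(0)),
                          total_length = 0, area = area, spacing = f$spacing),
                     class = "furrow_network")
  if (max(z) - min(z) < 1e-12) return(empty)
  if (is.null(seg)) seg <- segment_features(height_map(z, f$spacing),
                                            pruning = pruning)
  lab <- seg$dales
  if (is.null(seg$dale_table)) return(empty)
  nr <- nrow(z); nc <- ncol(z)
  # strict 1-D local minima along rows (x) or columns (y)
  minx <- matrix(FALSE, nr, nc)
  minx[, 2:(nc - 1)] <- z[, 2:(nc - 1)] < z[, 1:(nc - 2)] &
    z[, 2:(nc - 1)] < z[, 3:nc]
  miny <- matrix(FALSE, nr, nc)
  miny[2:(nr - 1), ] <- z[2:(nr - 1), ] < z[1:(nr - 2), ] &
    z[2:(nr - 1), ] < z[3:nr, ]
  valley <- (minx | miny) & lab > 0
  if (!any(valley)) return(empty)
  # local rims: running maxima over a window on each side, along each axis
  w <- max(2L, min(round(rim_window / f$spacing), nc - 1L, nr - 1L))
  shift_col <- function(m, k) {
    out <- matrix(-Inf, nr, nc)
    if (k > 0) out[, (k + 1):nc] <- m[, 1:(nc - k)]
    if (k < 0) out[, 1:(nc + k)] <- m[, (1 - k):nc]
    out
  }
  shift_row <- function(m, k) {
    out <- matrix(-Inf, nr, nc)
    if (k > 0) out[(k + 1):nr, ] <- m[1:(nr - k), ]
    if (k < 0) out[1:(nr + k), ] <- m[(1 - k):nr, ]
    out
  }
  maxL <- maxR <- maxU <- maxD <- matrix(-Inf, nr, nc)
  for (k in seq_len(w)) {
    maxL <- pmax(maxL, shift_col(z, k))
    maxR <- pmax(maxR, shift_col(z, -k))
    maxU <- pmax(maxU, shift_row(z, k))
    maxD <- pmax(maxD, shift_row(z, -k))
  }
  depth_x <- pmin(maxL, maxR) - z
  depth_y <- pmin(maxU, maxD) - z
  depth_all <- matrix(-Inf, nr, nc)
  depth_all[minx] <- depth_x[minx]
  depth_all[miny] <- pmax(depth_all[miny], depth_y[miny])
  cells <- which(valley)
  depth <- depth_all[cells]
  keep <- is.finite(depth) & depth >= min_depth_frac * seg$pruning_threshold
  cells <- cells[keep]; depth <- depth[keep]
  if (length(cells) == 0) return(empty)
  structure(list(
    cells = data.frame(row = ((cells - 1) %% nr) + 1,
                       col = ((cells - 1) %/% nr) + 1,
                       depth = depth),
    total_length = length(cells) * f$spacing,
    area = area, spacing = f$spacing
  ), class = "furrow_network")
}

#' Furrow summary parameters
#'
#' Maximum and mean furrow depth (mm) over skeleton cells, and furrow density
#' (total skeleton length per unit area) converted to cm/cm^2.
#'
#' @param net a [detect_furrows()] result.
#' @return List with `max_depth` (mm), `mean_depth` (mm), `mean_density`
#'   (cm/cm^2) and an `empty` flag.
#' @export
furrow_params <- function(net) {
  stopifnot(inherits(net, "furrow_network"))
  if (nrow(net$cells) == 0) {
    return(list(max_depth = 0, mean_depth = 0, mean_density = 0, empty = TRUE))
  }
  # mm/mm^2 -> cm/cm^2 is a factor of 10
  list(max_depth = max(net$cells$depth),
       mean_depth = mean(net$cells$depth),
       mean_density = net$total_length / net$area * 10,
       empty = FALSE)
}
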