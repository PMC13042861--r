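#' Root mean square height (Sq)
#'
#' RMS of heights over unmasked cells of a levelled map, in mm.
#'
#' @param map a levelled [height_map()].
#' @return Sq in mm, or `NA` with a `reason` attribute if no cells are valid.
#' @export
sq <- function(map) {
  assert_heightmap(map)
  z <- hm_values(map)
  if (length(z) == 0) return(missing_value("all cells masked"))
  sqrt(mean(z^2))
}

missing_value <- function(reason) structure(NA_real_, reason = reason)

#' Inverse areal material ratio (Smc)
#'
#' Height c at which the areal material ratio equals `p` percent: the height
#' exceeded by `p`% of the surface, from the Abbott-Firestone curve with
#' linear interpolation between sorted heights.
#'
#' @param map a levelled [height_map()].
#' @param p material ratio, percent (default 10).
#' @return Smc in mm.
#' @export
smc <- function(map, p = 10) {
  assert_heightmap(map)
  z <- hm_values(map)
  if (length(z) == 0) return(missing_value("all cells masked"))
  stats::quantile(z, 1 - p / 100, names = FALSE, type = 7)
}

# centred circular autocorrelation of the (mean-filled) height grid via FFT,
# normalised to 1 at zero lag
acf2d <- function(z) {
  z <- z - mean(z)
  n1 <- nrow(z); n2 <- ncol(z)
  F <- stats::fft(z)
  ac <- Re(stats::fft(F * Conj(F), inverse = TRUE)) / (n1 * n2)
  ac <- ac / ac[1, 1]
  # shift zero lag to the centre
  s1 <- n1 %/% 2; s2 <- n2 %/% 2
  ac[c((s1 + 1):n1, 1:s1), c((s2 + 1):n2, 1:s2)]
}

# brute-force circular autocorrelation (oracle for small grids)
acf2d_direct <- function(z) {
  z <- z - mean(z)
  n1 <- nrow(z); n2 <- ncol(z)
  out <- matrix(0, n1, n2)
  for (di in 0:(n1 - 1)) {
    for (dj in 0:(n2 - 1)) {
      zi <- z[((seq_len(n1) - 1 + di) %% n1) + 1,
              ((seq_len(n2) - 1 + dj) %% n2) + 1]
      out[di + 1, dj + 1] <- sum(z * zi)
    }
  }
  out <- out / out[1, 1]
  s1 <- n1 %/% 2; s2 <- n2 %/% 2
  out[c((s1 + 1):n1, 1:s1), c((s2 + 1):n2, 1:s2)]
}

#' Autocorrelation length (Sal) and texture aspect ratio (Str)
#'
#' From the FFT-based normalised areal autocorrelation: Sal is the shortest
#' radial lag at which the ACF first decays to `s`, over directions sampled
#' every 2 degrees; Str is Sal divided by the longest such lag. Directions
#' whose ACF never decays within the half-window are capped at the half-window
#' and flagged.
#'
#' @param map a levelled [height_map()].
#' @param s decay threshold (ISO default 0.2).
#' @return List with `Sal` (mm), `Str` (0, 1], and `capped` (logical).
#' @export
autocorrelation_params <- function(map, s = 0.2) {
  assert_heightmap(map)
  f <- hm_filled(map)
  z <- f$z; spacing <- f$spacing
  if (stats::sd(as.vector(z)) < 1e-14) {
    return(list(Sal = missing_value("flat surface"), Str = missing_value("flat surface"),
                capped = FALSE))
  }
  ac <- acf2d(z)
  n1 <- nrow(z); n2 <- ncol(z)
  c1 <- n1 %/% 2 + 1; c2 <- n2 %/% 2 + 1
  rmax <- (min(n1, n2) / 2 - 1) * spacing
  angles <- seq(0, 178, by = 2) * pi / 180
  radii <- seq(spacing / 2, rmax, by = spacing / 2)
  dec <- rep(NA_real_, length(angles))
  for (a in seq_along(angles)) {
    dx <- cos(angles[a]); dy <- sin(angles[a])
    gi <- c1 + radii * dy / spacing
    gj <- c2 + radii * dx / spacing
    # bilinear interpolation of the ACF along the ray
    i0 <- floor(gi); j0 <- floor(gj)
    ti <- gi - i0; tj <- gj - j0
    ok <- i0 >= 1 & i0 < n1 & j0 >= 1 & j0 < n2
    v <- rep(NA_real_, length(radii))
    idx <- function(i, j) (j - 1L) * n1 + i
    v[ok] <- (1 - ti[ok]) * ((1 - tj[ok]) * ac[idx(i0[ok], j0[ok])] +
                               tj[ok] * ac[idx(i0[ok], j0[ok] + 1L)]) +
      ti[ok] * ((1 - tj[ok]) * ac[idx(i0[ok] + 1L, j0[ok])] +
                  tj[ok] * ac[idx(i0[ok] + 1L, j0[ok] + 1L)])
    below <- which(v < s)
    if (length(below) > 0) {
      k <- below[1]
      if (k == 1) {
        # crossing between lag 0 (ACF = 1) and the first sample
        dec[a] <- radii[1] * (1 - s) / (1 - v[1])
      } else {
        dec[a] <- radii[k - 1] + (radii[k] - radii[k - 1]) *
          (v[k - 1] - s) / (v[k - 1] - v[k])
      }
    }
  }
  capped <- anyNA(dec)
  if (all(is.na(dec))) {
    return(list(Sal = missing_value("ACF never decays to threshold"),
                Str = missing_value("ACF never decays to threshold"),
                capped = TRUE))
  }
  dec[is.na(dec)] <- rmax
  list(Sal = min(dec), Str = min(dec) / max(dec), capped = capped)
}

# summed 3-D area of the two triangles per cell, plus projected area, over the
# valid (trimmed, filled) grid
surface_area <- function(z, spacing) {
  n1 <- nrow(z); n2 <- ncol(z)
  z00 <- z[-n1, -n2]; z10 <- z[-1, -n2]; z01 <- z[-n1, -1]; z11 <- z[-1, -1]
  h <- spacing
  # triangle (00,10,11) and (00,11,01)
  tri_area <- function(pa, pb, pc) {
    ux <- pb[[1]] - pa[[1]]; uy <- pb[[2]] - pa[[2]]; uz <- pb[[3]] - pa[[3]]
    vx <- pc[[1]] - pa[[1]]; vy <- pc[[2]] - pa[[2]]; vz <- pc[[3]] - pa[[3]]
    nx <- uy * vz - uz * vy; ny <- uz * vx - ux * vz; nz <- ux * vy - uy * vx
    0.5 * sqrt(nx^2 + ny^2 + nz^2)
  }
  a1 <- tri_area(list(0, 0, z00), list(0, h, z10), list(h, h, z11))
  a2 <- tri_area(list(0, 0, z00), list(h, h, z11), list(h, 0, z01))
  true_area <- sum(a1) + sum(a2)
  proj_area <- (n1 - 1) * (n2 - 1) * h^2
  c(true = true_area, projected = proj_area)
}

#' Developed interfacial area ratio (Sdr)
#'
#' (true triangulated surface area / projected area - 1) x 100, with each grid
#' cell split into two triangles.
#'
#' @param map a levelled [height_map()].
#' @return Sdr in percent.
#' @export
sdr <- function(map) {
  assert_heightmap(map)
  f <- hm_filled(map)
  a <- surface_area(f$z, f$spacing)
  (a[["true"]] / a[["projected"]] - 1) * 100
}

#' Dale void volume (Vvv)
#'
#' Void volume below the height at `p`% areal material ratio, per unit
#' projected area (mm^3/mm^2), by integrating the material-ratio curve.
#'
#' @param map a levelled [height_map()].
#' @param p material ratio, percent (default 80).
#' @return Vvv in mm^3/mm^2.
#' @export
vvv <- function(map, p = 80) {
  assert_heightmap(map)
  z <- hm_values(map)
  if (length(z) == 0) return(missing_value("all cells masked"))
  cp <- stats::quantile(z, 1 - p / 100, names = FALSE, type = 7)
  mean(pmax(0, cp - z))
}

#' Watershed segmentation of hills and dales
#'
#' Watershed on the surface (hills) and on the inverted surface (dales), with
#' prominence pruning: features whose height above the point of contact with a
#' neighbouring feature is below `pruning`% of Sz (the total height range) are
#' merged, following the Wolf pruning convention.
#'
#' @param map a levelled [height_map()].
#' @param pruning pruning threshold as percent of Sz (default 5).
#' @return A `feature_segmentation` object: integer label matrices `hills` and
#'   `dales`, per-feature tables `hill_table` / `dale_table` (label, peak/pit
#'   row, col, height, prominence), and the pruning threshold in mm.
#' @export
segment_features <- function(map, pruning = 5) {
  assert_heightmap(map)
  f <- hm_filled(map)
  z <- f$z
  sz <- max(z) - min(z)
  empty <- list(hills = matrix(0L, nrow(z), ncol(z)),
                dales = matrix(0L, nrow(z), ncol(z)),
                hill_table = NULL, dale_table = NULL,
                pruning_threshold = 0, spacing = f$spacing)
  if (sz < 1e-12) return(structure(empty, class = "feature_segmentation"))
  thr <- pruning / 100 * sz
  seg_one <- function(relief) {
    # relief: higher = feature interior; strictly positive for EBImage
    lab <- EBImage::watershed(relief - min(relief) + 1e-9, tolerance = thr,
                              ext = 1)
    lab <- matrix(as.integer(lab), nrow(relief), ncol(relief))
    labs <- sort(unique(lab[lab > 0]))
    tab <- lapply(labs, function(l) {
      cells <- which(lab == l)
      top <- cells[which.max(relief[cells])]
      data.frame(label = l,
                 row = ((top - 1) %% nrow(relief)) + 1,
                 col = ((top - 1) %/% nrow(relief)) + 1,
                 relief = max(relief[cells]),
                 prominence = max(relief[cells]) - min(relief[cells]))
    })
    list(labels = lab, table = do.call(rbind, tab))
  }
  hills <- seg_one(z)
  dales <- seg_one(-z)
  ht <- hills$table; dt <- dales$table
  if (!is.null(ht)) ht$height <- ht$relief
  if (!is.null(dt)) dt$depth <- dt$relief
  structure(list(hills = hills$labels, dales = dales$labels,
                 hill_table = ht, dale_table = dt,
                 pruning_threshold = thr, spacing = f$spacing,
                 heights = z),
            class = "feature_segmentation")
}

# arithmetic mean principal curvature at (row, col) from a local quadratic
# fit on the 3x3 neighbourhood: -(z_xx + z_yy)/2 (1/mm, positive for peaks)
peak_curvature <- function(z, row, col, spacing) {
  nr <- nrow(z); nc <- ncol(z)
  if (row < 2 || row > nr - 1 || col < 2 || col > nc - 1) return(NA_real_)
  zxx <- (z[row, col - 1] - 2 * z[row, col] + z[row, col + 1]) / spacing^2
  zyy <- (z[row - 1, col] - 2 * z[row, col] + z[row + 1, col]) / spacing^2
  -(zxx + zyy) / 2
}

# isoperimetric roundness (4 pi A / P^2) of the half-prominence contour
# around a feature top; NA when the contour is open or cannot be traced
feature_roundness <- function(z, spacing, row, col, level) {
  x <- (seq_len(ncol(z)) - 1) * spacing
  y <- (seq_len(nrow(z)) - 1) * spacing
  # contourLines expects z[x, y]: transpose so first index runs along x
  cl <- grDevices::contourLines(x, y, t(z), levels = level)
  if (length(cl) == 0) return(NA_real_)
  px <- (col - 1) * spacing; py <- (row - 1) * spacing
  for (cc in cl) {
    n <- length(cc$x)
    closed <- abs(cc$x[1] - cc$x[n]) < 1e-12 && abs(cc$y[1] - cc$y[n]) < 1e-12
    if (!closed) next
    if (!point_in_polygon(px, py, cc$x, cc$y)) next
    A <- abs(polygon_area(cc$x, cc$y))
    P <- sum(sqrt(diff(cc$x)^2 + diff(cc$y)^2))
    if (P <= 0) next
    return(4 * pi * A / P^2)
  }
  NA_real_
}

polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

point_in_polygon <- function(px, py, x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  crossing <- ((y > py) != (y[j] > py)) &
    (px < (x[j] - x) * (py - y) / (y[j] - y) + x)
  sum(crossing) %% 2 == 1
}

#' Feature parameters from a segmentation
#'
#' Spd = retained peaks per unit area (1/mm^2); Spc = arithmetic mean peak
#' curvature over retained peaks (1/mm) from 3x3 quadratic fits; Svd = density
#' of pits (1/mm^2); hill/dale roundness = isoperimetric ratio 4*pi*A/P^2 of
#' each feature's half-prominence contour, with Shrn/Sdrn the means and
#' Shrnq/Sdrnq the standard deviations.
#'
#' @param seg a [segment_features()] result.
#' @param map the [height_map()] the segmentation came from.
#' @return Named list with Spd, Spc, Svd, Shrn, Shrnq, Sdrn, Sdrnq and a
#'   `no_features` flag.
#' @export
feature_params <- function(seg, map) {
  stopifnot(inherits(seg, "feature_segmentation"))
  area <- hm_area(map)
  z <- seg$heights
  zero <- list(Spd = 0, Spc = 0, Svd = 0, Shrn = 0, Shrnq = 0,
               Sdrn = 0, Sdrnq = 0, no_features = TRUE)
  if (is.null(seg$hill_table) && is.null(seg$dale_table)) return(zero)
  res <- zero
  res$no_features <- FALSE
  if (!is.null(seg$hill_table)) {
    ht <- seg$hill_table
    res$Spd <- nrow(ht) / area
    cur <- mapply(function(r, c) peak_curvature(z, r, c, seg$spacing),
                  ht$row, ht$col)
    res$Spc <- mean(cur, na.rm = TRUE)
    rnd <- mapply(function(r, c, h, p) {
      feature_roundness(z, seg$spacing, r, c, h - p / 2)
    }, ht$row, ht$col, ht$height, ht$prominence)
    rnd <- rnd[is.finite(rnd)]
    res$Shrn <- if (length(rnd)) mean(rnd) else 0
    res$Shrnq <- if (length(rnd) > 1) stats::sd(rnd) else 0
  }
  if (!is.null(seg$dale_table)) {
    dt <- seg$dale_table
    res$Svd <- nrow(dt) / area
    rnd <- mapply(function(r, c, d, p) {
      feature_roundness(-z, seg$spacing, r, c, d - p / 2)
    }, dt$row, dt$col, dt$depth, dt$prominence)
    rnd <- rnd[is.finite(rnd)]
    res$Sdrn <- if (length(rnd)) mean(rnd) else 0
    res$Sdrnq <- if (length(rnd) > 1) stats::sd(rnd) else 0
  }
  if (!is.finite(res$Spc)) res$Spc <- 0
  res
}

#' Texture direction (Std)
#'
#' Orientation of maximal angular power in the Fourier spectrum (DC excluded),
#' folded to [0, 180) degrees; delegates to [direction_spectrum()]. Flagged
#' unstable when no angular bin dominates (maximum bin power below three times
#' the median bin power), as on nearly isotropic surfaces.
#'
#' @param map a levelled [height_map()].
#' @param bin angular bin width, degrees.
#' @return Std in degrees with attribute `unstable`.
#' @export
std_direction <- function(map, bin = 1) {
  spec <- direction_spectrum(map, bin = bin)
  pars <- texture_direction_params(spec)
  out <- pars$First
  attr(out, "unstable") <- max(spec$power) < 3 * stats::median(spec$power)
  out
}
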