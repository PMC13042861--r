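#' Relative-area curve (scale-sensitive fractal analysis)
#'
#' At each observation scale the surface is tiled by virtual triangles whose
#' legs span the scale; the relative area is the summed true triangle area
#' divided by the projected area. The scale is expressed as the nominal
#' triangle-pair footprint (leg length squared) in square micrometres. At the
#' coarsest useful scales the relative area approaches 1, and it grows as the
#' scale shrinks towards the sampling limit.
#'
#' @param map a levelled [height_map()].
#' @param scales optional vector of scales in um^2; defaults to 16
#'   logarithmically spaced scales between (2 x spacing)^2 and (extent / 2)^2.
#' @return A `relative_area_curve` object: `scales` (um^2, ascending) and
#'   `relative_area` (>= 1).
#' @export
relative_area_curve <- function(map, scales = NULL) {
  assert_heightmap(map)
  f <- hm_filled(map)
  z <- f$z; spacing <- f$spacing
  n <- min(dim(z))
  if (is.null(scales)) {
    lmin <- 2 * spacing
    # coarsest default scale extent/3: beyond that too few virtual triangles
    # remain for a stable estimate
    lmax <- (n - 1) * spacing / 3
    if (lmax <= lmin) lmax <- (n - 1) * spacing
    lengths <- exp(seq(log(lmin), log(lmax), length.out = 16))
    strides <- sort(unique(pmax(1L, as.integer(round(lengths / spacing)))))
  } else {
    strides <- sort(unique(pmax(1L, as.integer(round(sqrt(scales) / 1000 / spacing)))))
  }
  strides <- strides[strides <= (n - 1) %/% 1]
  strides <- strides[strides >= 1]
  if (length(strides) < 4) stop("fewer than 4 usable scales for this grid")
  ra <- vapply(strides, function(k) {
    # average over grid phase offsets: at coarse strides a single subgrid
    # carries few triangles and the estimate would be noisy
    offs <- unique(round(seq(0, k - 1, length.out = min(k, 4L))))
    vals <- c()
    for (o1 in offs) {
      for (o2 in offs) {
        idx1 <- seq(1 + o1, nrow(z), by = k)
        idx2 <- seq(1 + o2, ncol(z), by = k)
        if (length(idx1) < 2 || length(idx2) < 2) next
        a <- surface_area(z[idx1, idx2, drop = FALSE], spacing * k)
        vals <- c(vals, a[["true"]] / a[["projected"]])
      }
    }
    if (length(vals) == 0) NA_real_ else mean(vals)
  }, numeric(1))
  ok <- is.finite(ra)
  ra <- ra[ok]
  # isotonic projection: the relative area of a surface is non-increasing in
  # scale; residual estimator noise at the coarsest scales (few triangles) is
  # removed by a running minimum from fine to coarse
  ra <- cummin(ra)
  structure(list(scales = (strides[ok] * spacing * 1000)^2,
                 relative_area = ra),
            class = "relative_area_curve")
}

#' Fractal complexity and related SSFA parameters
#'
#' From the log-log relative-area curve: `Asfc` is -1000 times the steepest
#' negative slope among the piecewise segments of log(relative area) versus
#' log(scale); `Smfc` is the (geometric mid-) scale at which that steepest
#' slope occurs, in um^2; `Das` is the fractal dimension estimated from the
#' regression slope over the fine-scale regime (D = 2 - 2 x slope, finest five
#' scales); `Ymax` is the maximum relative area.
#'
#' @param curve a [relative_area_curve()].
#' @return List with `Asfc`, `Smfc` (um^2; `NA` flagged when the curve is
#'   flat), `Das`, `Ymax`.
#' @export
asfc <- function(curve) {
  stopifnot(inherits(curve, "relative_area_curve"))
  s <- curve$scales; ra <- curve$relative_area
  ymax <- max(ra)
  if (diff(range(ra)) < 1e-12) {
    return(list(Asfc = 0, Smfc = missing_value("flat relative-area curve"),
                Das = 2, Ymax = ymax))
  }
  ls <- log(s); lr <- log(ra)
  slopes <- diff(lr) / diff(ls)
  k <- which.min(slopes)
  asfc_val <- -1000 * min(slopes[k], 0)
  smfc <- sqrt(s[k] * s[k + 1])
  nf <- min(5L, length(s))
  fit <- stats::lm.fit(cbind(1, ls[seq_len(nf)]), lr[seq_len(nf)])
  das <- 2 - 2 * fit$coefficients[2]
  list(Asfc = asfc_val, Smfc = smfc, Das = unname(das), Ymax = ymax)
}

#' Heterogeneity of fractal complexity (3 x 3)
#'
#' Asfc is computed independently in each block of a 3 x 3 partition of the
#' map. `MedianAsfc` is the median of the block values and `HAsfc` their
#' median absolute deviation divided by their median (0 when the median is 0).
#'
#' @param map a levelled [height_map()].
#' @param grid blocks per side (default 3).
#' @return List with `HAsfc`, `MedianAsfc` and the per-block values.
#' @export
hasfc_grid <- function(map, grid = 3) {
  assert_heightmap(map)
  f <- hm_filled(map)
  z <- f$z
  nr <- nrow(z); nc <- ncol(z)
  if (nr %/% grid < 4 || nc %/% grid < 4) {
    stop("map cannot be divided into a ", grid, "x", grid,
         " grid with >= 16 cells per block")
  }
  rb <- floor(seq(0, nr, length.out = grid + 1))
  cb <- floor(seq(0, nc, length.out = grid + 1))
  vals <- c()
  for (i in seq_len(grid)) {
    for (j in seq_len(grid)) {
      blk <- z[(rb[i] + 1):rb[i + 1], (cb[j] + 1):cb[j + 1], drop = FALSE]
      sub <- height_map(blk, f$spacing)
      a <- tryCatch(asfc(relative_area_curve(sub))$Asfc, error = function(e) NA)
      vals <- c(vals, a)
    }
  }
  vals <- vals[is.finite(vals)]
  med <- stats::median(vals)
  h <- if (med == 0) 0 else stats::mad(vals, constant = 1) / med
  list(HAsfc = h, MedianAsfc = med, block_asfc = vals)
}

# mean relative length of profiles across the map at a given angle (radians)
# and segment scale (mm), via bilinear interpolation along parallel transects
relative_length_at <- function(map, theta, scale_mm, n_lines = 15) {
  ext <- hm_extent(map)
  cx <- map$origin[1] + ext[1] / 2; cy <- map$origin[2] + ext[2] / 2
  d <- c(cos(theta), sin(theta))
  perp <- c(-d[2], d[1])
  # half-length of the chord through an offset point, within the bounding box
  half <- min(ext) / 2 * 0.95
  offs <- seq(-0.4, 0.4, length.out = n_lines) * min(ext)
  rl <- vapply(offs, function(o) {
    p0 <- c(cx, cy) + o * perp
    t <- seq(-half, half, by = scale_mm)
    xs <- p0[1] + t * d[1]; ys <- p0[2] + t * d[2]
    ok <- xs >= map$origin[1] & xs <= map$origin[1] + ext[1] &
      ys >= map$origin[2] & ys <= map$origin[2] + ext[2]
    if (sum(ok) < 3) return(NA_real_)
    zs <- hm_interp(map, xs[ok], ys[ok])
    dz <- diff(zs)
    sum(sqrt(scale_mm^2 + dz^2)) / (length(dz) * scale_mm)
  }, numeric(1))
  mean(rl, na.rm = TRUE)
}

#' Length-scale anisotropy of relief (epLsar)
#'
#' For each orientation bin (0 to 175 degrees in `step`-degree increments) the
#' mean relative length of transect profiles at the given scale is computed;
#' the normalised rose of relative lengths is summarised by the length of its
#' mean vector with angles doubled (axial data). `NewEplsar` is the same
#' statistic computed on log-transformed relative lengths.
#'
#' @param map a levelled [height_map()].
#' @param scale observation scale in um (default 40); the sample spacing must
#'   not exceed half the scale.
#' @param step angular step in degrees (default 5).
#' @return List with `epLsar`, `NewEplsar` and the rose (`angles`, `rel_length`).
#' @export
eplsar <- function(map, scale = 40, step = 5) {
  assert_heightmap(map)
  scale_mm <- scale / 1000
  if (map$spacing > scale_mm / 2) {
    stop(sprintf("grid too coarse for a %g um scale (spacing %g mm)",
                 scale, map$spacing))
  }
  angles <- seq(0, 180 - step, by = step)
  rl <- vapply(angles * pi / 180, function(th) {
    relative_length_at(map, th, scale_mm)
  }, numeric(1))
  mean_vec <- function(w) {
    p <- w / sum(w)
    v <- sum(p * exp(2i * angles * pi / 180))
    Mod(v)
  }
  list(epLsar = mean_vec(rl), NewEplsar = mean_vec(pmax(log(rl), 1e-12)),
       angles = angles, rel_length = rl)
}
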