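#' Engraving cross-section trace
#'
#' An open 2-D polyline (x, z) in mm with strictly increasing x and at least
#' 20 points.
#'
#' @param x,z numeric vectors, mm.
#' @param spacing nominal sample step, mm; inferred from `x` when `NULL`.
#' @param meta provenance list.
#' @return A `profile_trace` object.
#' @export
profile_trace <- function(x, z, spacing = NULL, meta = list()) {
  stopifnot(length(x) == length(z), length(x) >= 20)
  if (any(diff(x) <= 0)) stop("profile x coordinates must be strictly increasing")
  if (is.null(spacing)) spacing <- stats::median(diff(x))
  structure(list(points = data.frame(x = x, z = z), spacing = spacing,
                 meta = meta),
            class = "profile_trace")
}

#' @export
print.profile_trace <- function(x, ...) {
  p <- x$points
  cat(sprintf("<profile_trace> %d points, x [%g, %g] mm, z [%g, %g] mm\n",
              nrow(p), min(p$x), max(p$x), min(p$z), max(p$z)))
  invisible(x)
}

#' Extract a cross-section profile from a height map
#'
#' Bilinear interpolation of heights along the straight section line from `p0`
#' to `p1`, sampled at the map spacing.
#'
#' @param map a [height_map()].
#' @param p0,p1 length-2 numeric (x, y) endpoints in mm.
#' @return A [profile_trace()]; x is the distance along the section line.
#' @export
extract_profile <- function(map, p0, p1) {
  assert_heightmap(map)
  len <- sqrt(sum((p1 - p0)^2))
  n <- max(21, floor(len / map$spacing) + 1)
  t <- seq(0, len, length.out = n)
  xs <- p0[1] + t / len * (p1[1] - p0[1])
  ys <- p0[2] + t / len * (p1[2] - p0[2])
  zs <- hm_interp(map, xs, ys)
  if (anyNA(zs)) stop("section line exits the valid region of the map")
  profile_trace(t, zs, spacing = map$spacing,
                meta = list(p0 = p0, p1 = p1))
}

#' Detect landmarks of an incision profile
#'
#' The apex is the global minimum (tie-break on flat-bottomed profiles: the
#' midpoint of the minimal plateau); the shoulders are the nearest crossings
#' of the reference surface level on each side of the apex; LDC/RDC are the
#' wall points at a configurable depth fraction. When a second trough reaches
#' more than half the main depth the profile is flagged as lacking a single
#' dominant trough.
#'
#' @param trace a [profile_trace()].
#' @param reference_z reference surface level, mm.
#' @param dc_fraction depth fraction for the depth-convergent landmarks.
#' @return A `profile_landmarks` object with indices `left_shoulder`, `apex`,
#'   `right_shoulder`, interpolated shoulder abscissae, LDC/RDC points, and
#'   flags.
#' @export
detect_landmarks <- function(trace, reference_z = 0, dc_fraction = 0.9) {
  stopifnot(inherits(trace, "profile_trace"))
  x <- trace$points$x; z <- trace$points$z
  n <- length(z)
  zmin <- min(z)
  depth <- reference_z - zmin
  tol <- max(1e-9, 1e-6 * max(abs(depth), 1))
  # minimal plateau containing the global minimum
  low <- which(z <= zmin + tol)
  amin <- which.min(z)
  runs <- split(low, cumsum(c(1, diff(low) != 1)))
  plateau <- runs[[which(vapply(runs, function(r) amin %in% r, logical(1)))]]
  apex <- plateau[ceiling(length(plateau) / 2)]
  # shoulder crossings of the reference level
  cross_x <- function(i, j) {
    # linear interpolation between samples i (below) and j (at/above)
    x[i] + (x[j] - x[i]) * (reference_z - z[i]) / (z[j] - z[i])
  }
  ls <- NA_integer_; ls_x <- x[1]; flag_left <- TRUE
  for (i in seq(apex, 2, by = -1)) {
    if (z[i - 1] >= reference_z - tol && z[i] < reference_z) {
      ls <- i - 1L
      ls_x <- if (z[i - 1] > reference_z) cross_x(i, i - 1L) else x[i - 1L]
      flag_left <- FALSE
      break
    }
  }
  if (is.na(ls)) ls <- 1L
  rs <- NA_integer_; rs_x <- x[n]; flag_right <- TRUE
  for (i in seq(apex, n - 1)) {
    if (z[i + 1] >= reference_z - tol && z[i] < reference_z) {
      rs <- i + 1L
      rs_x <- if (z[i + 1] > reference_z) cross_x(i, i + 1L) else x[i + 1L]
      flag_right <- FALSE
      break
    }
  }
  if (is.na(rs)) rs <- n
  # dominance of the main trough: depth of the deepest trough outside the
  # shoulder-to-shoulder span of the main one
  zz <- z
  zz[ls:rs] <- reference_z
  locmin <- which(diff(sign(diff(zz))) > 0) + 1
  sec_depth <- if (length(locmin)) max(reference_z - zz[locmin]) else 0
  dominance <- if (sec_depth > 1e-12) depth / sec_depth else Inf
  # depth-convergent wall points at dc_fraction of the depth
  target <- reference_z - dc_fraction * depth
  wall_point <- function(side) {
    idx <- if (side == "left") seq(apex, max(1, ls)) else seq(apex, min(n, rs))
    for (k in seq_along(idx)[-1]) {
      i0 <- idx[k - 1]; i1 <- idx[k]
      if ((z[i0] - target) * (z[i1] - target) <= 0 && z[i1] != z[i0]) {
        xx <- x[i0] + (x[i1] - x[i0]) * (target - z[i0]) / (z[i1] - z[i0])
        return(c(x = xx, z = target))
      }
    }
    c(x = x[apex], z = z[apex])
  }
  structure(list(left_shoulder = ls, apex = apex, right_shoulder = rs,
                 left_shoulder_x = ls_x, right_shoulder_x = rs_x,
                 LDC = wall_point("left"), RDC = wall_point("right"),
                 reference_z = reference_z, depth = depth,
                 flags = c(no_left_crossing = flag_left,
                           no_right_crossing = flag_right,
                           multi_trough = is.finite(dominance) && dominance < 2)),
            class = "profile_landmarks")
}

# x position on a wall at depth fraction `frac`, walking from the apex
wall_x_at <- function(x, z, apex, bound, reference_z, depth, frac) {
  target <- reference_z - frac * depth
  idx <- if (bound < apex) seq(apex, bound) else seq(apex, bound)
  for (k in seq_along(idx)[-1]) {
    i0 <- idx[k - 1]; i1 <- idx[k]
    if ((z[i0] - target) * (z[i1] - target) <= 0 && z[i1] != z[i0]) {
      return(x[i0] + (x[i1] - x[i0]) * (target - z[i0]) / (z[i1] - z[i0]))
    }
  }
  NA_real_
}

#' Measure an incision profile
#'
#' D = depth below the reference level at the apex; WIS = width of the
#' incision at the surface (between the interpolated shoulder crossings);
#' theta = opening angle at the apex between the apex-to-shoulder vectors; A =
#' wall asymmetry: the mean, over 20 evenly spaced depth fractions, of the
#' horizontal distance between the left wall reflected about the vertical
#' through the apex and the right wall (mm).
#'
#' @param trace a [profile_trace()].
#' @param lm a [detect_landmarks()] result.
#' @return An `engraving_measurements` list with D, WIS (mm), theta (degrees),
#'   A (mm) and a `shallow` flag (D < 3 x spacing).
#' @export
measure_profile <- function(trace, lm) {
  stopifnot(inherits(trace, "profile_trace"), inherits(lm, "profile_landmarks"))
  x <- trace$points$x; z <- trace$points$z
  D <- lm$depth
  WIS <- lm$right_shoulder_x - lm$left_shoulder_x
  va <- c(lm$left_shoulder_x - x[lm$apex], lm$reference_z - z[lm$apex])
  vb <- c(lm$right_shoulder_x - x[lm$apex], lm$reference_z - z[lm$apex])
  ct <- sum(va * vb) / (sqrt(sum(va^2)) * sqrt(sum(vb^2)))
  theta <- acos(pmin(1, pmax(-1, ct))) * 180 / pi
  fracs <- seq(0.05, 0.95, length.out = 20)
  ax <- x[lm$apex]
  dl <- vapply(fracs, function(f) {
    xl <- wall_x_at(x, z, lm$apex, lm$left_shoulder, lm$reference_z, D, f)
    xr <- wall_x_at(x, z, lm$apex, lm$right_shoulder, lm$reference_z, D, f)
    if (is.na(xl) || is.na(xr)) return(NA_real_)
    abs((2 * ax - xl) - xr)
  }, numeric(1))
  structure(list(D = D, WIS = WIS, theta = theta, A = mean(dl, na.rm = TRUE),
                 shallow = D < 3 * trace$spacing),
            class = "engraving_measurements")
}

#' Close an incision outline for Fourier analysis
#'
#' The outline is the wall polyline from the left shoulder through the apex to
#' the right shoulder, closed by the straight segment between the shoulders,
#' traversed counter-clockwise starting at the left shoulder, and resampled to
#' `n` points equally spaced along the perimeter.
#'
#' @param trace a [profile_trace()].
#' @param lm a [detect_landmarks()] result.
#' @param n number of resampled points (default 256).
#' @return An `n` x 2 matrix of (x, z) outline points.
#' @export
close_outline <- function(trace, lm, n = 256) {
  stopifnot(inherits(trace, "profile_trace"), inherits(lm, "profile_landmarks"))
  x <- trace$points$x; z <- trace$points$z
  idx <- seq(lm$left_shoulder, lm$right_shoulder)
  px <- c(lm$left_shoulder_x, x[idx[-c(1, length(idx))]], lm$right_shoulder_x)
  pz <- c(lm$reference_z, z[idx[-c(1, length(idx))]], lm$reference_z)
  # interior points at or above the closing segment would self-intersect
  if (any(pz[-c(1, length(pz))] >= lm$reference_z)) {
    stop("outline self-intersects: wall points reach the closing segment")
  }
  poly_x <- c(px, px[1]); poly_z <- c(pz, pz[1])  # closing edge back to start
  seg <- sqrt(diff(poly_x)^2 + diff(poly_z)^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  t <- total * (0:(n - 1)) / n
  ox <- stats::approx(s, poly_x, xout = t)$y
  oz <- stats::approx(s, poly_z, xout = t)$y
  out <- cbind(x = ox, z = oz)
  if (polygon_area(out[, 1], out[, 2]) < 0) out <- out[c(1, n:2), ]
  out
}

#' Elliptic Fourier analysis of a closed outline
#'
#' Standard elliptic Fourier decomposition (four coefficients a, b, c, d per
#' harmonic) of a closed outline, with per-harmonic power
#' (a^2 + b^2 + c^2 + d^2) / 2.
#'
#' @param outline n x 2 matrix of outline points (closed implicitly).
#' @param h number of harmonics (>= 1).
#' @param timing `"arc"` (default) parameterises the contour by arc length;
#'   `"vertex"` treats successive vertices as equal parameter steps, which is
#'   the parameterisation in which a parametrically sampled ellipse is exactly
#'   one harmonic. The two coincide for outlines resampled at equal arc
#'   spacing, as produced by [close_outline()].
#' @return An `outline_efa` object: `coefficients` (h x 4 matrix with columns
#'   a, b, c, d), `offset` (A0, C0), `power`, `centroid_size`, `normalized`.
#' @export
efa <- function(outline, h = 6, timing = c("arc", "vertex")) {
  if (h < 1) stop("at least one harmonic is required")
  timing <- match.arg(timing)
  outline <- as.matrix(outline)
  x <- outline[, 1]; y <- outline[, 2]
  n <- length(x)
  dx <- diff(c(x, x[1])); dy <- diff(c(y, y[1]))
  dt <- if (timing == "arc") sqrt(dx^2 + dy^2) else rep(1, n)
  keep <- dt > 0
  if (!any(keep)) stop("degenerate outline: zero perimeter")
  dx <- dx[keep]; dy <- dy[keep]; dt <- dt[keep]
  t1 <- cumsum(dt); t0 <- c(0, t1[-length(t1)])
  T <- t1[length(t1)]
  coefs <- matrix(0, h, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  for (k in seq_len(h)) {
    w <- 2 * pi * k / T
    cs <- cos(w * t1) - cos(w * t0)
    sn <- sin(w * t1) - sin(w * t0)
    f <- T / (2 * pi^2 * k^2)
    coefs[k, "a"] <- f * sum(dx / dt * cs)
    coefs[k, "b"] <- f * sum(dx / dt * sn)
    coefs[k, "c"] <- f * sum(dy / dt * cs)
    coefs[k, "d"] <- f * sum(dy / dt * sn)
  }
  # arc-weighted offset (A0, C0) of the piecewise-linear contour
  xk <- x[keep]; yk <- y[keep]
  xn <- c(x[-1], x[1])[keep]; yn <- c(y[-1], y[1])[keep]
  ctr <- c(sum((xk + xn) / 2 * dt), sum((yk + yn) / 2 * dt)) / T
  csize <- sqrt(mean((x - mean(x))^2 + (y - mean(y))^2))
  structure(list(coefficients = coefs, offset = ctr,
                 power = rowSums(coefs^2) / 2,
                 centroid_size = csize, normalized = FALSE, h = h),
            class = "outline_efa")
}

#' Reconstruct an outline from EFA coefficients
#'
#' @param e an [efa()] result.
#' @param n number of reconstruction points.
#' @return n x 2 matrix of points.
#' @export
efa_reconstruct <- function(e, n = 256) {
  stopifnot(inherits(e, "outline_efa"))
  t <- 2 * pi * (0:(n - 1)) / n
  x <- rep(e$offset[1], n); y <- rep(e$offset[2], n)
  for (k in seq_len(e$h)) {
    x <- x + e$coefficients[k, "a"] * cos(k * t) + e$coefficients[k, "b"] * sin(k * t)
    y <- y + e$coefficients[k, "c"] * cos(k * t) + e$coefficients[k, "d"] * sin(k * t)
  }
  cbind(x = x, y = y)
}

# rotate EFA coefficients: starting-point shift by theta and spatial rotation
# by psi (radians)
efa_transform <- function(coefs, theta = 0, psi = 0) {
  h <- nrow(coefs)
  out <- coefs
  for (k in seq_len(h)) {
    m <- matrix(coefs[k, ], 2, 2, byrow = TRUE)  # [a b; c d]
    S <- matrix(c(cos(k * theta), -sin(k * theta),
                  sin(k * theta), cos(k * theta)), 2, 2, byrow = TRUE)
    R <- matrix(c(cos(psi), sin(psi), -sin(psi), cos(psi)), 2, 2, byrow = TRUE)
    m2 <- R %*% m %*% S
    out[k, ] <- c(m2[1, 1], m2[1, 2], m2[2, 1], m2[2, 2])
  }
  out
}

#' Normalize EFA coefficients to shape space
#'
#' Size, rotation and starting phase are standardised using the first
#' harmonic: the starting point is shifted to the semi-major axis of the first
#' harmonic ellipse, the outline rotated so that axis lies along +x, and all
#' coefficients divided by the semi-major length. After normalization the
#' first-harmonic a, b and c are fixed (1, 0, 0), leaving (4 x h) - 3 shape
#' variables: d1 and the four coefficients of every higher harmonic.
#'
#' @param e an unnormalized [efa()] result.
#' @return The normalized `outline_efa`, with `shape_variables` attached.
#' @export
normalize_efa <- function(e) {
  stopifnot(inherits(e, "outline_efa"))
  if (e$normalized) return(e)
  cf <- e$coefficients
  a1 <- cf[1, "a"]; b1 <- cf[1, "b"]; c1 <- cf[1, "c"]; d1 <- cf[1, "d"]
  if (a1^2 + b1^2 + c1^2 + d1^2 < 1e-20) {
    stop("degenerate first harmonic: cannot normalize")
  }
  theta <- 0.5 * atan2(2 * (a1 * b1 + c1 * d1), a1^2 + c1^2 - b1^2 - d1^2)
  # pick the semi-major (not semi-minor) axis
  len_at <- function(th) {
    (a1 * cos(th) + b1 * sin(th))^2 + (c1 * cos(th) + d1 * sin(th))^2
  }
  if (len_at(theta + pi / 2) > len_at(theta)) theta <- theta + pi / 2
  # the starting point can sit at either end of the semi-major axis; both
  # candidates are computed and a canonical one chosen so that normalization
  # does not depend on the input starting point
  candidate <- function(th) {
    cf1 <- efa_transform(cf, theta = th)
    psi <- atan2(cf1[1, "c"], cf1[1, "a"])
    cf2 <- efa_transform(cf1, psi = psi)
    cf2 / cf2[1, "a"]
  }
  c1m <- candidate(theta)
  c2m <- candidate(theta + pi)
  pick_first <- TRUE
  for (i in seq_along(c1m)) {
    if (abs(c1m[i] - c2m[i]) > 1e-9) { pick_first <- c1m[i] > c2m[i]; break }
  }
  cf2 <- if (pick_first) c1m else c2m
  scale <- 1
  out <- e
  out$coefficients <- cf2
  out$power <- rowSums(cf2^2) / 2
  out$normalized <- TRUE
  sv <- c(cf2[1, "d"], as.vector(t(cf2[-1, , drop = FALSE])))
  names(sv) <- c("d1", paste0(rep(c("a", "b", "c", "d"), e$h - 1),
                              rep(seq_len(e$h)[-1], each = 4)))
  out$shape_variables <- sv
  out
}

#' Harmonic count needed to reach a cumulative power threshold
#'
#' Smallest number of harmonics whose cumulative power reaches `threshold`
#' percent of the total power of the reference decomposition.
#'
#' @param e an [efa()] result with a reference harmonic count (>= 20 for a
#'   stable total).
#' @param threshold percent of total power.
#' @return Integer harmonic count.
#' @export
harmonic_power_threshold <- function(e, threshold = 98) {
  stopifnot(inherits(e, "outline_efa"))
  cum <- cumsum(e$power) / sum(e$power) * 100
  as.integer(which(cum >= threshold - 1e-12)[1])
}

#' Allometry check for EFA shape variables
#'
#' Regresses every shape variable on log centroid size and reports slopes and
#' Holm-adjusted p-values; the shape-size pattern is called isometric when no
#' slope is significant at `alpha`.
#'
#' @param shape_variables n x p matrix (profiles x shape variables).
#' @param centroid_sizes length-n positive sizes.
#' @param alpha significance threshold (study-wide 0.003).
#' @return List with per-variable `slopes`, `p_values` (adjusted), and
#'   `isometric` verdict.
#' @export
allometry_check <- function(shape_variables, centroid_sizes, alpha = 0.003) {
  shape_variables <- as.matrix(shape_variables)
  n <- nrow(shape_variables)
  if (n < 10) stop("allometry check requires at least 10 profiles")
  if (stats::sd(centroid_sizes) < 1e-12) {
    return(list(slopes = rep(NA_real_, ncol(shape_variables)),
                p_values = rep(NA_real_, ncol(shape_variables)),
                isometric = NA, flag = "constant centroid sizes"))
  }
  ls <- log(centroid_sizes)
  res <- apply(shape_variables, 2, function(v) {
    if (stats::sd(v) < 1e-12) return(c(0, 1))
    fit <- stats::lm(v ~ ls)
    s <- summary(fit)$coefficients
    c(s[2, 1], s[2, 4])
  })
  padj <- stats::p.adjust(res[2, ], method = "holm")
  list(slopes = res[1, ], p_values = padj,
       isometric = all(padj > alpha, na.rm = TRUE))
}
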