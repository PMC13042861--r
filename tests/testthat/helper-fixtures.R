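# shared fixtures, all built in code

flat_map <- function(n = 64, spacing = 0.05, value = 0) {
  height_map(matrix(value, n, n), spacing)
}

# z = A * sin(2*pi*x / P) along x (grooves run along y, direction 90 deg)
sinusoid_map <- function(n = 128, spacing = 0.05, A = 0.05, P = 0.5,
                         orientation = 90) {
  m <- flat_map(n, spacing)
  g <- expand.grid(y = hm_y(m), x = hm_x(m))
  phi <- (orientation - 90) * pi / 180
  s <- g$x * cos(phi) + g$y * sin(phi)
  m$heights <- matrix(A * sin(2 * pi * s / P), n, n)
  m
}

noise_map <- function(n = 64, spacing = 0.05, sd = 0.01, seed = 1) {
  set.seed(seed)
  height_map(matrix(rnorm(n * n, 0, sd), n, n), spacing)
}

# one Gaussian bump at (cx, cy) in mm
bump_map <- function(n = 64, spacing = 0.05, cx = NULL, cy = NULL, h = 0.1,
                     sigma = 0.3) {
  m <- flat_map(n, spacing)
  if (is.null(cx)) cx <- (n - 1) * spacing / 2
  if (is.null(cy)) cy <- (n - 1) * spacing / 2
  g <- expand.grid(y = hm_y(m), x = hm_x(m))
  m$heights <- matrix(h * exp(-((g$x - cx)^2 + (g$y - cy)^2) / (2 * sigma^2)),
                      n, n)
  m
}

fast_cfg <- function(seed = 1, ...) {
  generator_config(grid_size = 6, spacing = 0.1, seed = seed, ...)
}

expect_ordered_desc <- function(x) {
  expect_true(all(diff(x) < 0),
              label = paste("strictly decreasing:", paste(signif(x, 4), collapse = " > ")))
}
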