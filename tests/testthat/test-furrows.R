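# parallel V-grooves running along y at the given x centres
groove_field <- function(n = 100, spacing = 0.05, centres = c(1, 2, 3, 4),
                         depth = 0.3, width = 0.2) {
  m <- flat_map(n, spacing)
  x <- hm_xy_grids(m)$X
  for (i in seq_along(centres)) {
    d <- if (length(depth) > 1) depth[i] else depth
    m$heights <- pmin(m$heights, -d * pmax(0, 1 - abs(x - centres[i]) / width))
  }
  m
}

test_that("furrow extraction recovers constructed groove networks", {
  expect_equal(detect_furrows(flat_map())$total_length, 0)

  k <- 4
  m <- groove_field(centres = c(1, 2, 3, 4))
  net <- detect_furrows(m)
  L <- hm_extent(m)[2]; A <- hm_area(m)
  expect_equal(net$total_length / A * 10, k * L / A * 10,
               tolerance = 0.1 * k * L / A * 10)
  fp <- furrow_params(net)
  expect_equal(fp$max_depth, 0.3, tolerance = 2 * m$spacing)

  # two grooves, depths 0.1 and 0.3: length-weighted mean 0.2, max 0.3
  m2 <- groove_field(centres = c(1.5, 3.5), depth = c(0.1, 0.3))
  fp2 <- furrow_params(detect_furrows(m2))
  expect_equal(fp2$max_depth, 0.3, tolerance = 0.02)
  expect_equal(fp2$mean_depth, 0.2, tolerance = 0.03)

  # density is intensive: tiling the same texture leaves it unchanged
  m4 <- groove_field(n = 200, centres = c(1, 2, 3, 4, 6, 7, 8, 9))
  d1 <- furrow_params(detect_furrows(m))$mean_density
  d4 <- furrow_params(detect_furrows(m4))$mean_density
  expect_equal(d4, d1, tolerance = 0.05 * d1)

  # depth scales linearly with height scaling
  ms <- m; ms$heights <- 2 * m$heights
  expect_equal(furrow_params(detect_furrows(ms))$mean_depth,
               2 * furrow_params(detect_furrows(m))$mean_depth,
               tolerance = 1e-9)
})

test_that("direction spectra are normalised, oriented and rotation-equivariant", {
  s <- sinusoid_map(n = 128, spacing = 0.05, P = 0.5, orientation = 30)
  spec <- direction_spectrum(s)
  expect_equal(sum(spec$power), 1, tolerance = 1e-12)
  expect_lt(abs(spec$angles[which.max(spec$power)] - 30), 2)

  # rotation by delta shifts the argmax by delta
  for (delta in c(20, 45)) {
    s2 <- sinusoid_map(n = 128, spacing = 0.05, P = 0.5,
                       orientation = 30 + delta)
    a2 <- direction_spectrum(s2)
    shift <- (a2$angles[which.max(a2$power)] -
                spec$angles[which.max(spec$power)]) %% 180
    expect_lt(min(abs(shift - delta), abs(shift - delta + 180)), 4)
  }

  # white noise: no dominant angular bin
  ratios <- vapply(1:20, function(i) {
    p <- direction_spectrum(noise_map(128, seed = i))$power
    max(p) / median(p)
  }, numeric(1))
  expect_true(all(ratios < 3))
})

test_that("isotropy and ranked directions behave at the extremes", {
  s <- sinusoid_map(n = 128, spacing = 0.05, P = 0.5, orientation = 30)
  tp <- texture_direction_params(direction_spectrum(s))
  expect_lt(tp$Isotropy, 30)
  expect_lt(abs(tp$First - 30), 2)

  iso <- vapply(1:20, function(i) {
    texture_direction_params(direction_spectrum(noise_map(128, seed = i)))$Isotropy
  }, numeric(1))
  expect_true(all(iso > 70))

  # analytic flat spectrum
  flat_spec <- structure(list(angles = seq(0.5, 179.5, 1),
                              power = rep(1 / 180, 180), bin = 1),
                         class = "direction_spectrum")
  expect_equal(texture_direction_params(flat_spec)$Isotropy, 100)

  # axial convention: directions reported on [0, 180)
  expect_true(tp$First >= 0 && tp$First < 180)
})
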