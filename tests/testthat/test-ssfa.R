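test_that("relative-area curves match flat and sawtooth closed forms", {
  cf <- relative_area_curve(flat_map())
  expect_true(all(abs(cf$relative_area - 1) < 1e-12))
  a <- asfc(cf)
  expect_equal(a$Asfc, 0)
  expect_equal(a$Ymax, 1)
  expect_true(is.na(a$Smfc))

  # 45-degree sawtooth along x: relative area -> sqrt(2) at fine scales
  n <- 128; spacing <- 0.05; P <- 3.2
  m <- flat_map(n, spacing)
  x <- hm_xy_grids(m)$X
  tri <- abs((x %% P) - P / 2)  # |slope| = 1
  m$heights <- tri
  cur <- relative_area_curve(m)
  expect_equal(cur$relative_area[1], sqrt(2), tolerance = 0.01)
  a <- asfc(cur)
  expect_equal(a$Ymax, sqrt(2), tolerance = 0.01)
  expect_gt(a$Asfc, 0)
})

test_that("relative area is >= 1 and non-increasing with scale on generated surfaces", {
  for (s in 1:10) {
    m <- level_surface(make_base_substrate(fast_cfg(seed = s)))
    cur <- relative_area_curve(m)
    expect_true(all(cur$relative_area >= 1 - 1e-12))
    expect_true(all(diff(cur$relative_area) <= 0))
    expect_true(all(diff(cur$scales) > 0))
  }
})

test_that("fractal dimension orders self-affine surfaces by Hurst exponent", {
  das <- function(h, s) {
    cfg <- generator_config(grid_size = 6, spacing = 0.05, substrate_hurst = h,
                            substrate_rms = 0.05, pore_density = 0,
                            noise_rms = 0, seed = s)
    asfc(relative_area_curve(make_base_substrate(cfg)))$Das
  }
  d5 <- vapply(1:8, function(s) das(0.5, s), numeric(1))
  d9 <- vapply(1:8, function(s) das(0.9, s), numeric(1))
  expect_gt(median(d5), median(d9))
  expect_true(all(d5 > d9))
})

test_that("heterogeneity of Asfc reflects constructed rough quadrants", {
  f <- hasfc_grid(flat_map(96))
  expect_equal(f$HAsfc, 0)
  expect_equal(f$MedianAsfc, 0)

  homo <- noise_map(96, sd = 0.01, seed = 3)
  hete <- homo
  set.seed(4)
  hete$heights[1:32, 1:32] <- hete$heights[1:32, 1:32] +
    matrix(rnorm(32 * 32, 0, 0.05), 32, 32)
  expect_gt(hasfc_grid(hete)$HAsfc, hasfc_grid(homo)$HAsfc)
})

test_that("profile relative length of a plane is exactly 1", {
  m <- flat_map(100, 0.02)
  rl <- sculptrace:::relative_length_at(m, theta = 0.3, scale_mm = 0.04)
  expect_equal(rl, 1, tolerance = 1e-12)
})

test_that("epLsar separates isotropic noise from unidirectional texture", {
  ep <- vapply(1:20, function(i) {
    eplsar(noise_map(100, spacing = 0.02, sd = 0.01, seed = i))$epLsar
  }, numeric(1))
  expect_true(all(ep < 0.005))

  s <- sinusoid_map(n = 100, spacing = 0.02, A = 0.05, P = 0.4,
                    orientation = 90)  # grooves along y
  e <- eplsar(s)
  expect_gt(e$epLsar, 0.01)
  # longest relative length perpendicular to the grooves (near 0 degrees)
  amax <- e$angles[which.max(e$rel_length)]
  expect_lte(min(amax, 180 - amax), 10)

  # rotating the map by 90 degrees leaves the magnitude unchanged
  s90 <- s
  s90$heights <- t(s$heights)[, rev(seq_len(ncol(s$heights)))]
  e90 <- eplsar(height_map(t(s$heights), s$spacing))
  expect_equal(e90$epLsar, e$epLsar, tolerance = 0.02 * e$epLsar + 1e-4)

  expect_error(eplsar(flat_map(20, spacing = 0.1), scale = 40), "coarse")
})

test_that("Asfc and epLsar are insensitive to a height sign flip", {
  m <- level_surface(make_base_substrate(generator_config(
    grid_size = 4, spacing = 0.02, seed = 6)))
  flip <- m; flip$heights <- -m$heights
  expect_equal(asfc(relative_area_curve(flip))$Asfc,
               asfc(relative_area_curve(m))$Asfc, tolerance = 1e-9)
  expect_equal(eplsar(flip)$epLsar, eplsar(m)$epLsar, tolerance = 1e-9)
})
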