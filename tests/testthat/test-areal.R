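test_that("Sq matches closed forms and Monte-Carlo noise level", {
  expect_equal(sq(flat_map()), 0)
  s <- sinusoid_map(n = 200, spacing = 0.05, A = 0.05, P = 1)
  expect_equal(sq(s), 0.05 / sqrt(2), tolerance = 0.005)
  sqs <- vapply(1:20, function(i) sq(noise_map(64, sd = 0.01, seed = i)),
                numeric(1))
  expect_equal(mean(sqs), 0.01, tolerance = 0.05 * 0.01 * 5)
  expect_true(all(abs(sqs - 0.01) / 0.01 < 0.05))
})

test_that("Smc follows the areal material ratio curve", {
  expect_equal(smc(flat_map()), 0)
  # uniform height distribution on [-h, h]
  h <- 0.2
  m <- flat_map(100)
  set.seed(1)
  m$heights <- matrix(runif(100 * 100, -h, h), 100, 100)
  for (p in c(10, 25, 40)) {
    expect_equal(smc(m, p), h * (1 - 2 * p / 100), tolerance = 0.06)
  }
  s <- sinusoid_map()
  expect_equal(smc(s, 50), 0, tolerance = 1e-3)
})

test_that("autocorrelation length and aspect ratio match the cosine oracle", {
  # FFT ACF equals direct ACF on small grids
  z <- noise_map(24, sd = 1, seed = 7)$heights
  expect_equal(sculptrace:::acf2d(z), sculptrace:::acf2d_direct(z),
               tolerance = 1e-9)

  # white noise: near-isotropic, decay within 1-2 sample spacings
  res <- lapply(1:20, function(i) autocorrelation_params(noise_map(64, 0.05, seed = i)))
  expect_true(all(vapply(res, `[[`, numeric(1), "Str") > 0.8))
  expect_true(all(vapply(res, `[[`, numeric(1), "Sal") < 2 * 0.05))

  # 1-D sinusoid: fastest decay at arccos(0.2) / (2 pi) * P, strongly anisotropic
  P <- 0.8
  s <- sinusoid_map(n = 128, spacing = 0.05, A = 0.05, P = P, orientation = 90)
  ac <- autocorrelation_params(s)
  expect_equal(ac$Sal, acos(0.2) / (2 * pi) * P, tolerance = 0.05 * P)
  expect_lt(ac$Str, 0.2)

  expect_true(is.na(autocorrelation_params(flat_map())$Sal))
})

test_that("Sdr matches flat and 45-degree closed forms and grows with craters", {
  expect_equal(sdr(flat_map()), 0)
  n <- 50
  m <- flat_map(n, 0.1)
  m$heights <- hm_xy_grids(m)$X  # 45-degree plane, levelling bypassed
  expect_equal(sdr(m), (sqrt(2) - 1) * 100, tolerance = 1e-6)

  base <- make_base_substrate(fast_cfg(seed = 3))
  cratered <- apply_pecking(base, default_tools()$pick,
                            skill_level("intermediate"), 2, 16, seed = 5)
  expect_gte(sdr(cratered), sdr(base))
})

test_that("Vvv captures the void volume below the material-ratio plane", {
  expect_equal(vvv(flat_map()), 0)
  # rectangular pit of depth d over area fraction f < 20%
  n <- 100
  m <- flat_map(n, 0.1)
  m$heights[1:10, 1:n] <- -0.5  # f = 10%
  expect_equal(vvv(m, p = 80), 0.1 * 0.5, tolerance = 0.01 * 0.5)
})

test_that("watershed segmentation counts and prunes features", {
  seg <- segment_features(flat_map())
  expect_equal(sum(seg$hills > 0), 0)
  expect_null(seg$hill_table)

  one <- segment_features(bump_map())
  expect_equal(nrow(one$hill_table), 1)

  two <- bump_map(n = 100, spacing = 0.05, cx = 1.2, cy = 1.2, h = 1,
                  sigma = 0.25)
  g <- hm_xy_grids(two)
  two$heights <- two$heights +
    0.03 * exp(-((g$X - 3.5)^2 + (g$Y - 3.5)^2) / (2 * 0.25^2))
  seg2 <- segment_features(two, pruning = 5)  # threshold 5% of Sz = 0.05 > 0.03
  expect_equal(nrow(seg2$hill_table), 1)
})

test_that("feature parameters match curvature, roundness and counting oracles", {
  # paraboloid peak z = h - r^2 / (2R): Spc = 1/R
  n <- 81; spacing <- 0.05; R <- 2
  m <- flat_map(n, spacing)
  g <- hm_xy_grids(m)
  r2 <- (g$X - 2)^2 + (g$Y - 2)^2
  m$heights <- pmax(0.5 - r2 / (2 * R), 0)
  seg <- segment_features(m)
  fp <- feature_params(seg, m)
  expect_equal(fp$Spc, 1 / R, tolerance = 0.05 / R)

  # circular Gaussian bump: isoperimetric roundness ~ 1
  b <- bump_map(n = 80, spacing = 0.05)
  fpb <- feature_params(segment_features(b), b)
  expect_equal(fpb$Shrn, 1, tolerance = 0.05)

  # n identical bumps: Spd = n / area
  nb <- flat_map(120, 0.05)
  g <- hm_xy_grids(nb)
  for (cx in c(1.5, 4.5)) for (cy in c(1.5, 4.5)) {
    nb$heights <- nb$heights +
      0.2 * exp(-((g$X - cx)^2 + (g$Y - cy)^2) / (2 * 0.2^2))
  }
  fpn <- feature_params(segment_features(nb), nb)
  expect_equal(fpn$Spd, 4 / hm_area(nb), tolerance = 1e-9)

  # translation invariance of Spd
  nb2 <- nb
  nb2$origin <- c(10, 20)
  fpn2 <- feature_params(segment_features(nb2), nb2)
  expect_equal(fpn2$Spd, fpn$Spd)
})

test_that("texture direction finds groove orientation and flags noise", {
  for (ang in c(0, 30)) {
    s <- sinusoid_map(n = 128, spacing = 0.05, P = 0.5, orientation = ang)
    d <- std_direction(s)
    expect_lt(min(abs(d - ang), abs(d - ang - 180), abs(d - ang + 180)), 2)
    expect_false(attr(d, "unstable"))
  }
  flagged <- vapply(1:20, function(i) {
    attr(std_direction(noise_map(128, seed = i)), "unstable")
  }, logical(1))
  expect_true(mean(flagged) > 0.9)
})

test_that("height scaling and translation equivariance hold", {
  m <- noise_map(48, sd = 0.02, seed = 12)
  for (c0 in c(2, 5)) {
    ms <- m; ms$heights <- m$heights * c0
    expect_equal(sq(ms), c0 * sq(m), tolerance = 1e-12)
    expect_equal(smc(ms), c0 * smc(m), tolerance = 1e-12)
    expect_equal(autocorrelation_params(ms)$Str,
                 autocorrelation_params(m)$Str, tolerance = 1e-9)
  }
})

test_that("masked border cells do not bias the distribution parameters", {
  m <- noise_map(60, sd = 0.02, seed = 13)
  inner <- height_map(m$heights[6:55, 6:55], m$spacing)
  annulus <- m
  annulus$mask[c(1:5, 56:60), ] <- FALSE
  annulus$mask[, c(1:5, 56:60)] <- FALSE
  expect_equal(sq(annulus), sq(inner))
  expect_equal(smc(annulus), smc(inner))
  expect_equal(vvv(annulus), vvv(inner))
  expect_equal(autocorrelation_params(annulus)$Sal,
               autocorrelation_params(inner)$Sal)
})
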