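test_that("profile extraction interpolates sections through grooves", {
  f <- flat_map(80, 0.05)
  tr <- extract_profile(f, c(0.2, 0.2), c(3.5, 3.5))
  expect_true(all(abs(tr$points$z) < 1e-12))

  g <- apply_engraving_groove(f, depth = 0.4, strokes = 1)
  trg <- extract_profile(g, c(1.975, 0), c(1.975, 3.95))
  expect_equal(min(trg$points$z), -0.4, tolerance = g$spacing)

  expect_error(extract_profile(f, c(-2, 0), c(5, 0)), "exits")
})

test_that("landmarks find apex, shoulders and depth-convergent points", {
  p <- generate_profile(depth = 1, wis = 2, shape = "V")
  lm <- detect_landmarks(p)
  x <- p$points$x
  expect_equal(x[lm$apex], 0, tolerance = p$spacing)
  expect_equal(lm$left_shoulder_x, -1, tolerance = p$spacing)
  expect_equal(lm$right_shoulder_x, 1, tolerance = p$spacing)
  expect_equal(abs(lm$left_shoulder_x + lm$right_shoulder_x), 0,
               tolerance = 2 * p$spacing)
  expect_false(any(lm$flags))
  # LDC/RDC at 90% depth
  expect_equal(unname(lm$LDC["z"]), -0.9, tolerance = 1e-9)
  expect_lt(lm$LDC["x"], lm$RDC["x"])

  # flat-bottomed U: apex at the centre of the minimal plateau
  u <- generate_profile(depth = 1, wis = 3, shape = "U")
  lmu <- detect_landmarks(u)
  expect_equal(u$points$x[lmu$apex], 0, tolerance = 2 * u$spacing)

  # two comparable troughs are flagged
  x2 <- seq(-2, 2, length.out = 201)
  z2 <- -pmax(0, 1 - abs(x2 + 1) / 0.4) - 0.8 * pmax(0, 1 - abs(x2 - 1) / 0.4)
  lm2 <- detect_landmarks(profile_trace(x2, z2))
  expect_true(lm2$flags[["multi_trough"]])
})

test_that("profile measurements match geometry and similarity transforms", {
  p <- generate_profile(depth = 1, wis = 2, shape = "V")
  m <- measure_profile(p, detect_landmarks(p))
  expect_equal(m$theta, 90, tolerance = 0.5)
  expect_lt(m$A, 0.01)

  p2 <- profile_trace(2 * p$points$x, 2 * p$points$z)
  m2 <- measure_profile(p2, detect_landmarks(p2))
  expect_equal(m2$D, 2 * m$D, tolerance = 1e-9)
  expect_equal(m2$WIS, 2 * m$WIS, tolerance = 1e-9)
  expect_equal(m2$theta, m$theta, tolerance = 1e-6)

  # horizontal translation invariance
  p3 <- profile_trace(p$points$x + 5, p$points$z)
  m3 <- measure_profile(p3, detect_landmarks(p3))
  expect_equal(m3$D, m$D)
  expect_equal(m3$WIS, m$WIS, tolerance = 1e-12)
  expect_equal(m3$A, m$A, tolerance = 1e-12)

  # mirror symmetry: A is exactly reflection-invariant
  pa <- generate_profile(depth = 1, wis = 2, asymmetry = 0.4)
  ma <- measure_profile(pa, detect_landmarks(pa))
  mir <- profile_trace(rev(-pa$points$x), rev(pa$points$z))
  mm <- measure_profile(mir, detect_landmarks(mir))
  expect_equal(mm$A, ma$A, tolerance = 1e-9)
  expect_gt(ma$A, m$A)
})

test_that("outline closure yields a counter-clockwise 256-point polygon", {
  p <- generate_profile(depth = 1, wis = 2, shape = "V")
  lm <- detect_landmarks(p)
  o <- close_outline(p, lm)
  expect_equal(nrow(o), 256)
  area <- sculptrace:::polygon_area(o[, 1], o[, 2])
  expect_gt(area, 0)
  m <- measure_profile(p, lm)
  expect_equal(area, 0.5 * m$WIS * m$D, tolerance = 0.02 * 0.5 * m$WIS * m$D)
})

test_that("EFA concentrates ellipse power in harmonic 1 and reconstructs outlines", {
  t <- 2 * pi * (0:127) / 128
  ellipse <- cbind(3 * cos(t), 1.2 * sin(t))
  # in vertex timing a parametric ellipse is exactly one harmonic
  e <- efa(ellipse, h = 10, timing = "vertex")
  expect_true(all(e$power >= 0))
  expect_gte(e$power[1] / sum(e$power), 0.9999)
  e20e <- efa(ellipse, h = 20, timing = "vertex")
  expect_equal(harmonic_power_threshold(e20e, 98), 1L)
  expect_equal(harmonic_power_threshold(e20e, 100), 1L)
  # arc-length timing: a mildly eccentric ellipse still concentrates in h1
  expect_gte(efa(ellipse, h = 20)$power[1] / sum(efa(ellipse, h = 20)$power),
             0.99)

  p <- generate_profile(depth = 1, wis = 2, asymmetry = 0.3, noise_rms = 0)
  o <- close_outline(p, detect_landmarks(p))
  e20 <- efa(o, h = 20)
  rec <- efa_reconstruct(e20, n = 256)
  d <- sqrt(rowSums((rec - o)^2))
  expect_lt(mean(d), 0.005 * e20$centroid_size)
})

test_that("EFA normalization yields 4h-3 invariant shape variables", {
  p <- generate_profile(depth = 0.8, wis = 1.6, asymmetry = 0.25)
  o <- close_outline(p, detect_landmarks(p))
  ne <- normalize_efa(efa(o, h = 6))
  expect_length(ne$shape_variables, 4 * 6 - 3)

  # rotation + scaling + starting-point invariance
  phi <- 40 * pi / 180
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  o2 <- 3 * (o %*% R)
  o2 <- o2[c(100:256, 1:99), ]  # new starting point
  ne2 <- normalize_efa(efa(o2, h = 6))
  expect_equal(ne2$shape_variables, ne$shape_variables, tolerance = 1e-6)

  expect_equal(sum((ne$shape_variables - ne$shape_variables)^2), 0)
  expect_error(normalize_efa(efa(cbind(rep(0, 32), rep(0, 32)), h = 2)),
               "degenerate")
  expect_error(efa(o, h = 0), "harmonic")
})

test_that("allometry check separates isometric from allometric sets", {
  set.seed(5)
  base <- generate_profile(depth = 1, wis = 2, asymmetry = 0.2)
  sizes <- exp(runif(12, -0.5, 0.8))
  sv <- t(vapply(sizes, function(s) {
    p <- profile_trace(base$points$x * s, base$points$z * s)
    normalize_efa(efa(close_outline(p, detect_landmarks(p)), h = 6))$shape_variables
  }, numeric(21)))
  iso <- allometry_check(sv, sizes)
  expect_true(iso$isometric)
  expect_true(all(abs(iso$slopes) < 1e-6))

  # shape drifting with size
  sv2 <- t(vapply(sizes, function(s) {
    p <- generate_profile(depth = 1, wis = 2, asymmetry = min(0.9, 0.5 * s))
    p <- profile_trace(p$points$x * s, p$points$z * s)
    normalize_efa(efa(close_outline(p, detect_landmarks(p)), h = 6))$shape_variables
  }, numeric(21)))
  allo <- allometry_check(sv2, sizes)
  expect_false(allo$isometric)

  expect_error(allometry_check(sv[1:2, ], sizes[1:2]), "at least 10")
  flagged <- allometry_check(sv, rep(2, 12))
  expect_true(is.na(flagged$isometric))
})
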