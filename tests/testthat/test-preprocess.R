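test_that("levelling annihilates exact planes and leaves orthogonal residuals", {
  n <- 40
  m <- flat_map(n, 0.1)
  g <- hm_xy_grids(m)
  m$heights <- 2 * g$X + 3 * g$Y + 5
  lv <- level_surface(m)
  expect_lt(max(abs(hm_values(lv))), 1e-9)

  r <- noise_map(n, 0.1, sd = 0.05, seed = 2)
  lv <- level_surface(r)
  res <- hm_values(lv)
  expect_lt(abs(sum(res)), 1e-8)
  expect_lt(abs(sum(g$X[lv$mask] * res)), 1e-7)
  expect_lt(abs(sum(g$Y[lv$mask] * res)), 1e-7)
  # idempotent
  lv2 <- level_surface(lv)
  expect_lt(max(abs(lv2$heights - lv$heights)), 1e-9)
})

test_that("levelling a masked map fits only the unmasked cells", {
  n <- 30
  m <- noise_map(n, 0.1, sd = 0.02, seed = 3)
  g <- hm_xy_grids(m)
  m$heights <- m$heights + 0.5 * g$X
  m$mask[, 1:(n / 2)] <- FALSE
  lv <- level_surface(m)
  # brute-force plane fit on the same subset
  ok <- m$mask
  fit <- lm.fit(cbind(1, g$X[ok], g$Y[ok]), m$heights[ok])
  expect_equal(hm_values(lv), unname(fit$residuals), tolerance = 1e-9)
})

test_that("form removal annihilates cubics and preserves finer texture", {
  n <- 60
  m <- flat_map(n, 0.1)
  g <- hm_xy_grids(m)
  m$heights <- g$X^3 - 2 * g$X * g$Y^2 + g$Y
  fr <- remove_form(m, degree = 3)
  expect_lt(max(abs(hm_values(fr))), 1e-6)

  sinz <- 0.05 * sin(2 * pi * g$X / 0.4)
  m$heights <- g$X^3 - g$Y^3 + sinz
  fr <- remove_form(m, degree = 3)
  expect_equal(sq(fr), sqrt(mean(sinz^2)), tolerance = 0.05)

  m0 <- noise_map(20, 0.1, seed = 4)
  d0 <- remove_form(m0, degree = 0)
  expect_equal(d0$heights, m0$heights - mean(m0$heights))
  fr2 <- remove_form(fr, degree = 3)
  expect_lt(max(abs(fr2$heights - fr$heights)), 1e-9)
})

test_that("subdivision tiles are disjoint, within bounds and worked-flagged", {
  m <- noise_map(60, 0.5, seed = 5)  # 30 x 30 mm
  tiles <- subdivide(m, tile = 10, n = 9)
  expect_length(tiles, 9)
  covered <- matrix(0, 60, 60)
  for (t in tiles) {
    w <- t$meta$window
    covered[w["row0"]:(w["row0"] + w["rows"] - 1),
            w["col0"]:(w["col0"] + w["cols"] - 1)] <-
      covered[w["row0"]:(w["row0"] + w["rows"] - 1),
              w["col0"]:(w["col0"] + w["cols"] - 1)] + 1
    expect_equal(dim(t$heights), c(20, 20))
  }
  expect_true(all(covered <= 1))
  expect_equal(sum(covered), 9 * 400)

  one <- subdivide(m, tile = 30, n = 1)
  expect_equal(one[[1]]$heights, m$heights)

  expect_error(subdivide(m, tile = 10, n = 16), "at most")

  worked <- matrix(FALSE, 60, 60)
  worked[1:40, 1:40] <- TRUE  # covers the 4 lower-left tiles
  tiles <- subdivide(m, tile = 10, n = 9, worked_mask = worked)
  expect_equal(sum(vapply(tiles, function(t) t$meta$worked, logical(1))), 4)
})
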