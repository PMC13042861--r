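test_that("substrate generation is seeded, normalised and degenerates to flat", {
  cfg0 <- fast_cfg(substrate_rms = 0, noise_rms = 0, pore_density = 0)
  expect_equal(sq(make_base_substrate(cfg0)), 0)

  cfg <- fast_cfg(seed = 11)
  m1 <- make_base_substrate(cfg)
  m2 <- make_base_substrate(cfg)
  expect_identical(m1$heights, m2$heights)

  expect_error(generator_config(grid_size = -1), "configuration error")
  expect_error(generator_config(substrate_hurst = 1.2), "configuration error")
})

test_that("substrate RMS matches the requested amplitude (Monte-Carlo)", {
  rms <- vapply(1:20, function(s) {
    cfg <- generator_config(grid_size = 10, spacing = 0.1,
                            substrate_hurst = 0.8, substrate_rms = 0.05,
                            pore_density = 0, noise_rms = 0, seed = s)
    sq(make_base_substrate(cfg))
  }, numeric(1))
  expect_true(all(abs(rms - 0.05) / 0.05 < 0.15))
})

test_that("sawing adds oriented grooves, increases anisotropy, only removes material", {
  f <- flat_map(80, 0.05)
  expect_equal(apply_sawing(f, groove_amplitude = 0)$heights, f$heights)
  expect_error(apply_sawing(f, period = 0.05), "aliasing")

  s <- apply_sawing(f, orientation = 0, groove_amplitude = 0.05, period = 0.5)
  expect_true(all(s$heights <= f$heights + 1e-12))
  d <- texture_direction_params(direction_spectrum(s))
  expect_lt(min(abs(d$First - 0), abs(d$First - 180)), 2)

  base <- make_base_substrate(fast_cfg(seed = 2))
  sawn <- apply_sawing(base, orientation = 30, groove_amplitude = 0.08,
                       period = 0.5)
  str0 <- autocorrelation_params(level_surface(base))$Str
  str1 <- autocorrelation_params(level_surface(sawn))$Str
  expect_lt(str1, str0)
})

test_that("pecking carves seeded craters and never adds material", {
  tools <- default_tools()
  sk <- skill_level("expert")
  f <- flat_map(80, 0.05)
  expect_equal(apply_pecking(f, tools$pick, sk, budget = 0)$heights, f$heights)
  expect_warning(apply_pecking(f, tools$pick, sk, budget = 5, rate = 0),
                 "zero pecking rate")
  expect_error(apply_pecking(f, tools$blade, sk), "point or cobble")

  # a single crater of depth d on a flat substrate bottoms out at -d
  z <- sculptrace:::subtract_crater(f$heights,
                                    hm_xy_grids(f)$X, hm_xy_grids(f)$Y,
                                    cx = 2, cy = 2, a = 0.8, b = 0.4,
                                    psi = 0.3, depth = 0.25)
  expect_equal(min(z), -0.25, tolerance = 1e-12)
  i <- which(z == min(z), arr.ind = TRUE)
  expect_equal(hm_x(f)[i[1, 2]], 2, tolerance = f$spacing)
  expect_equal(hm_y(f)[i[1, 1]], 2, tolerance = f$spacing)

  sub <- make_base_substrate(fast_cfg(seed = 5))
  p <- apply_pecking(sub, tools$pick, sk, budget = 5, rate = 16, seed = 7)
  expect_true(all(p$heights <= sub$heights + 1e-12))
})

test_that("expert crater orientations are more concentrated than novice", {
  tools <- default_tools()
  circ_var <- function(theta) 1 - sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
  cv <- sapply(1:8, function(s) {
    f <- flat_map(60, 0.1)
    pe <- apply_pecking(f, tools$pick, skill_level("expert"), 5, 16,
                        seed = s, mean_direction = 40)
    pn <- apply_pecking(f, tools$pick, skill_level("novice"), 5, 16,
                        seed = s, mean_direction = 40)
    c(expert = circ_var(pe$meta$events$orientation),
      novice = circ_var(pn$meta$events$orientation))
  })
  expect_true(all(cv["expert", ] < cv["novice", ]))
})

test_that("scraping grooves follow the requested direction and passes reduce Sq", {
  tools <- default_tools()
  sk <- skill_level("expert")
  f <- flat_map(80, 0.05)
  expect_equal(apply_scraping(f, tools$endscraper, sk, budget = 0)$heights,
               f$heights)
  s <- apply_scraping(f, tools$endscraper, sk, budget = 5, rate = 30,
                      seed = 3, mean_direction = 30)
  # strokes alternate between two hand-position families around the mean
  # direction: the axial circular mean of stroke angles recovers it
  ang <- s$meta$events$orientation[s$meta$events$step == "scrape"]
  axial_mean <- (atan2(mean(sin(2 * ang)), mean(cos(2 * ang))) / 2 * 180 / pi) %% 180
  expect_lt(min(abs(axial_mean - 30), abs(axial_mean - 30 - 180)), 10)
  d <- texture_direction_params(direction_spectrum(s))
  expect_lt(min(abs(d$First - 30), abs(d$First - 210), abs(d$First + 150)), 25)

  # repeated scraping passes on a pecked substrate homogenise the relief
  pk <- apply_pecking(make_base_substrate(fast_cfg(seed = 9)), tools$pick,
                      sk, 5, 16, seed = 11)
  sqs <- vapply(c(1, 3, 6), function(passes) {
    m <- apply_scraping(pk, tools$endscraper, sk, budget = passes,
                        rate = 25, seed = 13, strokes_per_pass = 25)
    sq(level_surface(m))
  }, numeric(1))
  expect_ordered_desc(sqs)
})

test_that("polishing smooths scraped relief and adds fine multidirectional furrows", {
  tools <- default_tools()
  sk <- skill_level("intermediate")
  f <- flat_map(64, 0.05)
  expect_equal(apply_polishing(f, tools$skin, budget = 0)$heights, f$heights)
  expect_error(apply_polishing(f, tools$blade), "cobble, skin or sand")

  scraped <- apply_scraping(make_base_substrate(fast_cfg(seed = 21)),
                            tools$blade, sk, 5, rate = 18, seed = 23)
  pol <- apply_polishing(scraped, tools$skin, 5, rate = 250, seed = 25)
  expect_true(all(pol$heights <= scraped$heights + 1e-12))
  f_s <- furrow_params(detect_furrows(remove_form(scraped)))
  f_p <- furrow_params(detect_furrows(remove_form(pol)))
  expect_gt(f_p$mean_density, f_s$mean_density)
  expect_lt(f_p$mean_depth, f_s$mean_depth)

  sawn <- apply_sawing(make_base_substrate(fast_cfg(seed = 27)),
                       orientation = 0, groove_amplitude = 0.08, period = 0.5)
  pol2 <- apply_polishing(sawn, tools$cobble, 5, rate = 250, seed = 29)
  expect_gt(autocorrelation_params(level_surface(pol2))$Str,
            autocorrelation_params(level_surface(sawn))$Str)
})

test_that("engraved grooves have prescribed depth and widen with stroke count", {
  f <- flat_map(81, 0.05)  # mid-line falls on a grid node
  expect_error(apply_engraving_groove(f, depth = 0), "positive")
  g1 <- apply_engraving_groove(f, depth = 0.3, asymmetry = 0, strokes = 1)
  tr <- extract_profile(g1, c(2, 0), c(2, 4))
  lm1 <- detect_landmarks(tr)
  m1 <- measure_profile(tr, lm1)
  expect_equal(m1$D, 0.3, tolerance = f$spacing)
  expect_lt(m1$A, f$spacing / 2)

  g5 <- apply_engraving_groove(f, depth = 0.3, asymmetry = 0, strokes = 5,
                               seed = 5)
  tr5 <- extract_profile(g5, c(2, 0), c(2, 4))
  m5 <- measure_profile(tr5, detect_landmarks(tr5))
  expect_gt(m5$WIS, m1$WIS)
})

test_that("modalities compose deterministically and enumerate the study design", {
  cfg <- fast_cfg(seed = 31)
  saw_spec <- modality_spec("SAW", list(list(technique = "saw", tool = "pick",
                                             minutes = 5)))
  m <- synthesize_modality(saw_spec, skill_level("expert"), cfg, seed = 31)
  ref <- apply_sawing(make_base_substrate(fast_cfg(seed = 31)))
  expect_equal(m$heights, ref$heights)
  expect_error(modality_spec("X", list(list(technique = "drill", tool = "pick"))),
               "unknown technique")

  design <- default_study_design()
  expect_length(design$modalities, 19)
  expect_length(design$participants, 5)
  # 19 modalities x 5 participants = the study's 95 trials
  expect_equal(length(design$modalities) * length(design$participants), 95)

  small <- study_design(design$modalities[1:2], design$participants[1:2],
                        seed = 7)
  st <- generate_study(small, fast_cfg())
  expect_equal(nrow(st$labels), 4)
  expect_length(st$maps, 4)
  st2 <- generate_study(small, fast_cfg())
  expect_identical(st$labels, st2$labels)
  expect_identical(st$maps[[1]]$heights, st2$maps[[1]]$heights)

  one <- study_design(design$modalities[1], design$participants[1])
  expect_length(generate_study(one, fast_cfg())$maps, 1)
  expect_error(study_design(design$modalities[1:2],
                            list(design$participants[[1]],
                                 design$participants[[1]])),
               "duplicate participant")
})

test_that("synthetic profiles honour their prescribed geometry", {
  p <- generate_profile(depth = 1, wis = 2, shape = "V", asymmetry = 0,
                        noise_rms = 0)
  m <- measure_profile(p, detect_landmarks(p))
  expect_equal(m$theta, 90, tolerance = 0.5)
  expect_equal(m$D, 1, tolerance = 1e-9)
  expect_equal(m$WIS, 2, tolerance = 2 * p$spacing)

  pa <- generate_profile(depth = 1, wis = 2, asymmetry = 0.5, noise_rms = 0)
  ma <- measure_profile(pa, detect_landmarks(pa))
  expect_gt(ma$A, m$A)
})
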