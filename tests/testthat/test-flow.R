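pos <- 0:140

test_that("extent detection reads the trigger crossings off the FSC trace", {
  pr <- make_profile(pos, fsc = rect_channel(pos, 10, 110, 1000))
  ext <- detect_extent(pr)
  expect_equal(ext$start_um, 10)
  expect_equal(ext$end_um, 110)
  expect_equal(ext$signal_length_um, 100)
  flat <- make_profile(pos, fsc = rep(50, length(pos)))
  expect_error(detect_extent(flat), "no particle")
  # noisy synthetic sphere: within 2 sample spacings of the true diameter
  g <- generate_pulse_profile(pulse_gen_params(pellet_diameter_um = 180,
                                               sample_spacing_um = 2,
                                               noise_sd_mv = 5, seed = 12L))
  expect_lt(abs(detect_extent(g$profile)$signal_length_um - 180), 2 * 2 + 1e-9)
})

test_that("particles classify by saturation and the 80 um length rule", {
  sat <- 3000
  long_sat <- make_profile(pos, fsc = pmin(rect_channel(pos, 10, 130, 5000), sat),
                           saturation_mv = sat)
  expect_identical(classify_particle(long_sat), "pellet")
  short_sat <- make_profile(pos, fsc = pmin(rect_channel(pos, 40, 100, 5000), sat),
                            saturation_mv = sat)
  expect_identical(classify_particle(short_sat), "small")   # 60 um, saturated
  long_unsat <- make_profile(pos, fsc = rect_channel(pos, 10, 130, 2000),
                             saturation_mv = sat)
  expect_identical(classify_particle(long_unsat), "large")
})

test_that("compactness reproduces the rectangle, triangle and sphere values", {
  fsc <- rect_channel(pos, 10, 110, 1000)
  # rectangle whose half-maximum crossings sit exactly on the extent ends
  ssc_rect <- numeric(length(pos))
  ssc_rect[pos >= 11 & pos <= 109] <- 1000
  ssc_rect[pos == 10 | pos == 110] <- 500
  expect_equal(compactness(make_profile(pos, fsc = fsc, ssc = ssc_rect)), 1,
               tolerance = 1e-9)
  # triangle spanning the extent: FWHM is half the base
  ssc_tri <- pmax(0, 1000 * (1 - abs(pos - 60) / 50))
  expect_equal(compactness(make_profile(pos, fsc = fsc, ssc = ssc_tri)), 0.5,
               tolerance = 1e-9)
  # noise-free projected sphere: sqrt(3)/2
  g <- generate_pulse_profile(pulse_gen_params(pellet_diameter_um = 240,
                                               noise_sd_mv = 0,
                                               saturation_mv = Inf,
                                               sample_spacing_um = 0.5,
                                               seed = 1L))
  expect_equal(compactness(g$profile), sqrt(3) / 2, tolerance = 0.01)
  flat_ssc <- make_profile(pos, fsc = fsc)
  expect_error(compactness(flat_ssc), "flat SSC")
})

test_that("the FDA viable layer follows the area-ratio arithmetic", {
  fsc <- rect_channel(pos, 10, 130, 400)
  flg <- rect_channel(pos, 10, 130, 100)
  pr <- make_profile(pos, fsc = fsc, flg = flg)
  # areas 400*120 and 100*120, length 120: 0.5 * (1/4) * 120 = 15
  expect_equal(viable_layer_fda(pr), 15, tolerance = 1e-9)
  expect_equal(viable_layer_fda(make_profile(pos, fsc = fsc)), 0, tolerance = 1e-9)
  same <- make_profile(pos, fsc = fsc, flg = fsc)
  expect_equal(viable_layer_fda(same), 60, tolerance = 1e-9)  # full radius
})

test_that("the PI viable layer subtracts the thresholded core length", {
  fsc <- rect_channel(pos, 10, 130, 1000)
  # no red signal anywhere: full viable radius
  expect_equal(viable_layer_pi(make_profile(pos, fsc = fsc)), 60, tolerance = 1e-9)
  # red above threshold across the whole extent: fully dead
  flr_all <- numeric(length(pos))
  flr_all[pos >= 11 & pos <= 129] <- 1000
  flr_all[pos == 10 | pos == 130] <- 400   # crossings of 0.3*max at the ends
  expect_equal(viable_layer_pi(make_profile(pos, fsc = fsc, flr = flr_all)), 0,
               tolerance = 1e-6)
  # synthetic pellet with sharp shells: 0.5 * (D - core)
  g <- generate_pulse_profile(pulse_gen_params(pellet_diameter_um = 100,
                                               dead_core_diameter_um = 60,
                                               noise_sd_mv = 0,
                                               saturation_mv = Inf,
                                               sample_spacing_um = 1,
                                               flr_shape = "slab", seed = 1L))
  expect_lt(abs(viable_layer_pi(g$profile) - 20), 1 + 1e-9)
})

test_that("viability and autofluorescence factors are plain ratios", {
  expect_equal(viability_factor(15, 120), 0.25, tolerance = 1e-12)
  expect_equal(viability_factor(60, 120), 1, tolerance = 1e-12)
  expect_equal(viability_factor(0, 120), 0)
  expect_error(viability_factor(10, 0), "positive")
  fsc <- rect_channel(pos, 10, 130, 400)
  flg <- rect_channel(pos, 10, 130, 84)
  pr <- make_profile(pos, fsc = fsc, flg = flg, stained = FALSE)
  expect_equal(autofluorescence_factor(pr), 0.21, tolerance = 1e-9)
  expect_equal(autofluorescence_factor(make_profile(pos, fsc = fsc)), 0,
               tolerance = 1e-12)
  expect_equal(autofluorescence_factor(make_profile(pos, fsc = fsc, flg = fsc)),
               1, tolerance = 1e-9)
})

test_that("metrics are invariant to common gain and position shifts", {
  p <- pulse_gen_params(pellet_diameter_um = 160, noise_sd_mv = 0,
                        saturation_mv = Inf, seed = 6L)
  pr <- generate_pulse_profile(p)$profile
  scaled <- pr
  for (ch in c("fsc_mv", "ssc_mv", "flg_mv", "flr_mv"))
    scaled[[ch]] <- 3.7 * pr[[ch]]
  scaled$trigger_mv <- 3.7 * pr$trigger_mv
  expect_equal(compactness(scaled), compactness(pr), tolerance = 1e-9)
  expect_equal(viable_layer_fda(scaled), viable_layer_fda(pr), tolerance = 1e-9)
  expect_equal(autofluorescence_factor(scaled), autofluorescence_factor(pr),
               tolerance = 1e-9)
  shifted <- pr
  shifted$position_um <- pr$position_um + 500
  expect_equal(compactness(shifted), compactness(pr), tolerance = 1e-12)
  expect_equal(viable_layer_fda(shifted), viable_layer_fda(pr), tolerance = 1e-9)
  expect_equal(detect_extent(shifted)$signal_length_um,
               detect_extent(pr)$signal_length_um)
})

test_that("a thicker viable shell never shrinks the FDA layer", {
  vls <- sapply(seq(5, 75, by = 10), function(t) {
    p <- pulse_gen_params(pellet_diameter_um = 150, viable_shell_um = t,
                          noise_sd_mv = 0, saturation_mv = Inf, seed = 2L)
    viable_layer_fda(generate_pulse_profile(p)$profile)
  })
  expect_true(all(diff(vls) >= -1e-9))
})

test_that("the FDA layer matches the chord-model closed form without saturation", {
  # integrating the chord profiles gives area ratio 1 - (1 - t/R)^2, so
  # vl = 0.5 * D * (flg_gain/fsc_gain) * (1 - (1 - t/R)^2)
  for (D in c(120, 200, 320)) {
    t <- 0.3 * D / 2
    p <- pulse_gen_params(pellet_diameter_um = D, viable_shell_um = t,
                          noise_sd_mv = 0, saturation_mv = Inf,
                          sample_spacing_um = 1, seed = 1L)
    vl <- viable_layer_fda(generate_pulse_profile(p)$profile)
    closed <- 0.5 * D * (p$flg_gain / p$fsc_gain) * (1 - (1 - t / (D / 2))^2)
    expect_lt(abs(vl / closed - 1), 0.02)
  }
})

test_that("population summaries count pellets only and track truth", {
  # identical pellets: zero spread on every metric
  p <- pulse_gen_params(noise_sd_mv = 0, seed = 1L)
  same <- replicate(20, generate_pulse_profile(p)$profile, simplify = FALSE)
  s <- suppressMessages(summarize_population(same, min_pellets = 10L))
  expect_equal(s$summary$n_pellets, 20L)
  expect_equal(s$summary$signal_length_sd_um, 0)
  expect_equal(s$summary$compactness_sd, 0)
  expect_equal(s$summary$viability_factor_sd, 0)
  # mixture with small elements: n counts only pellets
  small <- replicate(3, generate_pulse_profile(
    pulse_gen_params(pellet_diameter_um = 50, dead_core_diameter_um = 20,
                     viable_shell_um = 10, noise_sd_mv = 0, seed = 2L))$profile,
    simplify = FALSE)
  mix <- c(same, small)
  sm <- suppressMessages(summarize_population(mix, min_pellets = 10L))
  expect_equal(sm$summary$n_particles, 23L)
  expect_equal(sm$summary$n_pellets, 20L)
  # seeded population: mean signal length within 5% of the mean true diameter
  pop <- generate_pulse_population(n = 80L, seed = 77L)
  ps <- suppressMessages(summarize_population(pop$profiles, min_pellets = 50L))
  pel <- ps$particles$particle_class == "pellet"
  expect_gt(sum(pel), 50)
  expect_lt(abs(ps$summary$signal_length_mean_um /
                  mean(pop$truth$diameter_um[pel]) - 1), 0.05)
})

test_that("size exclusion and low-count flags surface as warnings", {
  pop <- generate_pulse_population(n = 30L, seed = 5L)
  s <- suppressMessages(summarize_population(pop$profiles, min_pellets = 50L,
                                             max_diameter_um = 200))
  expect_true(any(grepl("size exclusion", s$warnings)))
  expect_true(s$summary$below_min_pellets)
  expect_true(all(s$particles$signal_length_um <= 200))
})
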