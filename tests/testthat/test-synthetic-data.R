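# The generator is first-class code: its statistical contracts are what
# every downstream validation rests on.

test_that("identical config + seed reproduces the scene bit for bit", {
  cfg <- small_scene(seed = 42)
  s1 <- generate_fish_scene(cfg)
  s2 <- generate_fish_scene(cfg)
  expect_identical(s1$stack$voxels, s2$stack$voxels)
  expect_identical(s1$truth$foci, s2$truth$foci)
  s3 <- generate_fish_scene(small_scene(seed = 43))
  expect_false(identical(s1$stack$voxels, s3$stack$voxels))
})

test_that("noise-free focus rendering conserves intensity_per_length * L", {
  cfg <- quiet_noise(small_scene(seed = 3))
  cfg$telomeres_per_cell <- 1L
  cfg$rna_spots_per_cell <- 0L
  cfg$dapi_level <- 0
  sc <- generate_fish_scene(cfg)
  tr <- sc$truth$foci
  expect_equal(nrow(tr), 1L)
  total <- sum(get_channel(sc$stack, "telomere"))
  expect_lt(abs(total - 1000 * tr$length) / (1000 * tr$length), 0.01)
})

test_that("zero RNA spots give pure-background RNA channels", {
  cfg <- small_scene(seed = 5, rna_spots_per_cell = 0L)
  sc <- generate_fish_scene(cfg)
  expect_equal(sum(sc$truth$foci$channel %in% cfg$rna_channels), 0L)
  fs <- detect_foci(sc$stack, "terra")
  expect_equal(n_foci(fs), 0L)
})

test_that("p_rna_at_telomere == 1 places every RNA spot inside a telomere", {
  cfg <- small_scene(seed = 11, rna_spots_per_cell = 3L,
                     p_rna_at_telomere = function(len) rep(1, length(len)),
                     p_rna_pair = 0)
  sc <- generate_fish_scene(cfg)
  tr <- sc$truth$foci
  rna <- tr[tr$channel %in% cfg$rna_channels, ]
  expect_equal(nrow(rna), 6L)  # 3 per RNA channel
  expect_true(all(rna$at_telomere))
  d <- dim_zyx(sc$stack)
  vs <- sc$stack$voxel_size
  for (r in seq_len(nrow(rna))) {
    # point-in-object: the spot's voxel lies in its host telomere's
    # rendered support
    vox <- telotrack:::zyx_to_linear(
      matrix(round(c(rna$z_um[r], rna$y_um[r], rna$x_um[r]) / vs) + 1L, 1),
      d)
    host <- rna$partner_id[r]
    expect_false(is.na(host))
    expect_true(vox %in% sc$truth$voxels[[host]])
  }
})

test_that("ground truth row count equals planted object count", {
  cfg <- small_scene(seed = 8, telomeres_per_cell = 7L,
                     rna_spots_per_cell = 2L)
  sc <- generate_fish_scene(cfg)
  tr <- sc$truth$foci
  expect_equal(sum(tr$channel == "telomere"), 7L)  # doublet_fraction = 0
  expect_equal(sum(tr$channel == "terra"), 2L)
  expect_equal(sum(tr$channel == "htr"), 2L)
  expect_equal(length(sc$truth$voxels), nrow(tr))
  expect_equal(tr$object_id, seq_len(nrow(tr)))
})

test_that("placement errors surface when nuclei cannot fit", {
  expect_error(generate_fish_scene(
    scene_config(image_shape = c(8L, 40L, 40L), n_cells = 4L)),
    "placement error")
})

test_that("movie bleaching follows (1 - b)^t on a static noise-free scene", {
  scfg <- quiet_noise(movie_scene_config(telomeres_per_cell = 4L, seed = 2))
  kin <- kinetics_config(duration = 100, bleach_rate = 0.02,
                         diffusion_coeff = 0, k_on = 0, p_bound_init = 0,
                         n_particles = 1L, seed = 2)
  sim <- generate_live_movie(scfg, kin, render = TRUE)
  means <- vapply(sim$movie$frames,
                  function(f) mean(get_channel(f, "telomere")), numeric(1))
  expected <- means[1] * (1 - 0.02)^(seq_along(means) - 1)
  expect_equal(means, expected, tolerance = 1e-10)
})

test_that("pure-slow bound durations match the frame-quantized mean", {
  kin <- kinetics_config(p_fast = 0, tau_fast = 40, tau_slow = 40,
                         n_particles = 400L, duration = 600,
                         p_bound_init = 0.6, seed = 21)
  sim <- generate_live_movie(movie_scene_config(seed = 21), kin,
                             render = FALSE)
  done <- sim$truth$events[!sim$truth$events$censored, ]
  expect_gte(nrow(done), 500L)
  # ceiling-quantized Exp(40) at dt = 5: E = dt / (1 - exp(-dt/tau))
  expected <- 5 / (1 - exp(-5 / 40))
  se <- stats::sd(done$duration) / sqrt(nrow(done))
  expect_lt(abs(mean(done$duration) - expected), 3 * se)
})

test_that("immobile particle with no unbinding stays bound all movie", {
  kin <- kinetics_config(p_fast = 0, tau_fast = 1e9, tau_slow = 1e9,
                         diffusion_coeff = 0, p_bound_init = 1,
                         n_particles = 1L, duration = 100, seed = 3)
  sim <- generate_live_movie(movie_scene_config(seed = 3), kin,
                             render = FALSE)
  ev <- sim$truth$events
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start_frame, 0L)
  expect_equal(ev$end_frame, 20L)  # 100 s at 5 s -> frames 0..20
  expect_true(ev$censored)
  expect_true(all(sim$truth$tracks$bound))
})

test_that("config invariants are enforced", {
  expect_error(kinetics_config(frame_interval = 7, duration = 300),
               "divide")
  expect_error(kinetics_config(tau_fast = 50, tau_slow = 40), "tau_fast")
  expect_error(kinetics_config(p_fast = 1.2), "p_fast")
  expect_error(generate_live_movie(
    movie_scene_config(telomeres_per_cell = 0L), kinetics_config()),
    "config error")
  expect_error(scene_config(p_rna_at_telomere = function(l) 1 / (1 + l)),
               "non-decreasing")
})

test_that("sample_dwell_times: moments, censoring, determinism", {
  d <- sample_dwell_times(1e4, p_fast = 1, tau_fast = 10, tau_slow = 10,
                          seed = 4)
  expect_lt(abs(mean(d$duration) - 10), 0.3)
  expect_false(any(d$censored))

  # mixture moment at 3 * SE
  d2 <- sample_dwell_times(1e4, 0.6, 8, 40, seed = 5)
  mu <- 0.6 * 8 + 0.4 * 40
  se <- stats::sd(d2$duration) / sqrt(nrow(d2))
  expect_lt(abs(mean(d2$duration) - mu), 3 * se)

  d3 <- sample_dwell_times(100, 0.5, 5, 20, censor_at = 0, seed = 6)
  expect_true(all(d3$censored))
  expect_true(all(d3$duration == 0))

  expect_identical(sample_dwell_times(50, 0.5, 5, 20, seed = 7),
                   sample_dwell_times(50, 0.5, 5, 20, seed = 7))
  expect_error(sample_dwell_times(10, 0.5, -1, 20), "parameter error")
  expect_error(sample_dwell_times(0, 0.5, 1, 2), "positive")
})
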