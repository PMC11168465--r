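test_that("photobleaching correction inverts an exact geometric decay", {
  d <- c(1L, 4L, 16L, 16L)
  frames <- lapply(0:10, function(f) {
    image_stack(array(100 * (1 - 0.02)^f, d))
  })
  mv <- image_movie(frames, frame_interval = 5)
  out <- correct_photobleaching(mv)
  means <- vapply(out$frames, function(f) mean(get_channel(f, 1)), numeric(1))
  expect_equal(means, rep(means[1], length(means)), tolerance = 1e-6)
  expect_equal(means[1], 100, tolerance = 1e-6)  # frame-0 scale preserved
  expect_equal(attr(out, "bleach_rate"), 0.02, tolerance = 1e-6)

  const <- image_movie(lapply(1:5, function(i) image_stack(array(50, d))),
                       frame_interval = 5)
  out2 <- correct_photobleaching(const)
  expect_equal(out2$frames[[3]]$voxels, const$frames[[3]]$voxels,
               tolerance = 1e-12)

  single <- image_movie(list(image_stack(array(1, d))))
  expect_identical(correct_photobleaching(single)$frames,
                   single$frames)
})

test_that("bleach rate is recovered from a rendered noisy movie", {
  kin <- kinetics_config(duration = 150, bleach_rate = 0.02,
                         n_particles = 4L, seed = 12)
  sim <- generate_live_movie(movie_scene_config(image_shape = c(8L, 64L, 64L),
                                                nucleus_radius = c(1, 3.6, 3.6),
                                                telomeres_per_cell = 6L,
                                                seed = 12),
                             kin, render = TRUE)
  out <- correct_photobleaching(sim$movie)
  b_per_frame <- attr(out, "bleach_rate")
  expect_true(all(abs(b_per_frame - 0.02) / 0.02 < 0.1))
})

test_that("basic linking: single and well-separated particles", {
  det1 <- data.frame(frame = 0:9, z_um = 1, y_um = 2,
                     x_um = seq(0, 0.9, by = 0.1))
  tr1 <- link_detections(det1, max_disp = 0.5)
  expect_equal(length(unique(tr1$track_id)), 1L)
  expect_equal(nrow(tr1), 10L)

  det2 <- rbind(cbind(det1, id = 1),
                transform(det1, y_um = 10, id = 2))
  tr2 <- link_detections(det2[, c("frame", "z_um", "y_um", "x_um", "id")],
                         max_disp = 0.5)
  expect_equal(length(unique(tr2$track_id)), 2L)
  swaps <- tapply(tr2$id, tr2$track_id, function(v) length(unique(v)))
  expect_true(all(swaps == 1L))  # no identity swaps
  expect_error(link_detections(det1, max_disp = -1), "config error")
})

test_that("linking equals exhaustive min-cost matching on small instances", {
  for (seed in 1:5) {
    telotrack:::with_rng(seed, {
      n <- sample(2:5, 1)
      nf <- sample(5:10, 1)
      # well-separated starting points, small per-frame displacements
      start <- cbind(runif(n, 0, 1), seq(0, by = 4, length.out = n),
                     runif(n, 0, 10))
      steps <- array(runif(n * nf * 3, -0.25, 0.25), c(n, nf, 3))
      dets <- list()
      posn <- start
      for (f in seq_len(nf)) {
        if (f > 1) posn <- posn + steps[, f, ]
        dets[[f]] <- data.frame(frame = f - 1L, z_um = posn[, 1],
                                y_um = posn[, 2], x_um = posn[, 3],
                                truth = seq_len(n))
      }
      det <- do.call(rbind, dets)
    })
    got <- link_detections(det, max_disp = 1)
    # oracle: chain exhaustive per-frame optimal assignments
    oracle_id <- rep(NA_integer_, nrow(det))
    next_id <- 0L
    prev_rows <- NULL
    for (f in sort(unique(det$frame))) {
      rows <- which(det$frame == f)
      if (is.null(prev_rows)) {
        oracle_id[rows] <- seq_along(rows)
        next_id <- length(rows)
      } else {
        asg <- oracle_assign(as.matrix(det[prev_rows, c("z_um", "y_um", "x_um")]),
                             as.matrix(det[rows, c("z_um", "y_um", "x_um")]),
                             max_disp = 1)
        for (j in seq_along(rows)) {
          if (is.na(asg[j])) {
            next_id <- next_id + 1L
            oracle_id[rows[j]] <- next_id
          } else {
            oracle_id[rows[j]] <- oracle_id[prev_rows[asg[j]]]
          }
        }
      }
      prev_rows <- rows
    }
    # same partition of detections into tracks
    expect_equal(length(unique(got$track_id)), length(unique(oracle_id)))
    key_got <- tapply(seq_len(nrow(got)),
                      got$track_id, function(i) paste(sort(
                        paste(got$frame[i], got$truth[i])), collapse = ";"))
    ord <- order(det$frame)
    key_or <- tapply(seq_len(nrow(det)), oracle_id,
                     function(i) paste(sort(
                       paste(det$frame[i], det$truth[i])), collapse = ";"))
    expect_setequal(unname(key_got), unname(key_or))
  }
})

test_that("event durations and the 10-s stability rule", {
  tel <- data.frame(telomere_id = 1L, z_um = 0, y_um = 0, x_um = 0)
  tr3 <- data.frame(track_id = 1L, frame = 0:2, z_um = 0, y_um = 0, x_um = 0)
  ev3 <- assign_coloc_events(tr3, tel, frame_interval = 5)
  expect_equal(ev3$duration, 15)
  expect_true(ev3$stable)

  tr1 <- data.frame(track_id = 1L, frame = c(0L, 5L),
                    z_um = c(0, 5), y_um = 0, x_um = 0)
  ev1 <- assign_coloc_events(tr1, tel, frame_interval = 5)
  expect_equal(ev1$duration, 5)
  expect_false(ev1$stable)

  # durations are multiples of the frame interval; events of one track on
  # one telomere never overlap
  kin <- kinetics_config(n_particles = 40L, seed = 14, p_bound_init = 0.5)
  sim <- generate_live_movie(movie_scene_config(seed = 14), kin,
                             render = FALSE)
  ev <- assign_coloc_events(sim$truth$tracks, sim$truth$telomeres,
                            frame_interval = 5)
  expect_true(all(ev$duration %% 5 == 0))
  by_tt <- split(ev, paste(ev$track_id, ev$telomere_id))
  for (g in by_tt) {
    if (nrow(g) < 2) next
    g <- g[order(g$start_frame), ]
    expect_true(all(g$start_frame[-1] > g$end_frame[-nrow(g)]))
  }
  expect_equal(nrow(assign_coloc_events(sim$truth$tracks,
                                        sim$truth$telomeres[0, ])), 0L)
})

test_that("extracted events match generator truth boundaries", {
  kin <- kinetics_config(n_particles = 250L, seed = 9, duration = 600,
                         p_bound_init = 0.5)
  sim <- generate_live_movie(movie_scene_config(seed = 9), kin,
                             render = FALSE)
  ev_t <- sim$truth$events
  expect_gte(nrow(ev_t), 400L)
  ev_x <- assign_coloc_events(sim$truth$tracks, sim$truth$telomeres,
                              coloc_radius = 0.3, tolerance_gap = 0,
                              frame_interval = 5)
  ok <- 0L
  for (i in seq_len(nrow(ev_t))) {
    cand <- ev_x[ev_x$track_id == ev_t$track_id[i] &
                   ev_x$telomere_id == ev_t$telomere_id[i], ]
    hit <- abs(cand$start_frame - ev_t$start_frame[i]) <= 1 &
      abs(cand$end_frame - ev_t$end_frame[i]) <= 1
    if (any(hit)) ok <- ok + 1L
  }
  expect_gte(ok / nrow(ev_t), 0.95)
  # pooled dwell recovery: extracted mean within 10% of the quantized
  # mixture mean
  mix_mean <- with(kin, p_fast * 5 / (1 - exp(-5 / tau_fast)) +
                     (1 - p_fast) * 5 / (1 - exp(-5 / tau_slow)))
  got <- mean(ev_x$duration[!ev_x$censored])
  expect_lt(abs(got - mix_mean) / mix_mean, 0.10)
})

test_that("localization classes follow the 0.6-um precedence rules", {
  origin <- c(1, 5, 5)
  tels <- data.frame(z_um = c(1, 1), y_um = c(5, 5), x_um = c(5, 8))
  obs <- data.frame(z_um = c(1, 1, 1, 1.9, 1),
                    y_um = c(5, 5.5, 5.7, 5.5, 5),
                    x_um = c(5, 5, 5, 5, 8))
  cls <- classify_localization(obs, origin, tels)
  expect_equal(as.character(cls),
               c("origin_telomere",   # distance 0
                 "origin_proximal",   # 0.5 um, same slice
                 "nontelomeric",      # 0.7 um: beyond proximity
                 "nontelomeric",      # 0.5 um lateral but other z slice
                 "other_telomere"))   # on the non-origin telomere, 3 um away
  # precedence is total: every observation gets exactly one class
  telotrack:::with_rng(5, {
    robs <- data.frame(z_um = runif(50, 0, 2), y_um = runif(50, 0, 10),
                       x_um = runif(50, 0, 10))
  })
  rc <- classify_localization(robs, origin, tels)
  expect_false(any(is.na(rc)))
  # no origin: restricted classes
  cls2 <- classify_localization(obs, NULL, tels)
  expect_true(all(as.character(cls2) %in%
                    c("other_telomere", "nontelomeric")))
})

test_that("cis/trans summary reproduces hand percentages", {
  cls <- factor(rep(c("origin_telomere", "origin_proximal",
                      "other_telomere", "nontelomeric"),
                    c(4, 3, 57, 344)),
                levels = telotrack:::localization_levels)
  s <- summarize_cis_trans(cls)
  expect_equal(round(s$cis_percent, 1), 1.7)
  expect_equal(round(s$percent[["other_telomere"]], 1), 14.0)
  expect_equal(round(s$percent[["nontelomeric"]], 1), 84.3)
  all_origin <- factor(rep("origin_telomere", 10),
                       levels = telotrack:::localization_levels)
  expect_equal(summarize_cis_trans(all_origin)$cis_percent, 100)
  expect_error(summarize_cis_trans(factor(character(0))), "no classified")
})

test_that("other-telomere occupancy of random particles matches geometry", {
  # geometric Monte Carlo: uniform particles in an ellipsoid vs the
  # grid-computed volume fraction within the overlap radius of telomeres
  cen <- c(1.5, 6, 6); rad <- c(1.2, 5, 5)
  telotrack:::with_rng(8, {
    tel <- telotrack:::runif_ellipsoid(15, cen, 0.8 * rad)
    pts <- telotrack:::runif_ellipsoid(4000, cen, rad)
  })
  tel_df <- as.data.frame(tel); names(tel_df) <- c("z_um", "y_um", "x_um")
  obs <- as.data.frame(pts); names(obs) <- c("z_um", "y_um", "x_um")
  cls <- classify_localization(obs, NULL, tel_df, overlap_radius = 0.3)
  got <- mean(cls == "other_telomere")
  # independent grid oracle for the covered volume fraction
  gr <- expand.grid(z = seq(cen[1] - rad[1], cen[1] + rad[1], by = 0.08),
                    y = seq(cen[2] - rad[2], cen[2] + rad[2], by = 0.08),
                    x = seq(cen[3] - rad[3], cen[3] + rad[3], by = 0.08))
  inside <- rowSums(sweep(sweep(as.matrix(gr), 2, cen, "-"), 2, rad,
                          "/")^2) <= 1
  gm <- as.matrix(gr[inside, ])
  dmin <- apply(telotrack:::cross_dist_um(gm, tel), 1, min)
  f <- mean(dmin <= 0.3)
  se <- sqrt(f * (1 - f) / 4000)
  expect_lt(abs(got - f), 3 * se + 0.01)  # grid oracle has ~0.08-um bias
})

test_that("percent of telomeres with stable tracks", {
  ev0 <- data.frame(telomere_id = integer(0), stable = logical(0))
  expect_equal(percent_telomeres_colocalized(ev0, 1:5), 0)
  ev <- data.frame(telomere_id = 1:5, stable = TRUE)
  expect_equal(percent_telomeres_colocalized(ev, 1:5), 100)
  ev2 <- data.frame(telomere_id = c(1, 2), stable = c(TRUE, FALSE))
  expect_equal(percent_telomeres_colocalized(ev2, 1:4), 25)
  expect_error(percent_telomeres_colocalized(ev, integer(0)), "zero")
})

test_that("telomere occupancy rises with the binding rate", {
  # at k_on >> 1/dt binding saturates within one 5-s frame, so the probe
  # regime is k_on below ~0.2/s
  pct <- vapply(c(0.05, 0.1), function(kon) {
    kin <- kinetics_config(k_on = kon, n_particles = 120L,
                           p_bound_init = 0, seed = 19)
    sim <- generate_live_movie(movie_scene_config(seed = 19), kin,
                               render = FALSE)
    ev <- assign_coloc_events(sim$truth$tracks, sim$truth$telomeres,
                              frame_interval = 5)
    percent_telomeres_colocalized(ev, sim$truth$telomeres$telomere_id)
  }, numeric(1))
  expect_gt(pct[2], pct[1])
})
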