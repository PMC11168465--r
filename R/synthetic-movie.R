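#' Configuration for synthetic live-cell particle kinetics
#'
#' Parameters of the two-state (free diffusion / telomere-bound) particle
#' model used by [generate_live_movie()]. Bound durations are drawn from a
#' two-component exponential mixture
#' `p_fast * Exp(1/tau_fast) + (1 - p_fast) * Exp(1/tau_slow)`, mirroring
#' the probing/binding phases resolved by dwell-time survival analysis.
#'
#' @param frame_interval seconds between frames (default 5, the acquisition
#'   cadence the dwell analysis assumes).
#' @param duration total movie duration in seconds (default 300, i.e. 5
#'   minutes); must be a multiple of `frame_interval`.
#' @param diffusion_coeff free-diffusion coefficient, um^2/s (default
#'   0.05: chromatin-proximal RNP mobility; at the 5-s cadence faster
#'   diffusion makes free segments unlinkable, as in real acquisitions).
#' @param p_bound_init probability that a particle starts the movie bound
#'   to a random telomere (default 0.35, the telomere occupancy scale
#'   seen in live telomerase imaging).
#' @param p_fast fraction of binding events in the fast (probing)
#'   population.
#' @param tau_fast,tau_slow mean bound durations in seconds;
#'   `tau_fast <= tau_slow`.
#' @param k_on per-second binding rate while within `capture_radius` of a
#'   telomere.
#' @param bleach_rate per-frame fractional intensity loss (multiplicative
#'   `(1 - bleach_rate)^frame`).
#' @param capture_radius um within which a free particle can bind.
#' @param bound_jitter um s.d. of the particle position around the telomere
#'   centroid while bound (small, so the proximity rules stay meaningful).
#' @param n_particles particles per nucleus.
#' @param seed integer RNG seed.
#' @return An object of class `kinetics_config`.
#' @export
kinetics_config <- function(frame_interval = 5,
                            duration = 300,
                            diffusion_coeff = 0.05,
                            p_fast = 0.6,
                            tau_fast = 8,
                            tau_slow = 40,
                            k_on = 5,
                            bleach_rate = 0.01,
                            capture_radius = 0.3,
                            bound_jitter = 0.05,
                            p_bound_init = 0.35,
                            n_particles = 12L,
                            seed = 1L) {
  cfg <- list(frame_interval = frame_interval, duration = duration,
              diffusion_coeff = diffusion_coeff, p_fast = p_fast,
              tau_fast = tau_fast, tau_slow = tau_slow, k_on = k_on,
              bleach_rate = bleach_rate, capture_radius = capture_radius,
              bound_jitter = bound_jitter, p_bound_init = p_bound_init,
              n_particles = as.integer(n_particles), seed = as.integer(seed))
  validate_kinetics_config(cfg)
}

validate_kinetics_config <- function(cfg) {
  stopifnot(cfg$frame_interval > 0, cfg$duration > 0)
  if (abs(cfg$duration / cfg$frame_interval -
          round(cfg$duration / cfg$frame_interval)) > 1e-9) {
    stop("frame_interval must divide duration")
  }
  if (cfg$p_fast < 0 || cfg$p_fast > 1) stop("p_fast must be in [0, 1]")
  if (cfg$tau_fast <= 0 || cfg$tau_slow <= 0) {
    stop("parameter error: tau values must be positive")
  }
  if (cfg$tau_fast > cfg$tau_slow) stop("tau_fast must be <= tau_slow")
  stopifnot(cfg$k_on >= 0, cfg$bleach_rate >= 0, cfg$bleach_rate < 1,
            cfg$diffusion_coeff >= 0, cfg$capture_radius >= 0,
            cfg$n_particles >= 0,
            cfg$p_bound_init >= 0, cfg$p_bound_init <= 1)
  structure(cfg, class = "kinetics_config")
}

#' Sample dwell times from a two-component exponential mixture
#'
#' I.i.d. draws from
#' `p_fast * Exp(1/tau_fast) + (1 - p_fast) * Exp(1/tau_slow)`,
#' right-censored at `censor_at` (censored draws are returned as
#' `censor_at` with `censored = TRUE`).
#'
#' @param n number of draws (> 0).
#' @param p_fast mixture weight of the fast component.
#' @param tau_fast,tau_slow component means in seconds (> 0).
#' @param censor_at censoring time in seconds (default `Inf`).
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return data.frame with `duration`, `censored`, `population`
#'   ("fast"/"slow").
#' @examples
#' d <- sample_dwell_times(5, 0.6, 8, 40, seed = 1)
#' @export
sample_dwell_times <- function(n, p_fast, tau_fast, tau_slow,
                               censor_at = Inf, seed = NULL) {
  if (n <= 0) stop("n must be positive")
  if (tau_fast <= 0 || tau_slow <= 0) {
    stop("parameter error: tau values must be positive")
  }
  if (p_fast < 0 || p_fast > 1) stop("p_fast must be in [0, 1]")
  if (censor_at < 0) stop("censor_at must be non-negative")
  with_rng(seed, {
    fast <- stats::runif(n) < p_fast
    dur <- ifelse(fast, stats::rexp(n, 1 / tau_fast),
                  stats::rexp(n, 1 / tau_slow))
    cens <- dur >= censor_at
    dur[cens] <- censor_at
    data.frame(duration = dur, censored = cens,
               population = ifelse(fast, "fast", "slow"))
  })
}

#' Scene defaults suited to live-cell movies
#'
#' A single nucleus in a smaller field of view (one cell is imaged at a
#' time in live tracking), with the same voxel geometry, PSF and noise
#' model as [scene_config()].
#'
#' @param ... overrides passed to [scene_config()].
#' @return a `scene_config`.
#' @export
movie_scene_config <- function(...) {
  defaults <- list(image_shape = c(10L, 96L, 96L), n_cells = 1L,
                   nucleus_radius = c(1.2, 5.5, 5.5),
                   telomeres_per_cell = 20L, rna_spots_per_cell = 0L)
  args <- utils::modifyList(defaults, list(...))
  do.call(scene_config, args)
}

reflect_into_ellipsoid <- function(pos, center, radius) {
  rel <- (pos - center) / radius
  r2 <- sum(rel^2)
  if (r2 > 1) {
    pos <- center + rel / sqrt(r2) * radius * 0.98
  }
  pos
}

#' Generate a synthetic two-channel live-cell movie with ground truth
#'
#' Simulates particles alternating between free diffusion inside the
#' nucleus and telomere-bound states whose durations follow the
#' [kinetics_config()] exponential mixture, applies per-frame
#' multiplicative photobleaching, and (optionally) renders the particle and
#' telomere channels with PSF blur and noise. The ground truth lists every
#' frame-wise position, bound-state interval and population label.
#'
#' Bound intervals occupy a whole number of frames
#' (`ceiling(duration_cont / frame_interval)`), so true durations are sums
#' of consecutive bound frames times the frame interval.
#'
#' @param scene a [scene_config()] describing geometry, telomeres, PSF and
#'   noise. `n_cells` nuclei are simulated independently.
#' @param kin a [kinetics_config()].
#' @param render if `FALSE`, skip image rendering and return ground truth
#'   only (fast path for statistical tests).
#' @return list of class `live_movie` with `movie` (an [image_movie()] with
#'   channels `particle`, `telomere`; `NULL` when `render = FALSE`),
#'   `truth` (`tracks`, `events`, `telomeres` data.frames) and the two
#'   configs. Event durations are in seconds; `censored` marks events cut
#'   by the movie end.
#' @export
generate_live_movie <- function(scene = movie_scene_config(),
                                kin = kinetics_config(),
                                render = TRUE) {
  scfg <- validate_scene_config(scene)
  kcfg <- validate_kinetics_config(kin)
  tel_counts <- count_per_cell(scfg$telomeres_per_cell, scfg$n_cells)
  if (kcfg$k_on > 0 && all(tel_counts == 0)) {
    stop("config error: k_on > 0 requires at least one telomere")
  }
  with_rng(kcfg$seed, generate_live_movie_impl(scfg, kcfg, render))
}

generate_live_movie_impl <- function(scfg, kcfg, render) {
  dt <- kcfg$frame_interval
  n_frames <- as.integer(round(kcfg$duration / dt)) + 1L
  centers <- nucleus_centers(scfg)
  tel_counts <- count_per_cell(scfg$telomeres_per_cell, scfg$n_cells)

  telomeres <- list()
  tid <- 0L
  for (cell in seq_len(scfg$n_cells)) {
    if (tel_counts[cell] == 0L) next
    pos <- runif_ellipsoid(tel_counts[cell], centers[cell, ],
                           0.85 * scfg$nucleus_radius)
    len <- stats::rlnorm(tel_counts[cell], scfg$telomere_length_meanlog,
                         scfg$telomere_length_sdlog)
    for (j in seq_len(tel_counts[cell])) {
      tid <- tid + 1L
      telomeres[[tid]] <- data.frame(telomere_id = tid, cell_id = cell,
                                     z_um = pos[j, 1], y_um = pos[j, 2],
                                     x_um = pos[j, 3], length = len[j])
    }
  }
  telomeres <- if (tid > 0) do.call(rbind, telomeres) else
    data.frame(telomere_id = integer(0), cell_id = integer(0),
               z_um = numeric(0), y_um = numeric(0), x_um = numeric(0),
               length = numeric(0))

  sd_step <- sqrt(2 * kcfg$diffusion_coeff * dt)
  tracks <- list()
  events <- list()
  ev_id <- 0L
  pid <- 0L
  for (cell in seq_len(scfg$n_cells)) {
    tel_cell <- telomeres[telomeres$cell_id == cell, , drop = FALSE]
    tel_pos <- as.matrix(tel_cell[, c("z_um", "y_um", "x_um")])
    for (p in seq_len(kcfg$n_particles)) {
      pid <- pid + 1L
      pos <- drop(runif_ellipsoid(1, centers[cell, ],
                                  0.9 * scfg$nucleus_radius))
      bound_left <- 0L       # frames remaining in the current bound state
      bound_tel <- NA_integer_
      bound_pop <- NA_character_
      ev_start <- NA_integer_
      if (nrow(tel_pos) > 0 && kcfg$k_on > 0 &&
          stats::runif(1) < kcfg$p_bound_init) {
        bound_tel <- sample.int(nrow(tel_pos), 1L)
        fast <- stats::runif(1) < kcfg$p_fast
        bound_pop <- if (fast) "fast" else "slow"
        tau <- if (fast) kcfg$tau_fast else kcfg$tau_slow
        bound_left <- max(1L, as.integer(
          ceiling(stats::rexp(1, 1 / tau) / dt)))
        ev_start <- 1L
      }
      rows <- matrix(NA_real_, n_frames, 3)
      bflag <- logical(n_frames)
      btel <- rep(NA_integer_, n_frames)
      bpop <- rep(NA_character_, n_frames)
      for (f in seq_len(n_frames)) {
        if (bound_left == 0L) {
          # free: diffuse, then possibly bind within this frame (the
          # particle reaches the telomere during the interval, so the
          # frame itself is already a bound observation)
          if (f > 1L && kcfg$diffusion_coeff > 0) {
            pos <- pos + stats::rnorm(3, sd = sd_step)
            pos <- reflect_into_ellipsoid(pos, centers[cell, ],
                                          scfg$nucleus_radius)
          }
          if (nrow(tel_pos) > 0 && kcfg$k_on > 0) {
            dists <- sqrt(colSums((t(tel_pos) - pos)^2))
            near <- which.min(dists)
            if (dists[near] <= kcfg$capture_radius &&
                stats::runif(1) < 1 - exp(-kcfg$k_on * dt)) {
              bound_tel <- near
              fast <- stats::runif(1) < kcfg$p_fast
              bound_pop <- if (fast) "fast" else "slow"
              tau <- if (fast) kcfg$tau_fast else kcfg$tau_slow
              bound_left <- max(1L, as.integer(
                ceiling(stats::rexp(1, 1 / tau) / dt)))
              ev_start <- f
            }
          }
        }
        if (bound_left > 0L) {
          pos <- tel_pos[bound_tel, ] +
            stats::rnorm(3, sd = kcfg$bound_jitter)
          bflag[f] <- TRUE
          btel[f] <- tel_cell$telomere_id[bound_tel]
          bpop[f] <- bound_pop
          bound_left <- bound_left - 1L
          if (bound_left == 0L || f == n_frames) {
            ev_id <- ev_id + 1L
            events[[ev_id]] <- data.frame(
              event_id = ev_id, track_id = pid,
              telomere_id = tel_cell$telomere_id[bound_tel],
              start_frame = ev_start - 1L, end_frame = f - 1L,
              n_frames = f - ev_start + 1L,
              duration = (f - ev_start + 1L) * dt,
              population = bound_pop,
              censored = bound_left > 0L)
            if (bound_left == 0L) {
              bound_tel <- NA_integer_
              bound_pop <- NA_character_
            }
          }
        }
        rows[f, ] <- pos
      }
      tracks[[pid]] <- data.frame(
        track_id = pid, cell_id = cell, frame = seq_len(n_frames) - 1L,
        t_s = (seq_len(n_frames) - 1L) * dt,
        z_um = rows[, 1], y_um = rows[, 2], x_um = rows[, 3],
        bound = bflag, telomere_id = btel, population = bpop)
    }
  }
  tracks <- if (pid > 0) do.call(rbind, tracks) else
    data.frame(track_id = integer(0), cell_id = integer(0),
               frame = integer(0), t_s = numeric(0), z_um = numeric(0),
               y_um = numeric(0), x_um = numeric(0), bound = logical(0),
               telomere_id = integer(0), population = character(0))
  events <- if (ev_id > 0) do.call(rbind, events) else
    data.frame(event_id = integer(0), track_id = integer(0),
               telomere_id = integer(0), start_frame = integer(0),
               end_frame = integer(0), n_frames = integer(0),
               duration = numeric(0), population = character(0),
               censored = logical(0))
  rownames(tracks) <- NULL

  movie <- NULL
  if (render) {
    sd_bg <- max(scene_noise_sd(scfg), 1)
    amp <- scfg$snr * sd_bg / psf_peak_fraction(scfg$psf_sigma, scfg$voxel_size)
    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      decay <- (1 - kcfg$bleach_rate)^(f - 1L)
      ap <- array(scfg$background, scfg$image_shape)
      at <- array(scfg$background, scfg$image_shape)
      tf <- tracks[tracks$frame == f - 1L, , drop = FALSE]
      for (r in seq_len(nrow(tf))) {
        ap <- render_emitter(ap, c(tf$z_um[r], tf$y_um[r], tf$x_um[r]),
                             amp, scfg$psf_sigma, scfg$voxel_size)
      }
      c_per_len <- scene_intensity_per_length(scfg)
      for (r in seq_len(nrow(telomeres))) {
        at <- render_emitter(at, c(telomeres$z_um[r], telomeres$y_um[r],
                                   telomeres$x_um[r]),
                             c_per_len * telomeres$length[r],
                             scfg$psf_sigma, scfg$voxel_size)
      }
      ap <- apply_scene_noise(ap * decay, scfg)
      at <- apply_scene_noise(at * decay, scfg)
      vox <- array(0, c(2L, scfg$image_shape))
      vox[1, , , ] <- ap
      vox[2, , , ] <- at
      frames[[f]] <- image_stack(vox, voxel_size = scfg$voxel_size,
                                 channel_names = c("particle", "telomere"))
    }
    movie <- image_movie(frames, frame_interval = dt)
  }

  structure(list(movie = movie,
                 truth = list(tracks = tracks, events = events,
                              telomeres = telomeres),
                 scene_config = scfg, kinetics_config = kcfg),
            class = "live_movie")
}
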