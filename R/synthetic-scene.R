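#' Configuration for a synthetic multi-channel FISH scene
#'
#' Describes the statistical world the generator renders: ellipsoidal nuclei
#' on a regular grid, dozens of telomere foci per nucleus with log-normal
#' "length" (kb-equivalents) driving their integrated intensity, sparse RNA
#' spots placed at telomeres with a length-dependent probability, an
#' anisotropic Gaussian PSF, and Poisson + Gaussian read noise.
#'
#' @param image_shape integer length-3 `(z, y, x)` voxel counts.
#' @param voxel_size um per voxel `(z, y, x)`; defaults to a confocal
#'   acquisition with a 0.3-um z step and 0.133-um pixels.
#' @param n_cells number of nuclei, laid out on a regular grid.
#' @param telomeres_per_cell integer, or function(n_cells) returning counts.
#' @param telomere_length_meanlog,telomere_length_sdlog log-normal
#'   parameters of the per-focus length in kb-equivalents (defaults
#'   `log(5)` and `0.5`, giving the strongly right-skewed integrated-density
#'   distributions typical of telomere IF).
#' @param intensity_per_length photons per kb-equivalent. `NULL` derives it
#'   from `snr` so that the median-length focus has peak amplitude
#'   `snr` times the background noise s.d.
#' @param snr target peak signal-to-noise ratio of a median focus
#'   (default 10).
#' @param rna_spots_per_cell integer, or function(n_cells) returning counts,
#'   applied to each RNA channel.
#' @param rna_channels character names of the RNA channels (two by default,
#'   mimicking a dual-color RNA FISH experiment).
#' @param p_rna_at_telomere function(length) in \[0, 1\], non-decreasing:
#'   probability that an RNA spot offered to a telomere of that length is
#'   placed on it rather than in the nucleoplasm.
#' @param p_rna_pair probability that a spot in the second (and later) RNA
#'   channel is co-placed on a spot of the first RNA channel, creating a
#'   planted RNA-RNA colocalization.
#' @param doublet_fraction fraction of telomere foci planted as doublets:
#'   two emitters separated by 0.5-1.5 x the lateral PSF FWHM.
#' @param psf_sigma Gaussian PSF sigma in um `(z, y, x)`; axial larger than
#'   lateral, matching confocal anisotropy.
#' @param nucleus_radius ellipsoid semi-axes in um `(z, y, x)`.
#' @param background constant background level (photons).
#' @param gain Poisson gain; 0 disables shot noise.
#' @param read_sd Gaussian read-noise s.d.; 0 disables.
#' @param dapi_level DAPI channel plateau intensity inside nuclei.
#' @param seed integer RNG seed; identical config + seed reproduces the
#'   scene bit for bit.
#' @return An object of class `scene_config` (a validated list).
#' @export
scene_config <- function(image_shape = c(16L, 224L, 224L),
                         voxel_size = c(0.3, 0.133, 0.133),
                         n_cells = 4L,
                         telomeres_per_cell = 25L,
                         telomere_length_meanlog = log(5),
                         telomere_length_sdlog = 0.5,
                         intensity_per_length = NULL,
                         snr = 10,
                         rna_spots_per_cell = 5L,
                         rna_channels = c("terra", "htr"),
                         p_rna_at_telomere = function(len) 0.6 * stats::plogis((len - 5) / 2),
                         p_rna_pair = 0.3,
                         doublet_fraction = 0.07,
                         psf_sigma = c(0.4, 0.17, 0.17),
                         nucleus_radius = c(1.8, 6.9, 6.9),
                         background = 10,
                         gain = 1,
                         read_sd = 3,
                         dapi_level = 150,
                         seed = 1L) {
  cfg <- list(image_shape = as.integer(image_shape),
              voxel_size = as.numeric(voxel_size),
              n_cells = as.integer(n_cells),
              telomeres_per_cell = telomeres_per_cell,
              telomere_length_meanlog = telomere_length_meanlog,
              telomere_length_sdlog = telomere_length_sdlog,
              intensity_per_length = intensity_per_length,
              snr = snr,
              rna_spots_per_cell = rna_spots_per_cell,
              rna_channels = rna_channels,
              p_rna_at_telomere = p_rna_at_telomere,
              p_rna_pair = p_rna_pair,
              doublet_fraction = doublet_fraction,
              psf_sigma = as.numeric(psf_sigma),
              nucleus_radius = as.numeric(nucleus_radius),
              background = background,
              gain = gain,
              read_sd = read_sd,
              dapi_level = dapi_level,
              seed = as.integer(seed))
  validate_scene_config(cfg)
}

validate_scene_config <- function(cfg) {
  stopifnot(length(cfg$image_shape) == 3L, all(cfg$image_shape >= 1L))
  if (any(cfg$voxel_size <= 0) || any(cfg$psf_sigma <= 0) ||
      any(cfg$nucleus_radius <= 0)) {
    stop("voxel_size, psf_sigma and nucleus_radius must be positive")
  }
  stopifnot(cfg$n_cells >= 1L, cfg$background >= 0, cfg$gain >= 0,
            cfg$read_sd >= 0, cfg$doublet_fraction >= 0,
            cfg$doublet_fraction <= 1,
            cfg$p_rna_pair >= 0, cfg$p_rna_pair <= 1)
  if (!is.function(cfg$p_rna_at_telomere)) {
    stop("p_rna_at_telomere must be a function of length")
  }
  probe <- cfg$p_rna_at_telomere(c(0.5, 1, 2, 5, 10, 20, 50))
  if (any(probe < 0) || any(probe > 1) || any(diff(probe) < -1e-12)) {
    stop("p_rna_at_telomere must map into [0,1] and be non-decreasing")
  }
  structure(cfg, class = "scene_config")
}

count_per_cell <- function(spec, n_cells) {
  if (is.function(spec)) {
    as.integer(spec(n_cells))
  } else {
    rep(as.integer(spec), n_cells)
  }
}

# Peak fraction of the discretized, unit-sum PSF kernel: what fraction of a
# focus's total intensity lands in its brightest voxel.
psf_peak_fraction <- function(psf_sigma, voxel_size) {
  f <- 1
  for (a in 1:3) {
    s <- psf_sigma[a] / voxel_size[a]
    r <- max(1L, ceiling(4 * s))
    k <- stats::dnorm(seq(-r, r), sd = s)
    f <- f * max(k) / sum(k)
  }
  f
}

scene_noise_sd <- function(cfg) {
  sqrt(cfg$background * cfg$gain + cfg$read_sd^2)
}

scene_intensity_per_length <- function(cfg) {
  if (!is.null(cfg$intensity_per_length)) return(cfg$intensity_per_length)
  sd_bg <- scene_noise_sd(cfg)
  if (sd_bg == 0) sd_bg <- 1  # noise-free: arbitrary positive scale
  med_len <- exp(cfg$telomere_length_meanlog)
  cfg$snr * sd_bg / (psf_peak_fraction(cfg$psf_sigma, cfg$voxel_size) * med_len)
}

# Centers of nuclei on a regular grid; errors if the requested ellipsoids
# cannot be placed without touching each other or the image border.
nucleus_centers <- function(cfg) {
  d <- cfg$image_shape
  vs <- cfg$voxel_size
  ext <- (d - 1) * vs  # physical extent, um
  ncol_grid <- ceiling(sqrt(cfg$n_cells))
  nrow_grid <- ceiling(cfg$n_cells / ncol_grid)
  pitch_y <- ext[2] / nrow_grid
  pitch_x <- ext[3] / ncol_grid
  if (pitch_y < 2 * cfg$nucleus_radius[2] || pitch_x < 2 * cfg$nucleus_radius[3] ||
      ext[1] < 2 * cfg$nucleus_radius[1]) {
    stop("placement error: image too small for the requested nuclei")
  }
  centers <- matrix(0, cfg$n_cells, 3)
  for (i in seq_len(cfg$n_cells)) {
    gy <- (i - 1) %/% ncol_grid
    gx <- (i - 1) %% ncol_grid
    centers[i, ] <- c(ext[1] / 2,
                      (gy + 0.5) * pitch_y,
                      (gx + 0.5) * pitch_x)
  }
  colnames(centers) <- c("z_um", "y_um", "x_um")
  centers
}

# Uniform points inside an axis-aligned ellipsoid (rejection sampling).
runif_ellipsoid <- function(n, center, radius) {
  out <- matrix(NA_real_, n, 3)
  got <- 0L
  while (got < n) {
    m <- max(2L * (n - got), 8L)
    cand <- cbind(stats::runif(m, -1, 1), stats::runif(m, -1, 1),
                  stats::runif(m, -1, 1))
    keep <- rowSums(cand^2) <= 1
    cand <- cand[keep, , drop = FALSE]
    take <- min(nrow(cand), n - got)
    if (take > 0) {
      out[(got + 1):(got + take), ] <- cand[seq_len(take), , drop = FALSE]
      got <- got + take
    }
  }
  sweep(sweep(out, 2, radius, "*"), 2, center, "+")
}

# Render one emitter into `arr` (3D, z/y/x): separable Gaussian with unit sum
# over its support box, scaled to `total` intensity. Returns the updated
# array; records support voxels (> 1% of kernel peak) in the environment
# `support_env` under `id` when given.
render_emitter <- function(arr, center_um, total, psf_sigma, voxel_size,
                           support_env = NULL, id = NULL) {
  d <- dim(arr)
  cvox <- center_um / voxel_size + 1  # fractional voxel coordinates
  ks <- vector("list", 3)
  rng <- vector("list", 3)
  for (a in 1:3) {
    s <- psf_sigma[a] / voxel_size[a]
    r <- max(1L, ceiling(4 * s))
    lo <- max(1L, floor(cvox[a]) - r)
    hi <- min(d[a], ceiling(cvox[a]) + r)
    if (lo > hi) return(arr)  # fully outside the image
    idx <- lo:hi
    ks[[a]] <- stats::dnorm(idx - cvox[a], sd = s)
    rng[[a]] <- idx
  }
  kern <- outer(outer(ks[[1]], ks[[2]]), ks[[3]])
  kern <- kern / sum(kern) * total
  arr[rng[[1]], rng[[2]], rng[[3]]] <-
    arr[rng[[1]], rng[[2]], rng[[3]]] + kern
  if (!is.null(support_env)) {
    sup <- which(kern > 0.01 * max(kern))
    co <- arrayInd(sup, dim(kern))
    co[, 1] <- co[, 1] + rng[[1]][1] - 1L
    co[, 2] <- co[, 2] + rng[[2]][1] - 1L
    co[, 3] <- co[, 3] + rng[[3]][1] - 1L
    support_env$voxels[[id]] <- zyx_to_linear(co, d)
  }
  arr
}

apply_scene_noise <- function(arr, cfg) {
  if (cfg$gain > 0) {
    arr[] <- stats::rpois(length(arr), arr / cfg$gain) * cfg$gain
  }
  if (cfg$read_sd > 0) {
    arr[] <- arr + stats::rnorm(length(arr), sd = cfg$read_sd)
  }
  arr[arr < 0] <- 0
  arr
}

#' Generate a synthetic multi-channel FISH scene with ground truth
#'
#' Renders a DAPI channel (ellipsoidal nuclei), a telomere channel whose
#' per-focus total intensity is proportional to the focus's true length
#' before noise, and one or more RNA channels whose spots sit on telomeres
#' with a length-dependent probability. Every planted object is listed in
#' the ground-truth table; rendered support voxel sets are returned for
#' point-in-object checks.
#'
#' @param config a [scene_config()].
#' @return A list of class `fish_scene` with elements:
#'   * `stack`: an [image_stack()] with channels
#'     `dapi`, `telomere`, then the RNA channels;
#'   * `truth`: list with `cells` (nucleus centers/radii), `foci`
#'     (one row per planted emitter: `cell_id`, `channel`, `object_id`,
#'     `z_um`, `y_um`, `x_um`, `length`, `intensity`, `doublet_id`,
#'     `at_telomere`, `partner_id`) and `voxels` (per-emitter rendered
#'     support, linear indices into a `(z, y, x)` array);
#'   * `config`: the config used.
#' @examples
#' sc <- generate_fish_scene(scene_config(n_cells = 1, image_shape = c(12, 80, 80),
#'                                        telomeres_per_cell = 5, seed = 2))
#' nrow(sc$truth$foci)
#' @export
generate_fish_scene <- function(config = scene_config()) {
  cfg <- validate_scene_config(config)
  with_rng(cfg$seed, generate_fish_scene_impl(cfg))
}

generate_fish_scene_impl <- function(cfg) {
  d <- cfg$image_shape
  vs <- cfg$voxel_size
  centers <- nucleus_centers(cfg)
  c_per_len <- scene_intensity_per_length(cfg)
  channels <- c("dapi", "telomere", cfg$rna_channels)
  arrs <- lapply(channels, function(ch) array(cfg$background, d))
  names(arrs) <- channels

  # DAPI: plateau inside each nucleus ellipsoid, lightly blurred
  co_all <- arrayInd(seq_len(prod(d)), d)
  pos_um <- coords_to_um(co_all, vs)
  for (i in seq_len(nrow(centers))) {
    rel <- sweep(pos_um, 2, centers[i, ], "-")
    rel <- sweep(rel, 2, cfg$nucleus_radius, "/")
    inside <- rowSums(rel^2) <= 1
    arrs$dapi[inside] <- arrs$dapi[inside] + cfg$dapi_level
  }
  arrs$dapi <- gaussian_blur_3d(arrs$dapi, cfg$psf_sigma / vs)

  support_env <- new.env()
  support_env$voxels <- list()
  foci <- list()
  oid <- 0L
  fwhm_xy <- 2.3548 * cfg$psf_sigma[2]
  n_tel <- count_per_cell(cfg$telomeres_per_cell, cfg$n_cells)
  n_rna <- count_per_cell(cfg$rna_spots_per_cell, cfg$n_cells)

  add_focus <- function(cell, channel, pos, len, total, doublet_id,
                        at_tel, partner) {
    oid <<- oid + 1L
    foci[[oid]] <<- data.frame(
      cell_id = cell, channel = channel, object_id = oid,
      z_um = pos[1], y_um = pos[2], x_um = pos[3],
      length = len, intensity = total,
      doublet_id = doublet_id, at_telomere = at_tel,
      partner_id = partner, stringsAsFactors = FALSE)
    oid
  }

  tel_ids_by_cell <- vector("list", cfg$n_cells)
  for (cell in seq_len(cfg$n_cells)) {
    n <- n_tel[cell]
    if (n == 0L) next
    pos <- runif_ellipsoid(n, centers[cell, ], 0.85 * cfg$nucleus_radius)
    dbl <- stats::runif(n) < cfg$doublet_fraction
    dbl_counter <- 0L
    ids <- integer(0)
    for (j in seq_len(n)) {
      len <- stats::rlnorm(1, cfg$telomere_length_meanlog,
                           cfg$telomere_length_sdlog)
      if (dbl[j]) {
        dbl_counter <- dbl_counter + 1L
        did <- sprintf("c%d_d%d", cell, dbl_counter)
        sep <- stats::runif(1, 0.5, 1.5) * fwhm_xy
        theta <- stats::runif(1, 0, 2 * pi)
        off <- c(0, sin(theta), cos(theta)) * (sep / 2)
        len2 <- stats::rlnorm(1, cfg$telomere_length_meanlog,
                              cfg$telomere_length_sdlog)
        for (pp in list(list(p = pos[j, ] + off, l = len),
                        list(p = pos[j, ] - off, l = len2))) {
          id <- add_focus(cell, "telomere", pp$p, pp$l, c_per_len * pp$l,
                          did, TRUE, NA_integer_)
          arrs$telomere <- render_emitter(arrs$telomere, pp$p,
                                          c_per_len * pp$l, cfg$psf_sigma,
                                          vs, support_env, id)
          ids <- c(ids, id)
        }
      } else {
        id <- add_focus(cell, "telomere", pos[j, ], len, c_per_len * len,
                        NA_character_, TRUE, NA_integer_)
        arrs$telomere <- render_emitter(arrs$telomere, pos[j, ],
                                        c_per_len * len, cfg$psf_sigma,
                                        vs, support_env, id)
        ids <- c(ids, id)
      }
    }
    tel_ids_by_cell[[cell]] <- ids
  }

  rna_total <- cfg$snr * max(scene_noise_sd(cfg), 1) /
    psf_peak_fraction(cfg$psf_sigma, vs)
  first_rna_ids_by_cell <- rep(list(integer(0)), cfg$n_cells)
  for (ci in seq_along(cfg$rna_channels)) {
    ch <- cfg$rna_channels[ci]
    for (cell in seq_len(cfg$n_cells)) {
      n <- n_rna[cell]
      if (n == 0L) next
      tel_ids <- tel_ids_by_cell[[cell]]
      for (j in seq_len(n)) {
        partner <- NA_integer_
        at_tel <- FALSE
        pos <- NULL
        if (ci > 1L && length(first_rna_ids_by_cell[[cell]]) > 0 &&
            stats::runif(1) < cfg$p_rna_pair) {
          # co-placed with a spot of the first RNA channel
          partner <- sample(first_rna_ids_by_cell[[cell]], 1L)
          host <- foci[[partner]]
          pos <- c(host$z_um, host$y_um, host$x_um) +
            stats::rnorm(3, sd = 0.03)
          at_tel <- isTRUE(host$at_telomere)
        } else if (length(tel_ids) > 0) {
          cand <- sample(tel_ids, 1L)
          host <- foci[[cand]]
          if (stats::runif(1) < cfg$p_rna_at_telomere(host$length)) {
            pos <- c(host$z_um, host$y_um, host$x_um) +
              stats::rnorm(3, sd = 0.02)
            partner <- cand
            at_tel <- TRUE
          }
        }
        if (is.null(pos)) {
          pos <- drop(runif_ellipsoid(1, centers[cell, ],
                                      0.9 * cfg$nucleus_radius))
          at_tel <- FALSE
        }
        id <- add_focus(cell, ch, pos, 1, rna_total, NA_character_,
                        at_tel, partner)
        arrs[[ch]] <- render_emitter(arrs[[ch]], pos, rna_total,
                                     cfg$psf_sigma, vs, support_env, id)
        if (ci == 1L) {
          first_rna_ids_by_cell[[cell]] <-
            c(first_rna_ids_by_cell[[cell]], id)
        }
      }
    }
  }

  for (ch in channels) arrs[[ch]] <- apply_scene_noise(arrs[[ch]], cfg)
  vox <- array(0, c(length(channels), d))
  for (i in seq_along(channels)) vox[i, , , ] <- arrs[[i]]
  stack <- image_stack(vox, voxel_size = vs, channel_names = channels)

  truth_foci <- if (oid > 0L) do.call(rbind, foci) else
    data.frame(cell_id = integer(0), channel = character(0),
               object_id = integer(0), z_um = numeric(0), y_um = numeric(0),
               x_um = numeric(0), length = numeric(0), intensity = numeric(0),
               doublet_id = character(0), at_telomere = logical(0),
               partner_id = integer(0))
  voxels <- vector("list", oid)
  for (id in seq_len(oid)) voxels[[id]] <- support_env$voxels[[id]]
  cells <- data.frame(cell_id = seq_len(cfg$n_cells), centers,
                      r_z = cfg$nucleus_radius[1],
                      r_y = cfg$nucleus_radius[2],
                      r_x = cfg$nucleus_radius[3])
  structure(list(stack = stack,
                 truth = list(cells = cells, foci = truth_foci,
                              voxels = voxels),
                 config = cfg),
            class = "fish_scene")
}

#' Write scene ground truth as CSV
#'
#' @param scene a `fish_scene` from [generate_fish_scene()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(scene, path) {
  utils::write.csv(scene$truth$foci, path, row.names = FALSE)
  invisible(path)
}
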