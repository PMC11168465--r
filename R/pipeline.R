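#' Read a run configuration file (JSON, or YAML when available)
#'
#' Configuration files mirror the [scene_config()] / [kinetics_config()]
#' argument names under `scene:` and `kinetics:` keys, plus free-form
#' analysis options. JSON is always supported; `.yaml`/`.yml` files
#' require the `yaml` package.
#'
#' @param path file path.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML configs need the 'yaml' package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

config_from_list <- function(lst, constructor) {
  if (is.null(lst)) return(constructor())
  fml <- names(formals(constructor))
  do.call(constructor, lst[intersect(names(lst), fml)])
}

write_report_outputs <- function(report, out_dir, tables) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(tables)) {
    if (!is.null(tables[[nm]]) && nrow(tables[[nm]]) > 0) {
      utils::write.csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(report$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' Run the fixed-image (FISH) analysis pipeline
#'
#' Chains nucleus segmentation, per-channel focus detection, A-B overlap
#' colocalization, the optional shuffle null, triple partitioning by the
#' telomere channel, and the per-cell report. The input is either a
#' rendered scene (any [image_stack()] with the named channels) or a
#' [scene_config()] from which a synthetic scene is generated.
#'
#' @param stack an [image_stack()] with channels `dapi`, `telomere` and
#'   the two RNA channels, or `NULL` to generate one from `config`.
#' @param config a [scene_config()] (used when `stack` is NULL).
#' @param channels named list mapping roles `dapi`, `telomere`, `rna_a`,
#'   `rna_b` to channel names/indices.
#' @param n_shuffles shuffle count for the spatial null; 0 skips it.
#' @param seed seed for generation and the shuffle null.
#' @param out_dir optional output directory for CSV/JSON reports.
#' @param ... further arguments passed to [detect_foci()].
#' @return list of class `run_report` with `nuclei`, `foci` (per role),
#'   `pairs`, `partition`, `report`, `shuffle`, `summary`.
#' @export
run_fish_pipeline <- function(stack = NULL, config = scene_config(),
                              channels = list(dapi = "dapi",
                                              telomere = "telomere",
                                              rna_a = "terra",
                                              rna_b = "htr"),
                              n_shuffles = 0L, seed = 1L, out_dir = NULL,
                              ...) {
  truth <- NULL
  if (is.null(stack)) {
    config$seed <- as.integer(seed)
    scene <- generate_fish_scene(config)
    stack <- scene$stack
    truth <- scene$truth
  }
  for (role in c("dapi", "telomere", "rna_a", "rna_b")) {
    ch <- channels[[role]]
    if (is.character(ch) && !(ch %in% stack$channel_names)) {
      stop(sprintf("config error: channel '%s' (%s) missing", ch, role))
    }
  }
  nuclei <- segment_nuclei(stack, channels$dapi)
  tel <- detect_foci(stack, channels$telomere, nuclei = nuclei, ...)
  rna_a <- detect_foci(stack, channels$rna_a, nuclei = nuclei, ...)
  rna_b <- detect_foci(stack, channels$rna_b, nuclei = nuclei, ...)
  pairs <- overlap_colocalize(rna_a, rna_b)
  part <- triple_partition(pairs, rna_a, rna_b, tel)
  rep_cells <- if (nrow(nuclei$features) > 0)
    per_cell_report(rna_a, rna_b, tel, part$pairs,
                    part$b_with_c_without_a,
                    cell_ids = nuclei$features$cell_id) else NULL
  shuf <- NULL
  if (n_shuffles > 0L && n_foci(rna_a) > 0L && n_foci(rna_b) > 0L &&
      nrow(nuclei$features) > 0L) {
    shuf <- shuffle_null(rna_a, rna_b, nuclei, n_shuffles = n_shuffles,
                         seed = seed + 1L)
  }
  summary <- list(
    n_cells = nrow(nuclei$features),
    n_telomere_foci = n_foci(tel),
    n_rna_a = n_foci(rna_a), n_rna_b = n_foci(rna_b),
    n_pairs = nrow(pairs),
    n_telomeric_pairs = sum(part$pairs$label == "telomeric"),
    pct_cells_with_pair = if (!is.null(rep_cells))
      rep_cells$cohort$pct_cells_with_pair else NA,
    telomeric_fraction = if (!is.null(rep_cells))
      rep_cells$cohort$telomeric_fraction else NA,
    shuffle_decision = if (!is.null(shuf)) shuf$decision else NA,
    seed = seed)
  report <- structure(list(nuclei = nuclei,
                           foci = list(telomere = tel, rna_a = rna_a,
                                       rna_b = rna_b),
                           pairs = part$pairs,
                           b_with_c_without_a = part$b_with_c_without_a,
                           report = rep_cells, shuffle = shuf,
                           truth = truth, summary = summary),
                      class = "run_report")
  write_report_outputs(report, out_dir,
                       list(foci_telomere = tel$features,
                            foci_rna_a = rna_a$features,
                            foci_rna_b = rna_b$features,
                            pairs = part$pairs,
                            cells = if (!is.null(rep_cells))
                              rep_cells$cells else NULL))
  report
}

#' Run the live-movie analysis pipeline
#'
#' Chains photobleaching correction, frame-wise particle and telomere
#' detection, track linking, colocalization-event extraction,
#' dwell-survival construction, the constrained two-phase decay fit and
#' the Kaplan-Meier cumulative-dwell curve.
#'
#' @param movie an [image_movie()] with channels `particle` and
#'   `telomere`, or `NULL` to simulate one from the configs.
#' @param scene,kin [scene_config()] / [kinetics_config()] used when
#'   `movie` is NULL.
#' @param max_disp linker displacement limit in um per frame.
#' @param coloc_radius event colocalization radius in um.
#' @param seed generation seed (when simulating).
#' @param out_dir optional output directory.
#' @param ... passed to [detect_foci()] via [detect_particles()].
#' @return list of class `run_report` with `tracks`, `telomere_tracks`,
#'   `events`, `survival`, `fit` (NULL with a warning when there are too
#'   few events), `km`, `summary`.
#' @export
run_live_pipeline <- function(movie = NULL,
                              scene = movie_scene_config(),
                              kin = kinetics_config(),
                              max_disp = 1.0, coloc_radius = 0.3,
                              seed = 1L, out_dir = NULL, ...) {
  truth <- NULL
  if (is.null(movie)) {
    kin$seed <- as.integer(seed)
    sim <- generate_live_movie(scene, kin, render = TRUE)
    movie <- sim$movie
    truth <- sim$truth
  }
  if (length(movie$frames) < 2L) stop("need at least 2 frames")
  dt <- movie$frame_interval
  movie <- correct_photobleaching(movie)
  det_p <- detect_particles(movie, "particle", ...)
  det_t <- detect_particles(movie, "telomere", ...)
  tracks <- link_detections(det_p, max_disp = max_disp,
                            frame_interval = dt)
  tel_tracks <- link_detections(det_t, max_disp = max_disp / 2,
                                frame_interval = dt)
  names(tel_tracks)[names(tel_tracks) == "track_id"] <- "telomere_id"
  events <- assign_coloc_events(tracks, tel_tracks,
                                coloc_radius = coloc_radius,
                                frame_interval = dt)
  fit <- NULL; surv <- NULL; km <- NULL
  pct <- NA_real_
  n_tel <- length(unique(tel_tracks$telomere_id))
  if (nrow(events) == 0L) {
    warning("no colocalization events; survival fit skipped")
  } else {
    surv <- survival_from_dwells(events$duration, events$censored)
    if (length(unique(surv$t[surv$S > 0])) >= 6L) {
      fit <- tryCatch(fit_biexponential(surv), error = function(e) {
        warning(conditionMessage(e)); NULL
      })
    } else {
      warning("too few distinct durations; biexponential fit skipped")
    }
    cum <- stats::aggregate(list(duration = events$duration),
                            by = list(telomere_id = events$telomere_id),
                            FUN = sum)
    cens <- stats::aggregate(list(censored = events$censored),
                             by = list(telomere_id = events$telomere_id),
                             FUN = any)
    km <- km_cumulative_dwell(cum$duration,
                              cens$censored[match(cum$telomere_id,
                                                  cens$telomere_id)])
    if (n_tel > 0) {
      pct <- percent_telomeres_colocalized(events,
                                           unique(tel_tracks$telomere_id))
    }
  }
  summary <- list(
    n_frames = length(movie$frames),
    n_particle_tracks = length(unique(tracks$track_id)),
    n_telomeres = n_tel,
    n_events = nrow(events),
    n_stable_events = sum(events$stable),
    pct_telomeres_colocalized = pct,
    tau_fast = if (!is.null(fit)) fit$tau_fast else NA,
    tau_slow = if (!is.null(fit)) fit$tau_slow else NA,
    halflife_fast = if (!is.null(fit)) fit$halflife_fast else NA,
    halflife_slow = if (!is.null(fit)) fit$halflife_slow else NA,
    km_median = if (!is.null(km)) km$median else NA,
    bleach_rate = attr(movie, "bleach_rate"),
    seed = seed)
  report <- structure(list(tracks = tracks, telomere_tracks = tel_tracks,
                           events = events, survival = surv, fit = fit,
                           km = km, truth = truth, summary = summary),
                      class = "run_report")
  write_report_outputs(report, out_dir,
                       list(tracks = tracks, telomere_tracks = tel_tracks,
                            events = events))
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  utils::str(x$summary, give.attr = FALSE)
  invisible(x)
}

#' Run the built-in benchmark/acceptance suite
#'
#' Recomputes the package's headline validation quantities from scratch:
#' the cis/trans worked example, the colocalization stability rule, the
#' half-life identity, a noiseless two-phase fit recovery, and the
#' false-positive calibration of the shuffle-null decision.
#'
#' @param seed integer seed.
#' @param n_calibration number of null instances for the shuffle
#'   calibration (default 200; the acceptance script uses 1000).
#' @param out_dir optional output directory for the pass/fail table.
#' @return data.frame `id`, `description`, `value`, `expected`, `pass`.
#' @export
run_benchmark <- function(seed = 1L, n_calibration = 200L, out_dir = NULL) {
  rows <- list()
  # cis/trans worked example: published particle counts
  cls <- factor(rep(localization_levels, c(4, 3, 57, 344)),
                levels = localization_levels)
  ct <- summarize_cis_trans(cls)
  rows[[1]] <- data.frame(id = "cis_trans",
                          description = "cis% for counts 4/3/57/344",
                          value = round(ct$cis_percent, 1), expected = 1.7,
                          pass = round(ct$cis_percent, 1) == 1.7)
  # stability rule at 5-s cadence
  tr <- data.frame(track_id = 1, frame = 0:2, t_s = (0:2) * 5,
                   z_um = 0, y_um = 0, x_um = 0)
  tel <- data.frame(telomere_id = 1, z_um = 0, y_um = 0, x_um = 0)
  ev <- assign_coloc_events(tr, tel, frame_interval = 5)
  rows[[2]] <- data.frame(id = "stability",
                          description = "3 frames @5s -> 15s stable",
                          value = ev$duration[1], expected = 15,
                          pass = ev$duration[1] == 15 && ev$stable[1])
  # half-life identity
  hl <- derive_half_life(list(K_fast = 1 / 8, K_slow = 1 / 40))
  rows[[3]] <- data.frame(id = "half_life",
                          description = "halflife = ln2 * tau",
                          value = hl[["slow"]] / 40, expected = log(2),
                          pass = abs(hl[["slow"]] / 40 - log(2)) < 1e-12)
  # noiseless two-phase recovery
  tt <- seq(0, 200, by = 5)
  curve <- list(t = tt, S = 0.6 * exp(-tt / 8) + 0.4 * exp(-tt / 40))
  ft <- fit_biexponential(curve)
  rows[[4]] <- data.frame(id = "biexp_recovery",
                          description = "noiseless tau recovery (1%)",
                          value = ft$tau_slow, expected = 40,
                          pass = abs(ft$tau_fast - 8) / 8 < 0.01 &&
                            abs(ft$tau_slow - 40) / 40 < 0.01)
  # shuffle-null type-I calibration
  fp <- shuffle_false_positive_rate(n_instances = n_calibration,
                                    seed = seed)
  rows[[5]] <- data.frame(id = "shuffle_calibration",
                          description = "null rejection rate (%) <= 5",
                          value = fp$rate_percent, expected = 5,
                          pass = fp$ci_low_percent <= 5)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(out_dir, "benchmark.csv"),
                     row.names = FALSE)
  }
  out
}

#' Empirical false-positive rate of the shuffle-null decision
#'
#' Generates `n_instances` null scenes — reference and test objects both
#' placed uniformly at random inside an ellipsoidal nuclear mask, i.e. by
#' the same process the shuffle itself uses — runs [shuffle_null()] on
#' each, and reports the fraction declared significant with an exact
#' binomial 95% confidence interval.
#'
#' @param n_instances number of simulated null instances (default 1000).
#' @param n_a,n_b number of reference / test objects (default 20 each).
#' @param n_shuffles shuffles per test (default 100).
#' @param envelope decision rule passed to [shuffle_null()].
#' @param seed integer seed.
#' @return list `rate_percent`, `ci_low_percent`, `ci_high_percent`,
#'   `n_significant`, `n_instances`.
#' @export
shuffle_false_positive_rate <- function(n_instances = 1000L, n_a = 20L,
                                        n_b = 20L, n_shuffles = 100L,
                                        envelope = "global", seed = 1L) {
  d <- c(10L, 48L, 48L)
  vs <- c(0.3, 0.133, 0.133)
  co <- arrayInd(seq_len(prod(d)), d)
  cen <- (d + 1) / 2
  rel <- sweep(sweep(co, 2, cen, "-"), 2, d / 2 - 1, "/")
  mask <- array(rowSums(rel^2) <= 1, d)
  dom_idx <- which(mask)
  point_set <- function(idx) {
    co_i <- arrayInd(idx, d)
    pos <- coords_to_um(co_i, vs)
    feats <- data.frame(object_id = seq_along(idx), channel = "x",
                        cell_id = 1L, z_um = pos[, 1], y_um = pos[, 2],
                        x_um = pos[, 3], n_voxels = 1L,
                        volume_um3 = prod(vs), integrated_density = 1,
                        peak_count = 1L, border = FALSE)
    focus_set(feats, as.list(idx), d, vs)
  }
  hits <- with_rng(seed, {
    n_sig <- 0L
    for (i in seq_len(n_instances)) {
      ia <- sample(dom_idx, n_a)
      ib <- sample(dom_idx, n_b)
      res <- shuffle_null(point_set(ia), point_set(ib), mask,
                          n_shuffles = n_shuffles, seed = NULL,
                          envelope = envelope)
      if (res$decision == "significant") n_sig <- n_sig + 1L
    }
    n_sig
  })
  ci <- stats::binom.test(hits, n_instances)$conf.int
  list(rate_percent = 100 * hits / n_instances,
       ci_low_percent = 100 * ci[1], ci_high_percent = 100 * ci[2],
       n_significant = hits, n_instances = n_instances)
}
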