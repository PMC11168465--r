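#' Correct acquisition photobleaching in a time-lapse movie
#'
#' Fits a mono-exponential trend to the whole-frame mean intensity of each
#' channel and rescales frames so the fitted trend is flat, preserving the
#' frame-0 scale. A single-frame movie is returned unchanged.
#'
#' @param movie an [image_movie()].
#' @param channel channel to estimate the trend from and to correct;
#'   `NULL` (default) corrects every channel with its own trend.
#' @return the corrected movie, with attribute `bleach_rate` (estimated
#'   per-frame fractional loss per channel).
#' @export
correct_photobleaching <- function(movie, channel = NULL) {
  nf <- length(movie$frames)
  if (nf < 2L) {
    attr(movie, "bleach_rate") <- 0
    return(movie)
  }
  chans <- if (is.null(channel)) seq_len(n_channels(movie$frames[[1L]])) else
    resolve_channel(movie$frames[[1L]], channel)
  tt <- frame_times(movie)
  rates <- numeric(length(chans))
  for (ci in seq_along(chans)) {
    ch <- chans[ci]
    means <- vapply(movie$frames,
                    function(f) mean(get_channel(f, ch)), numeric(1))
    if (any(means <= 0)) next
    fit <- stats::lm(log(means) ~ tt)
    slope <- stats::coef(fit)[2L]
    # factor restoring each frame to the fitted frame-0 level
    fac <- exp(-slope * (tt - tt[1L]))
    for (f in seq_len(nf)) {
      movie$frames[[f]]$voxels[ch, , , ] <-
        movie$frames[[f]]$voxels[ch, , , ] * fac[f]
    }
    rates[ci] <- 1 - exp(slope * movie$frame_interval)
  }
  attr(movie, "bleach_rate") <- rates
  movie
}

#' Detect particles in every frame of a movie
#'
#' Runs [detect_foci()] on each frame of one channel and returns a
#' detection table in physical units.
#'
#' @param movie an [image_movie()].
#' @param channel channel index or name.
#' @param ... passed to [detect_foci()].
#' @return data.frame `frame` (0-based), `t_s`, `z_um`, `y_um`, `x_um`,
#'   `intensity` (integrated density).
#' @export
detect_particles <- function(movie, channel, ...) {
  tt <- frame_times(movie)
  out <- list()
  for (f in seq_along(movie$frames)) {
    fs <- detect_foci(movie$frames[[f]], channel, ...)
    if (n_foci(fs) == 0L) next
    out[[length(out) + 1L]] <- data.frame(
      frame = f - 1L, t_s = tt[f],
      z_um = fs$features$z_um, y_um = fs$features$y_um,
      x_um = fs$features$x_um,
      intensity = fs$features$integrated_density)
  }
  if (length(out) == 0L) {
    return(data.frame(frame = integer(0), t_s = numeric(0),
                      z_um = numeric(0), y_um = numeric(0),
                      x_um = numeric(0), intensity = numeric(0)))
  }
  do.call(rbind, out)
}

#' Link frame-wise detections into tracks
#'
#' Greedy nearest-neighbor linking: candidate links between open track
#' ends and current-frame detections within `max_disp` (scaled by the gap
#' length for gap closures) are accepted in order of increasing distance,
#' each end and each detection used at most once — i.e. mutual-nearest
#' pairs always link first. Gaps up to `max_gap` missing frames are
#' closed; unlinked detections start new tracks.
#'
#' @param detections data.frame with `frame` (integer), `z_um`, `y_um`,
#'   `x_um` and optionally `t_s`, `intensity`.
#' @param max_disp maximum frame-to-frame displacement in um (> 0).
#' @param max_gap maximum number of missing frames bridged (default 1).
#' @param frame_interval seconds per frame, used to fill `t_s` if absent.
#' @return data.frame: the detections plus a `track_id` column, ordered by
#'   track then frame.
#' @export
link_detections <- function(detections, max_disp, max_gap = 1L,
                            frame_interval = 5) {
  if (max_disp <= 0) stop("config error: max_disp must be positive")
  det <- detections
  if (nrow(det) == 0L) {
    det$track_id <- integer(0)
    return(det)
  }
  if (is.null(det$t_s)) det$t_s <- det$frame * frame_interval
  det <- det[order(det$frame), , drop = FALSE]
  det$track_id <- NA_integer_
  frames <- sort(unique(det$frame))
  next_id <- 0L
  # open track ends: track_id -> (frame, position)
  open_id <- integer(0)
  open_frame <- integer(0)
  open_pos <- matrix(numeric(0), 0, 3)
  for (f in frames) {
    rows <- which(det$frame == f)
    pos <- as.matrix(det[rows, c("z_um", "y_um", "x_um")])
    assigned <- rep(NA_integer_, length(rows))
    if (length(open_id) > 0L) {
      gap <- f - open_frame            # 1 = adjacent frame
      eligible <- which(gap >= 1L & gap <= max_gap + 1L)
      if (length(eligible) > 0L) {
        dd <- cross_dist_um(open_pos[eligible, , drop = FALSE], pos)
        lim <- max_disp * gap[eligible]
        cand <- which(dd <= lim, arr.ind = TRUE)
        if (nrow(cand) > 0L) {
          ord <- order(dd[cand])
          used_e <- logical(length(eligible))
          used_d <- logical(length(rows))
          for (r in ord) {
            i <- cand[r, 1]; j <- cand[r, 2]
            if (used_e[i] || used_d[j]) next
            used_e[i] <- TRUE; used_d[j] <- TRUE
            assigned[j] <- open_id[eligible[i]]
          }
        }
      }
    }
    for (j in seq_along(rows)) {
      if (is.na(assigned[j])) {
        next_id <- next_id + 1L
        assigned[j] <- next_id
      }
    }
    det$track_id[rows] <- assigned
    # update open ends
    for (j in seq_along(rows)) {
      k <- match(assigned[j], open_id)
      if (is.na(k)) {
        open_id <- c(open_id, assigned[j])
        open_frame <- c(open_frame, f)
        open_pos <- rbind(open_pos, pos[j, ])
      } else {
        open_frame[k] <- f
        open_pos[k, ] <- pos[j, ]
      }
    }
  }
  det <- det[order(det$track_id, det$frame), , drop = FALSE]
  rownames(det) <- NULL
  det
}

#' Frame-wise colocalization events between tracks and telomeres
#'
#' For each frame, a particle is colocalized with the nearest telomere
#' within `coloc_radius`. Maximal runs of consecutive colocalized frames
#' (bridging up to `tolerance_gap` missing or excursion frames) become
#' events. A run spanning frames `i..j` at interval `dt` has duration
#' `(j - i + 1) * dt` — a single-frame contact lasts one frame interval —
#' and is "stable" when the duration reaches `stable_min_s` (default 10 s,
#' i.e. two frames at the 5-s cadence).
#'
#' @param tracks data.frame from [link_detections()] (`track_id`, `frame`,
#'   positions in um).
#' @param telomere_tracks data.frame with `telomere_id`, `z_um`, `y_um`,
#'   `x_um`, and either a `frame` column (tracked telomeres) or one row
#'   per telomere (static positions applied to every frame).
#' @param coloc_radius um (default 0.3, about the lateral PSF).
#' @param tolerance_gap frames bridged inside an event (default 1).
#' @param frame_interval seconds per frame (default 5).
#' @param stable_min_s stability threshold in seconds (default 10).
#' @return data.frame `track_id`, `telomere_id`, `start_frame`,
#'   `end_frame`, `t_start`, `t_end`, `n_frames`, `duration`, `stable`,
#'   `censored` (event touches the last observed frame of the track).
#' @export
assign_coloc_events <- function(tracks, telomere_tracks, coloc_radius = 0.3,
                                tolerance_gap = 1L, frame_interval = 5,
                                stable_min_s = 10) {
  empty <- data.frame(track_id = integer(0), telomere_id = integer(0),
                      start_frame = integer(0), end_frame = integer(0),
                      t_start = numeric(0), t_end = numeric(0),
                      n_frames = integer(0), duration = numeric(0),
                      stable = logical(0), censored = logical(0))
  if (nrow(tracks) == 0L || is.null(telomere_tracks) ||
      nrow(telomere_tracks) == 0L) {
    return(empty)
  }
  static_tel <- is.null(telomere_tracks$frame)
  out <- list()
  last_frame_all <- max(tracks$frame)
  for (tid in unique(tracks$track_id)) {
    tr <- tracks[tracks$track_id == tid, , drop = FALSE]
    hit_tel <- rep(NA_integer_, nrow(tr))
    for (r in seq_len(nrow(tr))) {
      tel <- if (static_tel) telomere_tracks else
        telomere_tracks[telomere_tracks$frame == tr$frame[r], , drop = FALSE]
      if (nrow(tel) == 0L) next
      dd <- cross_dist_um(as.matrix(tr[r, c("z_um", "y_um", "x_um")]),
                          as.matrix(tel[, c("z_um", "y_um", "x_um")]))
      jm <- which.min(dd[1, ])
      if (dd[1, jm] <= coloc_radius) hit_tel[r] <- tel$telomere_id[jm]
    }
    for (tel_id in unique(stats::na.omit(hit_tel))) {
      fr <- sort(tr$frame[!is.na(hit_tel) & hit_tel == tel_id])
      # split into runs bridging gaps of <= tolerance_gap frames
      brk <- c(0L, which(diff(fr) > tolerance_gap + 1L), length(fr))
      for (s in seq_len(length(brk) - 1L)) {
        seg <- fr[(brk[s] + 1L):brk[s + 1L]]
        nfr <- seg[length(seg)] - seg[1L] + 1L
        dur <- nfr * frame_interval
        out[[length(out) + 1L]] <- data.frame(
          track_id = tid, telomere_id = tel_id,
          start_frame = seg[1L], end_frame = seg[length(seg)],
          t_start = seg[1L] * frame_interval,
          t_end = seg[length(seg)] * frame_interval,
          n_frames = nfr, duration = dur,
          stable = dur >= stable_min_s,
          censored = seg[length(seg)] >= min(max(tr$frame), last_frame_all))
      }
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res[order(res$track_id, res$start_frame), , drop = FALSE]
}

localization_levels <- c("origin_telomere", "origin_proximal",
                         "other_telomere", "nontelomeric")

#' Classify particle positions relative to the telomere of origin
#'
#' Assigns each observation exactly one class, in precedence order:
#' `origin_telomere` (overlapping the origin signal, i.e. within
#' `overlap_radius`), `origin_proximal` (within `proximity`, 0.6 um by
#' default, and in the same z slice when `same_z = TRUE`),
#' `other_telomere` (overlapping any non-origin telomere), else
#' `nontelomeric`. With no origin position, only the last two classes can
#' be assigned.
#'
#' @param observations data.frame with `z_um`, `y_um`, `x_um` (one row per
#'   particle observation).
#' @param origin numeric length-3 `(z, y, x)` um position of the telomere
#'   of origin, or `NULL` if unidentified.
#' @param telomeres data.frame of all telomere positions (`z_um`, `y_um`,
#'   `x_um`; the origin, if present among them, is identified by proximity
#'   to `origin` and excluded from the "other" set).
#' @param proximity um threshold for "in proximity" (default 0.6).
#' @param overlap_radius um threshold for "overlapping" (default 0.3).
#' @param same_z require the same z slice for proximity calls (default
#'   TRUE, as in slice-based live-cell scoring).
#' @param z_step um per z slice (default 0.3) used for the same-slice
#'   rule.
#' @return factor with levels origin_telomere, origin_proximal,
#'   other_telomere, nontelomeric.
#' @export
classify_localization <- function(observations, origin, telomeres,
                                  proximity = 0.6, overlap_radius = 0.3,
                                  same_z = TRUE, z_step = 0.3) {
  pos <- as.matrix(observations[, c("z_um", "y_um", "x_um")])
  n <- nrow(pos)
  cls <- rep("nontelomeric", n)
  tel <- as.matrix(telomeres[, c("z_um", "y_um", "x_um")])
  other <- tel
  if (!is.null(origin)) {
    origin <- as.numeric(origin)
    if (nrow(tel) > 0L) {
      d_or <- cross_dist_um(matrix(origin, 1), tel)[1, ]
      other <- tel[d_or > overlap_radius, , drop = FALSE]
    }
  }
  d_other <- if (nrow(other) > 0L)
    apply(cross_dist_um(pos, other), 1, min) else rep(Inf, n)
  cls[d_other <= overlap_radius] <- "other_telomere"
  if (!is.null(origin)) {
    d_o <- cross_dist_um(pos, matrix(origin, 1))[, 1]
    same_slice <- if (same_z) {
      floor(pos[, 1] / z_step + 0.5) == floor(origin[1] / z_step + 0.5)
    } else rep(TRUE, n)
    cls[d_o <= proximity & same_slice] <- "origin_proximal"
    cls[d_o <= overlap_radius] <- "origin_telomere"
  }
  factor(cls, levels = localization_levels)
}

#' Summarize cis/trans localization percentages
#'
#' @param classifications factor from [classify_localization()] (one entry
#'   per particle).
#' @return list with `counts`, `percent` (per class), `cis_percent`
#'   (origin_telomere + origin_proximal) and `n`.
#' @export
summarize_cis_trans <- function(classifications) {
  if (length(classifications) == 0L) stop("no classified particles")
  cls <- factor(classifications, levels = localization_levels)
  counts <- table(cls)
  pct <- 100 * as.numeric(counts) / length(cls)
  names(pct) <- names(counts)
  list(counts = counts, percent = pct,
       cis_percent = pct[["origin_telomere"]] + pct[["origin_proximal"]],
       n = length(cls))
}

#' Percentage of telomeres with at least one stable colocalized track
#'
#' A telomere counts as colocalized when it has at least one stable event
#' (duration >= 10 s by default) in the event table.
#'
#' @param events data.frame from [assign_coloc_events()].
#' @param telomere_ids vector of all telomere ids under observation.
#' @return percentage in \[0, 100\].
#' @export
percent_telomeres_colocalized <- function(events, telomere_ids) {
  telomere_ids <- unique(telomere_ids)
  if (length(telomere_ids) == 0L) stop("zero telomeres")
  if (nrow(events) == 0L) return(0)
  with_stable <- unique(events$telomere_id[events$stable])
  100 * sum(telomere_ids %in% with_stable) / length(telomere_ids)
}
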