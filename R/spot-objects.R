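#' Focus sets: segmented 3D objects and their features
#'
#' A `focus_set` holds the result of 3D object segmentation of one channel:
#' a feature table (one row per focus) plus the voxel support of every
#' object as linear indices into the `(z, y, x)` array. Integrated density
#' is the plain sum of raw voxel intensities over the object, the standard
#' telomere-length proxy; volume is `n_voxels` times the physical voxel
#' volume.
#'
#' @param features data.frame with at least `object_id`, `z_um`, `y_um`,
#'   `x_um`, `n_voxels`, `volume_um3`, `integrated_density`.
#' @param voxels list of integer vectors (linear voxel indices), one per
#'   row of `features`.
#' @param dim integer `(z, y, x)` image dimensions.
#' @param voxel_size um per voxel `(z, y, x)`.
#' @param peaks optional list of per-focus local-maxima coordinate matrices
#'   (um) used by [classify_singlet_doublet()].
#' @return object of class `focus_set`.
#' @export
focus_set <- function(features, voxels, dim, voxel_size, peaks = NULL) {
  stopifnot(nrow(features) == length(voxels))
  structure(list(features = features, voxels = voxels,
                 dim = as.integer(dim), voxel_size = as.numeric(voxel_size),
                 peaks = peaks),
            class = "focus_set")
}

#' @export
print.focus_set <- function(x, ...) {
  cat(sprintf("<focus_set> %d foci on a %s grid\n", nrow(x$features),
              paste(x$dim, collapse = "x")))
  invisible(x)
}

#' Number of foci in a focus_set
#' @param x a `focus_set`.
#' @return integer.
#' @export
n_foci <- function(x) nrow(x$features)

empty_focus_features <- function() {
  data.frame(object_id = integer(0), channel = character(0),
             cell_id = integer(0), z_um = numeric(0), y_um = numeric(0),
             x_um = numeric(0), n_voxels = integer(0),
             volume_um3 = numeric(0), integrated_density = numeric(0),
             peak_count = integer(0), border = logical(0))
}

robust_threshold <- function(values, k) {
  stats::median(values) + k * stats::mad(values)
}

# Otsu's between-class-variance threshold; appropriate when the foreground
# occupies a large volume fraction (nuclear counterstain), where the
# median + k*MAD background model breaks down.
otsu_threshold <- function(values, n_bins = 256L) {
  rng <- range(values)
  if (diff(rng) == 0) return(rng[1])
  h <- graphics::hist(values, breaks = seq(rng[1], rng[2],
                                           length.out = n_bins + 1L),
                      plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

# Collapse local maxima closer than `min_sep_um` (single linkage) and return
# one representative (the brightest) per cluster.
merge_peaks <- function(pos_um, values, min_sep_um) {
  n <- nrow(pos_um)
  if (n <= 1L) return(seq_len(n))
  dd <- cross_dist_um(pos_um, pos_um)
  g <- igraph::graph_from_adjacency_matrix((dd <= min_sep_um) * 1,
                                           mode = "undirected", diag = FALSE)
  mem <- igraph::components(g)$membership
  keep <- integer(0)
  for (cl in unique(mem)) {
    members <- which(mem == cl)
    keep <- c(keep, members[which.max(values[members])])
  }
  sort(keep)
}

#' Detect 3D foci in one channel
#'
#' Segmentation follows the standard FISH-spot recipe: the channel is
#' smoothed with a small Gaussian (matched to roughly the PSF scale, which
#' suppresses voxel noise without merging resolvable spots), thresholded at
#' `background median + k * MAD` of the smoothed image, and 26-connected
#' components become candidate objects. Each candidate is then refined on
#' the raw image (voxels above `median + refine_k * MAD` of the raw
#' channel), so features are measured on raw data: integrated density is
#' the exact raw-intensity sum over the final voxel set and volume the
#' exact voxel count times the voxel volume.
#'
#' @param stack an [image_stack()].
#' @param channel channel index or name.
#' @param threshold_policy `"mad"` (robust background statistics, default)
#'   or `"absolute"` (use `threshold` as given on both images). The
#'   thresholds are kept constant across images of an experiment by
#'   construction.
#' @param k MAD multiplier for the detection threshold (default 6).
#' @param threshold absolute threshold, only for
#'   `threshold_policy = "absolute"`.
#' @param min_voxels,max_voxels object size window in voxels.
#' @param smooth_sigma_um Gaussian pre-smoothing sigma in um `(z, y, x)`;
#'   default `c(0.15, 0.08, 0.08)`, slightly under the PSF so noise is
#'   suppressed with minimal loss of two-spot resolution.
#' @param refine_k MAD multiplier for the raw-image refinement (default 2).
#' @param nuclei optional [segment_nuclei()] result; when given, each focus
#'   is assigned the `cell_id` of the nucleus with majority voxel overlap
#'   (ties broken by nearest nucleus centroid), else `NA`.
#' @param split_min_sep_um candidate components containing several
#'   smoothed-intensity maxima farther apart than this are split into one
#'   object per maximum (default 0.3 um, about the effective resolution of
#'   the matched-filtered confocal image); partially overlapping spots
#'   therefore become touching objects rather than one blob.
#' @param peak_min_sep_um minimum separation (um) between intensity maxima
#'   counted as distinct peaks inside one object (default 0.115, the
#'   lateral resolution of 3D-SIM; irrelevant below confocal resolution).
#' @return a [focus_set()].
#' @examples
#' arr <- array(0, c(1, 6, 20, 20)); arr[1, 3, 10, 10] <- 50
#' fs <- detect_foci(image_stack(arr), 1, min_voxels = 1)
#' n_foci(fs)
#' @export
detect_foci <- function(stack, channel,
                        threshold_policy = c("mad", "absolute"),
                        k = 6, threshold = NULL,
                        min_voxels = 2L, max_voxels = Inf,
                        smooth_sigma_um = c(0.15, 0.08, 0.08),
                        refine_k = 2,
                        nuclei = NULL,
                        split_min_sep_um = 0.3,
                        peak_min_sep_um = 0.115) {
  if (is.character(threshold_policy) &&
      !all(threshold_policy %in% c("mad", "absolute"))) {
    stop("config error: unknown threshold_policy")
  }
  threshold_policy <- match.arg(threshold_policy)
  x <- get_channel(stack, channel)
  vs <- stack$voxel_size
  d <- dim(x)
  s <- gaussian_blur_3d(x, smooth_sigma_um / vs)
  if (threshold_policy == "mad") {
    t_s <- robust_threshold(as.vector(s), k)
    t_r <- robust_threshold(as.vector(x), refine_k)
  } else {
    if (is.null(threshold)) stop("config error: absolute policy needs threshold")
    t_s <- threshold
    t_r <- threshold
  }
  lab <- label_components_3d(s > t_s)
  ch_name <- if (is.character(channel)) channel else
    if (!is.null(stack$channel_names)) stack$channel_names[channel] else
      as.character(channel)
  if (lab$n == 0L) {
    return(focus_set(empty_focus_features(), list(), d, vs, peaks = list()))
  }
  vox_by_obj <- split(lab$index, lab$label)
  voxvol <- prod(vs)
  feats <- list()
  voxels <- list()
  peaks <- list()
  oid <- 0L
  for (cand in vox_by_obj) {
    cand_co <- arrayInd(cand, d)
    # resolvable maxima of the matched-filtered image inside the candidate
    pk_idx <- object_peaks(s, cand, cand_co, d)
    pk_pos_all <- coords_to_um(arrayInd(pk_idx, d), vs)
    sel <- merge_peaks(pk_pos_all, s[pk_idx], split_min_sep_um)
    seeds <- pk_pos_all[sel, , drop = FALSE]
    if (nrow(seeds) <= 1L) {
      part <- rep(1L, length(cand))
    } else {
      # assign candidate voxels to the nearest resolvable maximum
      part <- apply(cross_dist_um(coords_to_um(cand_co, vs), seeds),
                    1, which.min)
    }
    for (pi in sort(unique(part))) {
      sub_vox <- cand[part == pi]
      keep <- sub_vox[x[sub_vox] > t_r]
      if (length(keep) == 0L) keep <- sub_vox[which.max(x[sub_vox])]
      if (length(keep) > 1L) {
        # refinement/splitting can disconnect: keep the component holding
        # the brightest raw voxel
        sub <- array(FALSE, d)
        sub[keep] <- TRUE
        sl <- label_components_3d(sub)
        top <- keep[which.max(x[keep])]
        keep <- sl$index[sl$label == sl$label[match(top, sl$index)]]
      }
      nv <- length(keep)
      if (nv < min_voxels || nv > max_voxels) next
      co <- arrayInd(keep, d)
      w <- x[keep]
      pos <- coords_to_um(co, vs)
      cen <- colSums(pos * w) / sum(w)
      pk_idx2 <- object_peaks(s, keep, co, d)
      pk_pos <- coords_to_um(arrayInd(pk_idx2, d), vs)
      pk_val <- s[pk_idx2]
      sel2 <- merge_peaks(pk_pos, pk_val, peak_min_sep_um)
      pk_pos <- pk_pos[sel2, , drop = FALSE]
      pk_val <- pk_val[sel2]
      border <- any(co == 1L) || any(sweep(co, 2, d, "-") == 0L)
      oid <- oid + 1L
      feats[[oid]] <- data.frame(
        object_id = oid, channel = ch_name, cell_id = NA_integer_,
        z_um = cen[1], y_um = cen[2], x_um = cen[3],
        n_voxels = nv, volume_um3 = nv * voxvol,
        integrated_density = sum(w), peak_count = nrow(pk_pos),
        border = border, stringsAsFactors = FALSE)
      voxels[[oid]] <- sort(keep)
      peaks[[oid]] <- cbind(pk_pos, value = pk_val)
    }
  }
  if (oid == 0L) {
    return(focus_set(empty_focus_features(), list(), d, vs, peaks = list()))
  }
  feats <- do.call(rbind, feats)
  fs <- focus_set(feats, voxels, d, vs, peaks = peaks)
  if (!is.null(nuclei)) fs <- assign_cells(fs, nuclei)
  fs
}

# Local maxima of `s` within the voxel set `keep`: voxels >= all of their
# 26 neighbors that also lie in the object.
object_peaks <- function(s, keep, co, d) {
  offs <- neighbor_offsets_26()
  inobj <- array(FALSE, d)
  inobj[keep] <- TRUE
  best <- rep(TRUE, length(keep))
  for (kk in seq_len(nrow(offs))) {
    nz <- co[, 1] + offs[kk, 1]
    ny <- co[, 2] + offs[kk, 2]
    nx <- co[, 3] + offs[kk, 3]
    ok <- nz >= 1L & nz <= d[1] & ny >= 1L & ny <= d[2] & nx >= 1L & nx <= d[3]
    idx <- which(ok)
    if (length(idx) == 0L) next
    nl <- nz[idx] + (ny[idx] - 1L) * d[1] + (nx[idx] - 1L) * (d[1] * d[2])
    cmp <- s[keep[idx]] >= s[nl]
    best[idx] <- best[idx] & cmp
  }
  keep[best]
}

#' Segment nuclei from the DAPI channel
#'
#' Otsu-threshold segmentation of the nuclear counterstain: the channel is
#' smoothed, thresholded by Otsu's method (nuclei occupy too large a
#' volume fraction for a robust background model), and 26-connected
#' components above `min_volume_um3` become nuclei. Masks touching the
#' image border are flagged. Masks whose volume deviates strongly from the
#' volume of the ellipsoid implied by their own second moments are flagged
#' as `merged` (a fused pair of nuclei is markedly non-ellipsoidal).
#'
#' @param stack an [image_stack()].
#' @param dapi_channel channel index or name (default "dapi").
#' @param min_volume_um3 minimum nucleus volume (default 20).
#' @param smooth_sigma_um smoothing sigma in um.
#' @param solidity_threshold masks with moment-ellipsoid solidity below
#'   this are flagged merged (default 0.9).
#' @return object of class `nucleus_masks`: list with `features`
#'   (`cell_id`, centroid, `volume_um3`, `border`, `merged`), `voxels`,
#'   `dim`, `voxel_size`.
#' @export
segment_nuclei <- function(stack, dapi_channel = "dapi",
                           min_volume_um3 = 20,
                           smooth_sigma_um = c(0.3, 0.2, 0.2),
                           solidity_threshold = 0.9) {
  x <- get_channel(stack, dapi_channel)
  vs <- stack$voxel_size
  d <- dim(x)
  if (all(x == 0)) {
    return(structure(list(features = data.frame(cell_id = integer(0),
                                                z_um = numeric(0),
                                                y_um = numeric(0),
                                                x_um = numeric(0),
                                                volume_um3 = numeric(0),
                                                border = logical(0),
                                                merged = logical(0)),
                          voxels = list(), dim = d, voxel_size = vs),
                     class = "nucleus_masks"))
  }
  s <- gaussian_blur_3d(x, smooth_sigma_um / vs)
  thr <- otsu_threshold(as.vector(s))
  lab <- label_components_3d(s > thr)
  voxvol <- prod(vs)
  feats <- list()
  voxels <- list()
  cid <- 0L
  if (lab$n > 0L) {
    for (vox in split(lab$index, lab$label)) {
      vol <- length(vox) * voxvol
      if (vol < min_volume_um3) next
      co <- arrayInd(vox, d)
      pos <- coords_to_um(co, vs)
      cen <- colMeans(pos)
      border <- any(co == 1L) || any(sweep(co, 2, d, "-") == 0L)
      cid <- cid + 1L
      feats[[cid]] <- data.frame(cell_id = cid, z_um = cen[1],
                                 y_um = cen[2], x_um = cen[3],
                                 volume_um3 = vol, border = border,
                                 merged = mask_solidity(pos, vol) <
                                   solidity_threshold)
      voxels[[cid]] <- sort(vox)
    }
  }
  feats <- if (cid > 0) do.call(rbind, feats) else
    data.frame(cell_id = integer(0), z_um = numeric(0), y_um = numeric(0),
               x_um = numeric(0), volume_um3 = numeric(0),
               border = logical(0), merged = logical(0))
  structure(list(features = feats, voxels = voxels, dim = d,
                 voxel_size = vs),
            class = "nucleus_masks")
}

# Ratio of actual mask volume to the volume of the uniform ellipsoid with
# the same second moments (semi-axes sqrt(5 * eigenvalue)). ~1 for a solid
# ellipsoid; ~0.8 for two fused equal ellipsoids.
mask_solidity <- function(pos_um, vol) {
  if (nrow(pos_um) < 10L) return(1)
  cv <- stats::cov(pos_um) * (nrow(pos_um) - 1) / nrow(pos_um)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  ev[ev < 1e-12] <- 1e-12
  vpred <- 4 / 3 * pi * prod(sqrt(5 * ev))
  vol / vpred
}

#' @export
print.nucleus_masks <- function(x, ...) {
  cat(sprintf("<nucleus_masks> %d nuclei\n", nrow(x$features)))
  invisible(x)
}

#' Assign foci to cells by majority overlap with nucleus masks
#'
#' @param foci a [focus_set()].
#' @param nuclei a [segment_nuclei()] result on the same grid.
#' @return the focus_set with `cell_id` filled (NA when a focus overlaps no
#'   nucleus); ties are broken by nearest nucleus centroid.
#' @export
assign_cells <- function(foci, nuclei) {
  if (!identical(foci$dim, nuclei$dim)) stop("mismatched voxel grids")
  if (nrow(nuclei$features) == 0L || n_foci(foci) == 0L) return(foci)
  label <- integer(prod(nuclei$dim))
  for (i in seq_along(nuclei$voxels)) {
    label[nuclei$voxels[[i]]] <- nuclei$features$cell_id[i]
  }
  ncen <- as.matrix(nuclei$features[, c("z_um", "y_um", "x_um")])
  for (i in seq_len(n_foci(foci))) {
    labs <- label[foci$voxels[[i]]]
    labs <- labs[labs > 0L]
    if (length(labs) == 0L) {
      foci$features$cell_id[i] <- NA_integer_
      next
    }
    tab <- table(labs)
    winners <- as.integer(names(tab)[tab == max(tab)])
    if (length(winners) > 1L) {
      p <- as.numeric(foci$features[i, c("z_um", "y_um", "x_um")])
      dd <- cross_dist_um(matrix(p, 1), ncen)
      cand <- nuclei$features$cell_id
      winners <- winners[which.min(dd[1, match(winners, cand)])]
    }
    foci$features$cell_id[i] <- winners[1L]
  }
  foci
}

#' Classify telomere foci as singlets or doublets
#'
#' Operationalizes doublet scoring (two partially overlapping telomeric
#' signals) as: foci whose voxel sets overlap or touch (26-adjacency) are
#' grouped, and a group is a doublet iff it carries at least two intensity
#' local maxima separated by at least the lateral resolution limit and at
#' least `min_prominence` of the group's brightest peak. A single object
#' with two resolvable internal maxima is likewise a doublet; disjoint
#' objects are separate singlets.
#'
#' @param foci a [focus_set()] from one channel (peaks recorded by
#'   [detect_foci()]).
#' @param min_separation_um resolution floor between countable peaks
#'   (default 0.115 um, the 3D-SIM lateral resolution).
#' @param min_prominence secondary peaks below this fraction of the main
#'   peak are ignored (default 0.3, guards against noise ripples).
#' @return data.frame `object_id`, `group`, `n_peaks` (resolvable peaks of
#'   the group), `label` ("singlet"/"doublet"); attribute
#'   `fraction_singlet` is the fraction of groups scored singlet.
#' @export
classify_singlet_doublet <- function(foci, min_separation_um = 0.115,
                                     min_prominence = 0.3) {
  n <- n_foci(foci)
  if (n == 0L) {
    out <- data.frame(object_id = integer(0), group = integer(0),
                      n_peaks = integer(0), label = character(0))
    attr(out, "fraction_singlet") <- NA_real_
    return(out)
  }
  group <- touching_groups(foci)
  labs <- character(n)
  npk <- integer(n)
  for (g in unique(group)) {
    members <- which(group == g)
    pk <- do.call(rbind, lapply(members, function(i) foci$peaks[[i]]))
    if (is.null(pk) || nrow(pk) == 0L) {
      cnt <- 1L
    } else {
      val <- pk[, "value"]
      pk2 <- pk[val >= min_prominence * max(val), , drop = FALSE]
      sel <- merge_peaks(pk2[, 1:3, drop = FALSE], pk2[, "value"],
                         min_separation_um)
      cnt <- length(sel)
    }
    npk[members] <- cnt
    labs[members] <- if (cnt >= 2L) "doublet" else "singlet"
  }
  out <- data.frame(object_id = foci$features$object_id, group = group,
                    n_peaks = npk, label = labs)
  grp_lab <- tapply(labs, group, function(v) v[1L])
  attr(out, "fraction_singlet") <- mean(grp_lab == "singlet")
  out
}

# Group foci whose voxel sets overlap or are 26-adjacent (checked only for
# pairs with nearby centroids, for speed).
touching_groups <- function(foci, max_centroid_dist_um = 1.5) {
  n <- n_foci(foci)
  if (n == 1L) return(1L)
  pos <- as.matrix(foci$features[, c("z_um", "y_um", "x_um")])
  dd <- cross_dist_um(pos, pos)
  d <- foci$dim
  adj <- matrix(0, n, n)
  co_cache <- lapply(foci$voxels, function(v) arrayInd(v, d))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (dd[i, j] > max_centroid_dist_um) next
      ci <- co_cache[[i]]; cj <- co_cache[[j]]
      touch <- FALSE
      for (r in seq_len(nrow(ci))) {
        if (any(abs(cj[, 1] - ci[r, 1]) <= 1L &
                abs(cj[, 2] - ci[r, 2]) <= 1L &
                abs(cj[, 3] - ci[r, 3]) <= 1L)) {
          touch <- TRUE
          break
        }
      }
      if (touch) adj[i, j] <- adj[j, i] <- 1
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  as.integer(igraph::components(g)$membership)
}

#' Per-focus integrated-density delta from the cell mean
#'
#' For each cell, the distance of each focus's integrated density from the
#' average integrated density of the foci of the same cell. Used as a
#' per-cell-normalized telomere-length proxy: cross-technique validation
#' correlates these deltas between independent markers of the same
#' telomeres.
#'
#' @param foci a [focus_set()] with `cell_id` assigned, or a data.frame
#'   with `cell_id` and `integrated_density`.
#' @return the feature data.frame with an added `density_delta` column
#'   (deltas sum to zero within each cell).
#' @export
integrated_density_delta <- function(foci) {
  df <- if (inherits(foci, "focus_set")) foci$features else foci
  if (nrow(df) == 0L) stop("no foci: cannot compute deltas for an empty cell")
  if (any(is.na(df$cell_id))) {
    stop("all foci must carry a cell assignment")
  }
  mu <- stats::ave(df$integrated_density, df$cell_id)
  df$density_delta <- df$integrated_density - mu
  df
}

#' Match detected foci to ground-truth emitters
#'
#' Greedy nearest-centroid matching in physical units, used for
#' recall/precision and proxy-validation analyses against the synthetic
#' ground truth.
#'
#' @param foci a [focus_set()].
#' @param truth data.frame with `z_um`, `y_um`, `x_um` (e.g.
#'   `scene$truth$foci` rows of one channel).
#' @param max_dist_um maximum match distance (default 0.4).
#' @return data.frame `focus_row`, `truth_row`, `dist_um` (one row per
#'   matched pair).
#' @export
match_to_truth <- function(foci, truth, max_dist_um = 0.4) {
  if (n_foci(foci) == 0L || nrow(truth) == 0L) {
    return(data.frame(focus_row = integer(0), truth_row = integer(0),
                      dist_um = numeric(0)))
  }
  a <- as.matrix(foci$features[, c("z_um", "y_um", "x_um")])
  b <- as.matrix(truth[, c("z_um", "y_um", "x_um")])
  dd <- cross_dist_um(a, b)
  pairs <- which(dd <= max_dist_um, arr.ind = TRUE)
  if (nrow(pairs) == 0L) {
    return(data.frame(focus_row = integer(0), truth_row = integer(0),
                      dist_um = numeric(0)))
  }
  ord <- order(dd[pairs])
  pairs <- pairs[ord, , drop = FALSE]
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  keep <- list(); ki <- 0L
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    ki <- ki + 1L
    keep[[ki]] <- data.frame(focus_row = i, truth_row = j,
                             dist_um = dd[i, j])
  }
  do.call(rbind, keep)
}
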