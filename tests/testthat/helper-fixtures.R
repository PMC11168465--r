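# Shared fixtures and independent oracles. Everything is built in code;
# no binary fixtures.

# --- focus_set builders ------------------------------------------------

# Build a focus_set from a list of voxel-coordinate matrices (z,y,x rows).
make_focus_set <- function(coord_list, d = c(8L, 32L, 32L),
                           vs = c(0.3, 0.133, 0.133),
                           intensities = NULL) {
  vox <- lapply(coord_list, function(co) {
    co <- matrix(as.integer(co), ncol = 3)
    sort(telotrack:::zyx_to_linear(co, d))
  })
  feats <- do.call(rbind, lapply(seq_along(coord_list), function(i) {
    co <- matrix(as.integer(coord_list[[i]]), ncol = 3)
    cen <- colMeans(telotrack:::coords_to_um(co, vs))
    data.frame(object_id = i, channel = "x", cell_id = 1L,
               z_um = cen[1], y_um = cen[2], x_um = cen[3],
               n_voxels = nrow(co), volume_um3 = nrow(co) * prod(vs),
               integrated_density = if (is.null(intensities)) nrow(co)
               else intensities[i],
               peak_count = 1L, border = FALSE)
  }))
  focus_set(feats, vox, d, vs)
}

# Random small focus set: n objects, each a random box of voxels.
random_focus_set <- function(n, d = c(8L, 32L, 32L), seed = 1,
                             max_extent = 3L) {
  telotrack:::with_rng(seed, {
    coords <- lapply(seq_len(n), function(i) {
      ext <- sample.int(max_extent, 3, replace = TRUE)
      lo <- c(sample.int(d[1] - ext[1], 1), sample.int(d[2] - ext[2], 1),
              sample.int(d[3] - ext[3], 1))
      as.matrix(expand.grid(lo[1]:(lo[1] + ext[1] - 1L),
                            lo[2]:(lo[2] + ext[2] - 1L),
                            lo[3]:(lo[3] + ext[3] - 1L)))
    })
    make_focus_set(coords, d = d)
  })
}

# --- brute-force oracles ----------------------------------------------

# Overlap colocalization by direct voxel-set intersection over all pairs.
oracle_overlap <- function(a, b) {
  out <- list()
  for (i in seq_len(n_foci(a))) {
    for (j in seq_len(n_foci(b))) {
      shared <- length(intersect(a$voxels[[i]], b$voxels[[j]]))
      if (shared >= 1L) {
        out[[length(out) + 1L]] <- data.frame(
          focus_a = a$features$object_id[i],
          focus_b = b$features$object_id[j],
          shared_voxels = shared)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(focus_a = integer(0), focus_b = integer(0),
                      shared_voxels = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$focus_a, res$focus_b), ]
}

# Three-way partition by direct intersection of the pair union with every
# C focus.
oracle_triple <- function(pairs, a, b, c_set) {
  lab <- character(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    va <- a$voxels[[match(pairs$focus_a[r], a$features$object_id)]]
    vb <- b$voxels[[match(pairs$focus_b[r], b$features$object_id)]]
    u <- union(va, vb)
    hit <- FALSE
    for (k in seq_len(n_foci(c_set))) {
      if (length(intersect(u, c_set$voxels[[k]])) >= 1L) { hit <- TRUE; break }
    }
    lab[r] <- if (hit) "telomeric" else "extratelomeric"
  }
  lab
}

# Exhaustive minimal-total-displacement frame-to-frame assignment.
# prev, cur: position matrices; returns integer vector: for each cur row,
# the prev row it links to (NA = new track). Enumerates all injective
# mappings (feasible for <= 5 particles).
oracle_assign <- function(prev, cur, max_disp) {
  np <- nrow(prev); nc <- nrow(cur)
  dd <- telotrack:::cross_dist_um(prev, cur)
  best <- NULL; best_cost <- Inf; best_n <- -1L
  assignments <- function(cand_prev, j, cur_assign, cost, used) {
    if (j > nc) {
      n_linked <- sum(!is.na(cur_assign))
      # prefer more links, then lower cost (a linker should not drop a
      # feasible link: unlinked detections start new tracks)
      if (n_linked > best_n ||
          (n_linked == best_n && cost < best_cost)) {
        best <<- cur_assign; best_cost <<- cost; best_n <<- n_linked
      }
      return(invisible(NULL))
    }
    assignments(cand_prev, j + 1L, cur_assign, cost, used)  # leave j new
    for (i in seq_len(np)) {
      if (!used[i] && dd[i, j] <= max_disp) {
        ca <- cur_assign; ca[j] <- i
        u <- used; u[i] <- TRUE
        assignments(cand_prev, j + 1L, ca, cost + dd[i, j], u)
      }
    }
  }
  assignments(seq_len(np), 1L, rep(NA_integer_, nc), 0, rep(FALSE, np))
  best
}

# Hand log-rank: observed-minus-expected over pooled event times.
oracle_logrank <- function(ta, tb) {
  times <- sort(unique(c(ta, tb)))
  O <- 0; E <- 0; V <- 0
  for (tt in times) {
    n1 <- sum(ta >= tt); n2 <- sum(tb >= tt); n <- n1 + n2
    d1 <- sum(ta == tt); d2 <- sum(tb == tt); d <- d1 + d2
    if (n < 1 || d == 0) next
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# --- small synthetic configs ------------------------------------------

small_scene <- function(seed = 1, ...) {
  defaults <- list(image_shape = c(12L, 128L, 128L), n_cells = 1L,
                   nucleus_radius = c(1.5, 7, 7), telomeres_per_cell = 10L,
                   rna_spots_per_cell = 3L, doublet_fraction = 0,
                   seed = seed)
  do.call(scene_config, utils::modifyList(defaults, list(...)))
}

quiet_noise <- function(cfg) {
  cfg$background <- 0; cfg$gain <- 0; cfg$read_sd <- 0
  cfg$intensity_per_length <- 1000
  telotrack:::validate_scene_config(cfg)
}
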