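test_that("nuclei are segmented with centroids matching the truth", {
  cfg <- scene_config(image_shape = c(14L, 200L, 200L), n_cells = 3L,
                      nucleus_radius = c(1.5, 5.5, 5.5),
                      telomeres_per_cell = 5L, rna_spots_per_cell = 0L,
                      seed = 2)
  sc <- generate_fish_scene(cfg)
  nuc <- segment_nuclei(sc$stack)
  expect_equal(nrow(nuc$features), 3L)
  got <- as.matrix(nuc$features[, c("z_um", "y_um", "x_um")])
  want <- as.matrix(sc$truth$cells[, c("z_um", "y_um", "x_um")])
  dd <- telotrack:::cross_dist_um(got, want)
  expect_true(all(apply(dd, 2, min) < 0.3))  # within one (axial) voxel
  expect_false(any(nuc$features$merged))
})

test_that("an all-zero stack yields no nuclei", {
  st <- image_stack(array(0, c(1, 6, 24, 24)),
                    channel_names = "dapi")
  nuc <- segment_nuclei(st)
  expect_equal(nrow(nuc$features), 0L)
})

test_that("two fused ellipsoids become one mask flagged as merged", {
  d <- c(12L, 90L, 90L)
  vs <- c(0.3, 0.133, 0.133)
  arr <- array(0, d)
  co <- arrayInd(seq_len(prod(d)), d)
  pos <- telotrack:::coords_to_um(co, vs)
  r <- c(1.2, 2.2, 2.2)
  for (cen in list(c(1.65, 6, 3.8), c(1.65, 6, 8.2))) {  # 4.4 um apart = 2*r_x
    rel <- sweep(sweep(pos, 2, cen, "-"), 2, r, "/")
    arr[rowSums(rel^2) <= 1] <- 150
  }
  st <- image_stack(array(arr, c(1, d)), voxel_size = vs,
                    channel_names = "dapi")
  nuc <- segment_nuclei(st)
  expect_equal(nrow(nuc$features), 1L)
  expect_true(nuc$features$merged[1])

  # control: a single ellipsoid is not flagged
  arr2 <- array(0, d)
  rel <- sweep(sweep(pos, 2, c(1.65, 6, 6), "-"), 2, r, "/")
  arr2[rowSums(rel^2) <= 1] <- 150
  st2 <- image_stack(array(arr2, c(1, d)), voxel_size = vs,
                     channel_names = "dapi")
  nuc2 <- segment_nuclei(st2)
  expect_equal(nrow(nuc2$features), 1L)
  expect_false(nuc2$features$merged[1])
})

test_that("well-separated planted spots are recovered exactly at SNR 5", {
  # constant length: every planted spot sits exactly at peak SNR 5
  cfg <- small_scene(seed = 13, telomeres_per_cell = 6L,
                     rna_spots_per_cell = 0L, snr = 5,
                     telomere_length_sdlog = 1e-9)
  sc <- generate_fish_scene(cfg)
  tr <- sc$truth$foci
  # guard: this fixed seed gives well-separated spots
  pos <- as.matrix(tr[, c("z_um", "y_um", "x_um")])
  dd <- telotrack:::cross_dist_um(pos, pos); diag(dd) <- Inf
  expect_gt(min(dd), 1)
  fs <- detect_foci(sc$stack, "telomere")
  expect_equal(n_foci(fs), nrow(tr))
  m <- match_to_truth(fs, tr)
  expect_equal(nrow(m), nrow(tr))
  expect_true(all(m$dist_um < 0.3))  # < 1 (axial) voxel
})

test_that("uniform background yields zero foci", {
  telotrack:::with_rng(9, {
    arr <- array(rpois(6 * 40 * 40, 10), c(1, 6, 40, 40))
  })
  fs <- detect_foci(image_stack(arr), 1)
  expect_equal(n_foci(fs), 0L)
})

test_that("a constant cube has exact integrated density and volume", {
  d <- c(10L, 24L, 24L)
  arr <- array(0, d)
  arr[4:6, 10:12, 10:12] <- 50
  st <- image_stack(array(arr, c(1, d)))
  fs <- detect_foci(st, 1, min_voxels = 1)
  expect_equal(n_foci(fs), 1L)
  expect_equal(fs$features$integrated_density, 27 * 50)
  expect_equal(fs$features$volume_um3, 27 * prod(st$voxel_size))
  expect_equal(fs$features$n_voxels, 27L)
  # brute-force feature recomputation over the stored voxel set
  x <- get_channel(st, 1)
  expect_equal(sum(x[fs$voxels[[1]]]), fs$features$integrated_density)
})

test_that("unknown threshold policy is a config error", {
  st <- image_stack(array(0, c(1, 4, 8, 8)))
  expect_error(detect_foci(st, 1, threshold_policy = "banana"),
               "config error")
  expect_error(detect_foci(st, 1, threshold_policy = "absolute"),
               "config error")
})

test_that("singlet/doublet scoring follows peak structure", {
  d <- c(12L, 64L, 64L)
  vs <- c(0.3, 0.133, 0.133)
  psf <- c(0.4, 0.17, 0.17)
  fwhm <- 2.3548 * psf[2]
  base <- c(1.8, 4.2, 4.2)
  render <- function(centers) {
    arr <- array(0, d)
    for (cen in centers) {
      arr <- telotrack:::render_emitter(arr, cen, 5000, psf, vs)
    }
    image_stack(array(arr, c(1, d)), voxel_size = vs)
  }
  # planted doublet at 1.2 x FWHM separation
  sep <- 1.2 * fwhm
  st <- render(list(base, base + c(0, 0, sep)))
  fs <- detect_foci(st, 1)
  cls <- classify_singlet_doublet(fs)
  expect_true(all(cls$label == "doublet"))
  expect_equal(length(unique(cls$group)), 1L)

  # isolated spot: singlet with one peak
  st1 <- render(list(base))
  fs1 <- detect_foci(st1, 1)
  cls1 <- classify_singlet_doublet(fs1)
  expect_equal(nrow(cls1), 1L)
  expect_equal(cls1$label, "singlet")
  expect_equal(fs1$features$peak_count, 1L)

  # two spots at 5 x FWHM: two disjoint singlets
  st2 <- render(list(base, base + c(0, 0, 5 * fwhm)))
  fs2 <- detect_foci(st2, 1)
  cls2 <- classify_singlet_doublet(fs2)
  expect_equal(nrow(cls2), 2L)
  expect_true(all(cls2$label == "singlet"))
  expect_equal(length(unique(cls2$group)), 2L)
  expect_equal(attr(cls2, "fraction_singlet"), 1)
})

test_that("integrated-density deltas are centered per cell", {
  df <- data.frame(cell_id = c(1, 1, 1, 2),
                   integrated_density = c(2, 4, 6, 5))
  out <- integrated_density_delta(df)
  expect_equal(out$density_delta, c(-2, 0, 2, 0))
  # deltas sum to zero within each cell (random property case)
  telotrack:::with_rng(2, {
    df2 <- data.frame(cell_id = sample(1:5, 60, replace = TRUE),
                      integrated_density = runif(60, 10, 1000))
  })
  out2 <- integrated_density_delta(df2)
  sums <- tapply(out2$density_delta, out2$cell_id, sum)
  expect_true(all(abs(sums) < 1e-9 * max(df2$integrated_density)))
  expect_error(integrated_density_delta(df[0, ]), "empty")
})

test_that("detection recall/precision hold on a mid-size crowded scene", {
  cfg <- scene_config(image_shape = c(14L, 144L, 144L), n_cells = 1L,
                      nucleus_radius = c(1.6, 6.5, 6.5),
                      telomeres_per_cell = 15L, rna_spots_per_cell = 0L,
                      seed = 31)
  sc <- generate_fish_scene(cfg)
  fs <- detect_foci(sc$stack, "telomere")
  tr <- sc$truth$foci
  pos <- as.matrix(tr[, c("z_um", "y_um", "x_um")])
  # resolution-clustered truth: emitters closer than ~the matched-filter
  # resolution cannot be separated by any detector; the recall claim
  # conditions on per-emitter peak SNR >= 5 (the scene's snr parameter is
  # set at the median length, so the log-normal tail can dip below)
  snr_i <- tr$intensity *
    telotrack:::psf_peak_fraction(cfg$psf_sigma, cfg$voxel_size) /
    telotrack:::scene_noise_sd(cfg)
  ddm <- telotrack:::cross_dist_um(pos, pos)
  g <- igraph::graph_from_adjacency_matrix((ddm <= 0.4) * 1,
                                           mode = "undirected", diag = FALSE)
  cl <- igraph::components(g)$membership
  fpos <- as.matrix(fs$features[, c("z_um", "y_um", "x_um")])
  d2 <- telotrack:::cross_dist_um(fpos, pos)
  covered <- apply(d2 <= 0.4, 2, any)
  bright <- tapply(snr_i, cl, max) >= 5
  recall <- mean(tapply(covered, cl, any)[bright])
  precision <- mean(apply(d2 <= 0.4, 1, any))
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})
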