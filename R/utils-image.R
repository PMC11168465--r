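# Low-level 3D image helpers shared by the generator and the detectors.
# Arrays are (z, y, x), column-major linear indices throughout.

# Evaluate expr with a private RNG stream; the caller's .Random.seed is
# untouched. seed = NULL uses the current stream (and does advance it).
with_rng <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

zyx_to_linear <- function(co, d) {
  # co: n x 3 integer matrix of (z, y, x); d: dim vector
  as.integer(co[, 1] + (co[, 2] - 1) * d[1] + (co[, 3] - 1) * (d[1] * d[2]))
}

linear_to_zyx <- function(idx, d) {
  arrayInd(idx, d)
}

# Physical centroid (um) of voxel coordinates, optionally intensity weighted.
# Voxel (1,1,1) center sits at 0 um on each axis.
coords_to_um <- function(co, voxel_size) {
  sweep(co - 1, 2, voxel_size, "*")
}

cross_dist_um <- function(a, b) {
  # a: n x 3, b: m x 3 physical coordinates -> n x m Euclidean distances
  dz <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  dx <- outer(a[, 3], b[, 3], "-")
  sqrt(dz^2 + dy^2 + dx^2)
}

neighbor_offsets_26 <- function() {
  g <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  as.matrix(g[!(g$dz == 0 & g$dy == 0 & g$dx == 0), ])
}

# Connected components of a logical 3D mask, 26-connectivity.
# Returns list(index = linear indices of foreground, label = component id
# per foreground voxel, n = number of components).
label_components_3d <- function(mask) {
  d <- dim(mask)
  fg <- which(mask)
  if (length(fg) == 0L) {
    return(list(index = integer(0), label = integer(0), n = 0L))
  }
  pos <- integer(prod(d))
  pos[fg] <- seq_along(fg)
  co <- arrayInd(fg, d)
  offs <- neighbor_offsets_26()
  offs <- offs[offs[, 1] > 0 |
                 (offs[, 1] == 0 & (offs[, 2] > 0 |
                                      (offs[, 2] == 0 & offs[, 3] > 0))), ,
               drop = FALSE]  # forward half, each pair counted once
  efrom <- integer(0); eto <- integer(0)
  for (k in seq_len(nrow(offs))) {
    nz <- co[, 1] + offs[k, 1]
    ny <- co[, 2] + offs[k, 2]
    nx <- co[, 3] + offs[k, 3]
    ok <- nz >= 1L & nz <= d[1] & ny >= 1L & ny <= d[2] & nx >= 1L & nx <= d[3]
    if (!any(ok)) next
    nidx <- nz[ok] + (ny[ok] - 1L) * d[1] + (nx[ok] - 1L) * (d[1] * d[2])
    hit <- pos[nidx] > 0L
    if (!any(hit)) next
    efrom <- c(efrom, pos[fg[ok][hit]])
    eto <- c(eto, pos[nidx[hit]])
  }
  if (length(efrom) == 0L) {
    return(list(index = fg, label = seq_along(fg), n = length(fg)))
  }
  g <- igraph::make_graph(edges = rbind(efrom, eto), n = length(fg),
                          directed = FALSE)
  cmp <- igraph::components(g)
  list(index = fg, label = as.integer(cmp$membership), n = cmp$no)
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

conv_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(arr, perm)
  dp <- dim(ap)
  m <- matrix(ap, nrow = dp[1])
  r <- (length(kernel) - 1L) %/% 2L
  n <- nrow(m)
  # replicate edges to avoid darkening at the borders
  top <- m[rep(1L, r), , drop = FALSE]
  bot <- m[rep(n, r), , drop = FALSE]
  mp <- rbind(top, m, bot)
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(kernel)) {
    out <- out + kernel[j] * mp[j:(j + n - 1L), , drop = FALSE]
  }
  res <- array(out, dp)
  aperm(res, order(perm))
}

# Separable Gaussian blur; sigma_vox in voxel units per (z, y, x) axis.
gaussian_blur_3d <- function(arr, sigma_vox) {
  out <- arr
  for (axis in 1:3) {
    if (sigma_vox[axis] > 1e-8) {
      out <- conv_axis(out, gaussian_kernel_1d(sigma_vox[axis]), axis)
    }
  }
  out
}

shift_array_3d <- function(arr, dz, dy, dx, fill = -Inf) {
  d <- dim(arr)
  out <- array(fill, d)
  src_z <- max(1, 1 - dz):min(d[1], d[1] - dz)
  src_y <- max(1, 1 - dy):min(d[2], d[2] - dy)
  src_x <- max(1, 1 - dx):min(d[3], d[3] - dx)
  out[src_z + dz, src_y + dy, src_x + dx] <- arr[src_z, src_y, src_x]
  out
}

# Linear indices of voxels that are >= all 26 neighbors (plateau-tolerant;
# callers deduplicate nearby maxima in physical units).
local_maxima_3d <- function(arr, min_value = -Inf) {
  keep <- array(TRUE, dim(arr))
  offs <- neighbor_offsets_26()
  for (k in seq_len(nrow(offs))) {
    keep <- keep & (arr >= shift_array_3d(arr, offs[k, 1], offs[k, 2],
                                          offs[k, 3], fill = -Inf))
    if (!any(keep)) break
  }
  which(keep & arr > min_value)
}
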