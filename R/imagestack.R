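#' Multi-channel 3D image stack
#'
#' An `image_stack` is the in-memory container for a multi-channel 3D
#' acquisition: a numeric array indexed `(channel, z, y, x)` plus the
#' physical voxel dimensions in micrometres. Time-lapse data are held as an
#' [image_movie()] (a list of stacks sharing one geometry). Confocal
#' acquisitions are strongly anisotropic (default 0.3 um axial step versus
#' 0.133 um lateral pixels), so every distance computed by the package is in
#' physical units, never in voxel units.
#'
#' @param voxels numeric array with dimensions `(channel, z, y, x)`.
#'   A 3D array is promoted to a single-channel stack.
#' @param voxel_size numeric length-3, micrometres per voxel along
#'   `(z, y, x)`. Default `c(0.3, 0.133, 0.133)`.
#' @param channel_names optional character vector naming the channels.
#' @return An object of class `image_stack`.
#' @examples
#' st <- image_stack(array(0, c(1, 4, 8, 8)))
#' dim_zyx(st)
#' @export
image_stack <- function(voxels, voxel_size = c(0.3, 0.133, 0.133),
                        channel_names = NULL) {
  if (length(dim(voxels)) == 3L) {
    voxels <- array(voxels, c(1L, dim(voxels)))
  }
  stopifnot(length(dim(voxels)) == 4L)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0)) {
    stop("voxel_size must be three strictly positive values (z, y, x)")
  }
  if (any(voxels < 0, na.rm = TRUE)) {
    stop("intensities must be non-negative")
  }
  if (!is.null(channel_names)) {
    stopifnot(length(channel_names) == dim(voxels)[1L])
  }
  structure(list(voxels = voxels, voxel_size = voxel_size,
                 channel_names = channel_names),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d channel(s), %d x %d x %d (z,y,x) voxels\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  voxel size (um): z=%.3g y=%.3g x=%.3g\n",
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  if (!is.null(x$channel_names)) {
    cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Spatial dimensions of a stack
#'
#' @param stack an [image_stack()].
#' @return integer length-3 `(z, y, x)`.
#' @export
dim_zyx <- function(stack) {
  dim(stack$voxels)[2:4]
}

#' Number of channels in a stack
#' @param stack an [image_stack()].
#' @return integer count.
#' @export
n_channels <- function(stack) {
  dim(stack$voxels)[1L]
}

#' Extract one channel as a 3D array
#'
#' @param stack an [image_stack()].
#' @param channel integer index or channel name.
#' @return numeric 3D array `(z, y, x)`.
#' @export
get_channel <- function(stack, channel) {
  ch <- resolve_channel(stack, channel)
  arr <- stack$voxels[ch, , , , drop = FALSE]
  dim(arr) <- dim(stack$voxels)[2:4]
  arr
}

resolve_channel <- function(stack, channel) {
  if (is.character(channel)) {
    if (is.null(stack$channel_names)) stop("stack has no channel names")
    ch <- match(channel, stack$channel_names)
    if (is.na(ch)) stop(sprintf("channel '%s' not present", channel))
    return(ch)
  }
  ch <- as.integer(channel)
  if (ch < 1L || ch > n_channels(stack)) stop("channel index out of range")
  ch
}

#' Time-lapse movie of image stacks
#'
#' A thin container for a two-channel (or more) time series: a list of
#' [image_stack()] frames sharing geometry, plus the frame interval in
#' seconds. Frame `i` corresponds to time `(i - 1) * frame_interval`.
#'
#' @param frames list of [image_stack()] objects with identical dimensions.
#' @param frame_interval seconds between consecutive frames (default 5).
#' @return An object of class `image_movie`.
#' @export
image_movie <- function(frames, frame_interval = 5) {
  stopifnot(length(frames) >= 1L, frame_interval > 0)
  d0 <- dim(frames[[1L]]$voxels)
  ok <- vapply(frames, function(f) identical(dim(f$voxels), d0), logical(1))
  if (!all(ok)) stop("all frames must share dimensions")
  structure(list(frames = frames, frame_interval = as.numeric(frame_interval)),
            class = "image_movie")
}

#' @export
print.image_movie <- function(x, ...) {
  cat(sprintf("<image_movie> %d frames, dt=%gs\n",
              length(x$frames), x$frame_interval))
  print(x$frames[[1L]])
  invisible(x)
}

#' Frame times of a movie
#' @param movie an [image_movie()].
#' @return numeric vector of times in seconds, starting at 0.
#' @export
frame_times <- function(movie) {
  (seq_along(movie$frames) - 1) * movie$frame_interval
}

#' Write / read a stack as a long-format voxel table
#'
#' Plain-text serialization used instead of TIFF (no TIFF codec is part of
#' this package's dependency set). Only voxels with non-zero intensity are
#' stored, one row per `(channel, z, y, x, value)`.
#'
#' @param stack an [image_stack()].
#' @param path CSV file path.
#' @return `write_stack_csv` returns `path` invisibly; `read_stack_csv`
#'   returns an [image_stack()].
#' @export
write_stack_csv <- function(stack, path) {
  arr <- stack$voxels
  idx <- which(arr != 0)
  co <- arrayInd(idx, dim(arr))
  df <- data.frame(channel = co[, 1], z = co[, 2], y = co[, 3], x = co[, 4],
                   value = arr[idx])
  header <- sprintf("# dim=%s voxel_size=%s",
                    paste(dim(arr), collapse = ","),
                    paste(stack$voxel_size, collapse = ","))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stack_csv
#' @export
read_stack_csv <- function(path) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header,
                  regexec("dim=([0-9,]+) voxel_size=([0-9.,eE+-]+)", header))[[1]]
  if (length(m) != 3L) stop("malformed stack CSV header")
  d <- as.integer(strsplit(m[2], ",")[[1]])
  vs <- as.numeric(strsplit(m[3], ",")[[1]])
  df <- utils::read.csv(path, skip = 1L)
  arr <- array(0, d)
  arr[cbind(df$channel, df$z, df$y, df$x)] <- df$value
  image_stack(arr, voxel_size = vs)
}
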