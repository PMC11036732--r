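#' Construct a timed frame stream
#'
#' A frame stream is the in-memory form of a decoded slow-motion video clip:
#' an ordered list of 8-bit RGB rasters with per-frame timestamps. The
#' recording protocol asks for at least 180 frames/s, so the stream carries
#' its estimated sampling rate and downstream code assumes uniform sampling.
#'
#' @param images list of `H x W x 3` numeric/integer arrays with values in
#'   `[0, 255]` (channel order red, green, blue).
#' @param timestamps numeric vector of per-frame times in seconds, strictly
#'   increasing and uniformly spaced to within `1e-6` s.
#' @param expected_min_fps protocol minimum sampling rate in Hz; a stream
#'   below it is accepted with a warning (default 180).
#'
#' @return An object of class `gtr_frames`: a list with elements `images`,
#'   `timestamps`, `index` (0-based frame ordinals) and `fs` (Hz), where
#'   `fs = (n - 1) / (t_last - t_first)`.
#' @export
frame_stream <- function(images, timestamps, expected_min_fps = 180) {
  if (!is.list(images) || length(images) < 2L)
    gtr_stop("frame stream needs at least 2 frames", "gtr_decode_error")
  if (length(timestamps) != length(images))
    gtr_stop("timestamps and images differ in length", "gtr_stream_integrity_error")
  dt <- diff(timestamps)
  if (any(dt <= 0))
    gtr_stop("frame timestamps are not strictly increasing", "gtr_stream_integrity_error")
  if (length(dt) > 1L && (max(dt) - min(dt)) > 1e-6)
    gtr_stop("frame timestamps are not uniformly spaced (tolerance 1e-6 s)",
             "gtr_stream_integrity_error")
  for (k in seq_along(images)) {
    d <- dim(images[[k]])
    if (length(d) != 3L || d[3] != 3L || d[1] < 32L || d[2] < 32L)
      gtr_stop(sprintf("frame %d is not an HxWx3 raster with H,W >= 32", k - 1L),
               "gtr_decode_error")
  }
  n <- length(images)
  fs <- (n - 1) / (timestamps[n] - timestamps[1])
  if (fs < expected_min_fps)
    gtr_warn(sprintf("frame rate %.1f Hz is below the expected minimum of %g Hz",
                     fs, expected_min_fps), "gtr_low_fps_warning")
  structure(list(images = images, timestamps = as.numeric(timestamps),
                 index = seq_len(n) - 1L, fs = fs),
            class = "gtr_frames")
}

#' Read a decoded frame sequence from disk
#'
#' Video container decoding is delegated to the recording toolchain: a clip
#' is presented to the pipeline as a directory of per-frame PNG images plus
#' a `timestamps.csv` sidecar with columns `frame_index,timestamp`. Only the
#' timestamps and frame count are consumed as metadata; the sampling rate is
#' re-estimated from the timestamps.
#'
#' @param path directory containing `frame_<index>.png` files and
#'   `timestamps.csv`.
#' @inheritParams frame_stream
#' @return A `gtr_frames` stream (see [frame_stream()]).
#' @export
read_frames <- function(path, expected_min_fps = 180) {
  if (!dir.exists(path))
    gtr_stop(sprintf("cannot decode '%s': no such directory", path), "gtr_decode_error")
  ts_file <- file.path(path, "timestamps.csv")
  if (!file.exists(ts_file))
    gtr_stop(sprintf("cannot decode '%s': missing timestamps.csv", path), "gtr_decode_error")
  meta <- utils::read.csv(ts_file)
  if (nrow(meta) < 2L)
    gtr_stop(sprintf("cannot decode '%s': fewer than 2 frames", path), "gtr_decode_error")
  meta <- meta[order(meta$frame_index), , drop = FALSE]
  if (!requireNamespace("png", quietly = TRUE))
    gtr_stop("reading PNG frame sequences requires the 'png' package", "gtr_decode_error")
  images <- lapply(meta$frame_index, function(i) {
    f <- file.path(path, sprintf("frame_%06d.png", i))
    if (!file.exists(f))
      gtr_stop(sprintf("cannot decode '%s': missing %s", path, basename(f)),
               "gtr_decode_error")
    img <- png::readPNG(f)
    if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
    round(img[, , 1:3, drop = FALSE] * 255)
  })
  frame_stream(images, meta$timestamp, expected_min_fps = expected_min_fps)
}

#' Write a frame stream as a PNG sequence with a timestamp sidecar
#'
#' @param frames a `gtr_frames` stream.
#' @param path output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path) {
  stopifnot(inherits(frames, "gtr_frames"))
  if (!requireNamespace("png", quietly = TRUE))
    gtr_stop("writing PNG frame sequences requires the 'png' package", "gtr_decode_error")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(frames$images)) {
    png::writePNG(frames$images[[k]] / 255,
                  file.path(path, sprintf("frame_%06d.png", frames$index[k])))
  }
  utils::write.csv(data.frame(frame_index = frames$index,
                              timestamp = frames$timestamps),
                   file.path(path, "timestamps.csv"), row.names = FALSE)
  invisible(path)
}

#' @export
print.gtr_frames <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("<gtr_frames> %d frames, %dx%d px, fs = %.2f Hz (interval %.2f ms)\n",
              length(x$images), d[1], d[2], x$fs, 1000 / x$fs))
  invisible(x)
}

#' Frame interval implied by a sampling rate
#'
#' Convenience for the protocol constant: at the minimum recommended rate of
#' 180 frames/s the interval between consecutive images is 1000/180 = 5.6 ms.
#'
#' @param fs sampling rate in Hz.
#' @return Frame interval in milliseconds.
#' @export
frame_interval_ms <- function(fs) {
  stopifnot(is.numeric(fs), fs > 0)
  1000 / fs
}
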