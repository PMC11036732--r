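#' Construct a 1D pipeline signal
#'
#' The pipeline reduces a clip to two uniformly sampled series: the tapping
#' channel (mean blue intensity in the glabellar ROI, elevated while the
#' blue-gloved finger covers it) and the blinking channel (inverted count of
#' non-zero eye pixels, so lid closure produces positive peaks). Conditioning
#' state is tracked explicitly and its order is enforced:
#' raw -> baseline_removed -> filtered.
#'
#' @param values numeric samples; `NA` marks missing samples and is only
#'   allowed while `conditioning = "raw"`.
#' @param fs sampling rate in Hz.
#' @param t0 time of the first sample in seconds.
#' @param channel `"tapping"` or `"blinking"`.
#' @param conditioning `"raw"`, `"baseline_removed"` or `"filtered"`.
#' @param params named list of conditioning parameters (provenance).
#' @return An object of class `gtr_signal`.
#' @export
gtr_signal <- function(values, fs, t0 = 0,
                       channel = c("tapping", "blinking"),
                       conditioning = c("raw", "baseline_removed", "filtered"),
                       params = list()) {
  channel <- match.arg(channel)
  conditioning <- match.arg(conditioning)
  stopifnot(is.numeric(fs), fs > 0, length(values) >= 2L)
  if (conditioning != "raw" && anyNA(values))
    gtr_stop("conditioned signals must not contain missing samples",
             "gtr_validation_error")
  structure(list(values = as.numeric(values), fs = fs, t0 = t0,
                 channel = channel, conditioning = conditioning,
                 params = params),
            class = "gtr_signal")
}

#' @export
print.gtr_signal <- function(x, ...) {
  cat(sprintf("<gtr_signal> %s/%s, %d samples @ %.1f Hz, t0 = %.3f s\n",
              x$channel, x$conditioning, length(x$values), x$fs, x$t0))
  invisible(x)
}

#' Sample times of a signal
#' @param s a `gtr_signal`.
#' @return Numeric vector of sample times in seconds.
#' @export
signal_times <- function(s) s$t0 + (seq_along(s$values) - 1L) / s$fs

resolve_rois <- function(rois, n, what) {
  # accept a single ROI (static geometry) or a per-frame list; NULL entries
  # (face-detection gaps) reuse the last valid ROI
  if (!is.list(rois) || inherits(rois, c("gtr_roi_polygon", "gtr_eye_roi")))
    rois <- rep(list(rois), n)
  if (length(rois) != n)
    gtr_stop(sprintf("%s: need one ROI per frame (%d vs %d)", what, length(rois), n),
             "gtr_validation_error")
  last <- NULL
  for (k in seq_len(n)) {
    if (is.null(rois[[k]])) {
      if (is.null(last))
        gtr_stop(sprintf("%s: no valid ROI before frame %d", what, k - 1L),
                 "gtr_validation_error")
      rois[[k]] <- last
    } else last <- rois[[k]]
  }
  rois
}

#' Tapping signal: mean blue intensity in the glabellar ROI
#'
#' For every frame, the blue channel is averaged over the pixels whose
#' centres fall inside the glabellar polygon. Bare skin sets the baseline
#' level; while the examiner's blue glove covers the region the mean rises,
#' which is what makes the tap time point detectable.
#'
#' @param frames a `gtr_frames` stream.
#' @param rois a single `gtr_roi_polygon` or a per-frame list (NULL entries
#'   reuse the previous valid ROI).
#' @return A raw tapping `gtr_signal`.
#' @export
tapping_signal <- function(frames, rois) {
  stopifnot(inherits(frames, "gtr_frames"))
  n <- length(frames$images)
  rois <- resolve_rois(rois, n, "tapping_signal")
  d <- dim(frames$images[[1]])
  vals <- numeric(n)
  cache_key <- NULL; cache_mask <- NULL; clipped_warned <- FALSE
  for (k in seq_len(n)) {
    v <- rois[[k]]$vertices
    key <- c(v)
    if (is.null(cache_key) || !identical(key, cache_key)) {
      if (any(v[, 1] < 0) || any(v[, 2] < 0) || any(v[, 1] > d[2]) || any(v[, 2] > d[1])) {
        if (!clipped_warned) {
          gtr_warn("glabellar ROI extends outside the frame; clipping", "gtr_roi_clip_warning")
          clipped_warned <- TRUE
        }
      }
      cache_mask <- polygon_mask(v, d[1:2])
      cache_key <- key
      if (is.null(cache_mask$mask) || !any(cache_mask$mask))
        gtr_stop("glabellar ROI empty after clipping to the frame", "gtr_geometry_error")
    }
    blue <- frames$images[[k]][cache_mask$rows, cache_mask$cols, 3]
    vals[k] <- mean(blue[cache_mask$mask])
  }
  gtr_signal(vals, frames$fs, t0 = frames$timestamps[1], channel = "tapping")
}

#' Blinking signal: inverted non-zero eye-pixel count
#'
#' For every frame, pixels inside the eye bounding box but outside the lid
#' contour are set to zero, the remaining non-zero pixels are counted, and
#' the count series is inverted as `max(count) - count` so that lid closure
#' (a shrinking lid contour, hence fewer non-zero pixels) yields positive
#' peaks while an open eye sits near zero.
#'
#' @param frames a `gtr_frames` stream.
#' @param rois a single `gtr_eye_roi` or per-frame list.
#' @return A raw blinking `gtr_signal`.
#' @export
blinking_signal <- function(frames, rois) {
  stopifnot(inherits(frames, "gtr_frames"))
  n <- length(frames$images)
  rois <- resolve_rois(rois, n, "blinking_signal")
  d <- dim(frames$images[[1]])
  counts <- numeric(n)
  for (k in seq_len(n)) {
    pm <- polygon_mask(rois[[k]]$lid_contour, d[1:2])
    if (is.null(pm$mask)) { counts[k] <- 0; next }
    px <- frames$images[[k]][pm$rows, pm$cols, , drop = FALSE]
    nonzero <- (px[, , 1] + px[, , 2] + px[, , 3]) > 0
    counts[k] <- sum(nonzero & pm$mask)
  }
  if (all(counts == 0))
    gtr_stop("eye ROI contains no non-zero pixels in any frame; nothing to invert against",
             "gtr_signal_degenerate_error")
  gtr_signal(max(counts) - counts, frames$fs, t0 = frames$timestamps[1],
             channel = "blinking")
}

#' Baseline removal by running percentile subtraction
#'
#' Sets the signal to a common baseline by subtracting a running 10th
#' percentile computed over a centred window. Percentile tracking follows
#' slow drift (illumination, ROI size changes) while leaving upward event
#' peaks essentially untouched, provided the window is a few times longer
#' than the longest event. Missing samples (face-detection gaps) are filled
#' by linear interpolation, bounded by their neighbours, before the
#' percentile runs.
#'
#' @param s a raw `gtr_signal`.
#' @param window_s window length in seconds (default 2; keep it above three
#'   times the longest expected event).
#' @param probs percentile tracked as baseline (default 0.10).
#' @return A `gtr_signal` with `conditioning = "baseline_removed"`.
#' @export
remove_baseline <- function(s, window_s = 2, probs = 0.10) {
  stopifnot(inherits(s, "gtr_signal"))
  if (s$conditioning != "raw")
    gtr_stop("remove_baseline expects a raw signal", "gtr_conditioning_error")
  w <- round(window_s * s$fs)
  if (w < 3)
    gtr_stop("baseline window shorter than 3 samples", "gtr_config_error")
  if (w %% 2 == 0) w <- w + 1  # odd window: unambiguous centre sample
  v <- s$values
  if (anyNA(v)) v <- zoo::na.approx(v, na.rm = FALSE, rule = 2)
  base <- zoo::rollapply(zoo::zoo(v), width = w, align = "center", partial = TRUE,
                         FUN = function(z) unname(quantile(z, probs)))
  gtr_signal(v - as.numeric(base), s$fs, s$t0, s$channel,
             conditioning = "baseline_removed",
             params = c(s$params, list(baseline_window_s = window_s,
                                       baseline_percentile = probs)))
}

#' Zero-phase low-pass filtering
#'
#' Forward-backward (zero-phase) Butterworth filter, order 4 per pass. The
#' default analysis cutoff of 0.75 Hz suppresses illumination flicker; the
#' squared magnitude response of the two passes gives gain 0.5 at the
#' cutoff and leaves event peak times unshifted, which matters because
#' blink classification uses a millisecond-scale window around taps.
#'
#' @param s a baseline-removed `gtr_signal`.
#' @param cutoff_hz cutoff frequency in Hz (default 0.75); must be below
#'   the Nyquist frequency `fs/2`.
#' @param order filter order per pass (default 4).
#' @return A `gtr_signal` with `conditioning = "filtered"`.
#' @export
lowpass_filter <- function(s, cutoff_hz = 0.75, order = 4) {
  stopifnot(inherits(s, "gtr_signal"))
  if (s$conditioning != "baseline_removed")
    gtr_stop("lowpass_filter expects a baseline-removed signal (conditioning order is raw -> baseline_removed -> filtered)",
             "gtr_conditioning_error")
  if (cutoff_hz <= 0 || cutoff_hz >= s$fs / 2)
    gtr_stop(sprintf("cutoff %.3g Hz must lie in (0, fs/2 = %.3g Hz)",
                     cutoff_hz, s$fs / 2), "gtr_config_error")
  bf <- signal::butter(order, cutoff_hz / (s$fs / 2), type = "low")
  # Forward-backward passes run by hand: the signal is extended by even
  # (mirror) reflection at both ends, which preserves the local signal
  # level, and each pass starts from the steady state of its first sample,
  # so start-up transients decay inside the pads instead of ringing into
  # the record (a concern at low cutoff-to-fs ratios, where transients are
  # seconds long).
  b <- bf$b; a <- bf$a
  v <- s$values
  n <- length(v)
  pad <- min(n - 1L, ceiling(3 * s$fs / cutoff_hz))
  ext <- c(v[(pad + 1L):2], v, v[(n - 1L):(n - pad)])
  steady <- function(x) as.numeric(signal::filter(b, a, x,
    init.x = rep(x[1], length(b) - 1L), init.y = rep(x[1], length(a) - 1L)))
  out <- rev(steady(rev(steady(ext))))[(pad + 1L):(pad + n)]
  gtr_signal(out, s$fs, s$t0, s$channel, conditioning = "filtered",
             params = c(s$params, list(lowpass_cutoff_hz = cutoff_hz,
                                       lowpass_order = order)))
}

#' Full conditioning chain
#'
#' Convenience wrapper applying [remove_baseline()] then [lowpass_filter()].
#'
#' @inheritParams remove_baseline
#' @inheritParams lowpass_filter
#' @return A filtered `gtr_signal`.
#' @export
condition_signal <- function(s, window_s = 2, cutoff_hz = 0.75) {
  lowpass_filter(remove_baseline(s, window_s = window_s), cutoff_hz = cutoff_hz)
}

#' Write / read a signal as CSV plus JSON sidecar
#'
#' The CSV holds `time_s,value`; the sidecar `<path>.json` records fs, t0,
#' channel, conditioning and all conditioning parameters for provenance.
#'
#' @param s a `gtr_signal`.
#' @param path CSV output path.
#' @return `path` (write) / a `gtr_signal` (read).
#' @export
write_signal <- function(s, path) {
  stopifnot(inherits(s, "gtr_signal"))
  data.table::fwrite(data.table::data.table(time_s = signal_times(s),
                                            value = s$values), path)
  meta <- list(fs = s$fs, t0 = s$t0, channel = s$channel,
               conditioning = s$conditioning, params = s$params)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_signal
#' @export
read_signal <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(meta_path))
    gtr_stop(sprintf("signal file '%s' or its JSON sidecar is missing", path),
             "gtr_parse_error")
  tab <- data.table::fread(path)
  meta <- jsonlite::fromJSON(meta_path)
  gtr_signal(tab$value, meta$fs, t0 = meta$t0, channel = meta$channel,
             conditioning = meta$conditioning, params = as.list(meta$params))
}
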