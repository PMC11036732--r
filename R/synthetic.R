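# Ground-truthed synthetic GTR sessions at three levels: event schedules,
# 1D signals, and rendered frame + landmark streams. The generator encodes
# the recording protocol (>= 180 frames/s; 5-8 taps at an irregular rhythm
# slower than 2 per second; reflex blinks inside the -50/+200 ms window;
# spontaneous blinks between taps; blink durations spanning ~0.05-0.45 s)
# so every pipeline stage can be validated against known truth.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Synthetic session configuration
#'
#' @param fs sampling rate in Hz (protocol minimum 180).
#' @param duration_s total session length; `NULL` sizes it from the tap
#'   schedule plus lead-in/tail.
#' @param n_taps tap count in 5..8; `NULL` draws it uniformly.
#' @param tap_interval_range_s inter-tap interval bounds; the lower bound
#'   must exceed 0.5 s (slower than 2 taps/s).
#' @param p_reflex_per_tap probability that a tap elicits a reflex blink.
#' @param reflex_latency_range_s tap-to-apex latency bounds, strictly
#'   interior to the -50/+200 ms classification window so boundary rules
#'   cannot flip labels.
#' @param non_reflex_rate_hz Poisson rate of spontaneous blinks.
#' @param blink_duration_range_s half-maximum blink duration bounds.
#' @param blink_amplitude blinking-signal pulse amplitude (a.u.).
#' @param tap_blue_level,skin_blue_level 8-bit blue intensities of the
#'   glove and of bare skin.
#' @param tap_contact_s glove contact duration per tap.
#' @param flicker_hz,flicker_amplitude illumination flicker sinusoid.
#' @param noise_sd additive Gaussian noise SD (signal units).
#' @param lead_in_s,tail_s silence before the first and after the last tap.
#' @param seed RNG seed; every level of the generator is deterministic in it.
#' @return A list of class `gtr_synth_config`.
#' @export
synthetic_config <- function(fs = 180, duration_s = NULL, n_taps = NULL,
                             tap_interval_range_s = c(0.6, 2.5),
                             p_reflex_per_tap = 0.9,
                             reflex_latency_range_s = c(0.010, 0.180),
                             non_reflex_rate_hz = 0.5,
                             blink_duration_range_s = c(0.05, 0.45),
                             blink_amplitude = 50,
                             tap_blue_level = 220, skin_blue_level = 90,
                             tap_contact_s = 0.15,
                             flicker_hz = 25, flicker_amplitude = 2,
                             noise_sd = 1,
                             lead_in_s = 1.5, tail_s = 1.5,
                             seed = 1L) {
  stopifnot(fs > 0, tap_interval_range_s[1] > 0.5,
            diff(tap_interval_range_s) >= 0,
            p_reflex_per_tap >= 0, p_reflex_per_tap <= 1,
            reflex_latency_range_s[1] > -0.050,
            reflex_latency_range_s[2] < 0.200,
            diff(reflex_latency_range_s) >= 0,
            non_reflex_rate_hz >= 0,
            blink_duration_range_s[1] > 0, diff(blink_duration_range_s) >= 0,
            tap_blue_level > skin_blue_level)
  if (!is.null(n_taps)) stopifnot(n_taps >= 5L, n_taps <= 8L)
  structure(as.list(environment()), class = "gtr_synth_config")
}

#' Raised-cosine blink pulse
#'
#' `A/2 * (1 + cos(2*pi*(t - t0)/(2*D)))` on `|t - t0| <= D`, zero outside.
#' Chosen as the blink waveform because its width at half maximum is exactly
#' the duration parameter `D`, making ground truth unambiguous.
#'
#' @param t time vector (s).
#' @param t0 apex time (s).
#' @param D width at half maximum (s).
#' @param A amplitude.
#' @return Numeric vector.
#' @export
raised_cosine_pulse <- function(t, t0, D, A = 1) {
  out <- numeric(length(t))
  m <- abs(t - t0) <= D
  out[m] <- A / 2 * (1 + cos(pi * (t[m] - t0) / D))
  out
}

#' Sample a ground-truth session schedule
#'
#' Draws the tap schedule (irregular rhythm), reflex blinks (per-tap
#' Bernoulli with latency inside the classification window), and
#' spontaneous blinks (thinned Poisson process with a 1 s dead time around
#' every other blink apex, so pulses never merge). Reflex blink durations
#' are capped so that neighbouring-tap reflex pulses cannot overlap.
#' Spontaneous blinks falling before the first tap are true
#' `pre_first_tap` events.
#'
#' @param cfg a [synthetic_config()].
#' @return A list of class `gtr_truth` with `tap_times_s`, `blinks`
#'   (`data.frame`: `time_s, category, duration_s, amplitude, assigned_tap`),
#'   `duration_s`, `fs`, `config`.
#' @export
sample_session <- function(cfg = synthetic_config()) {
  with_seed(cfg$seed, {
    n_taps <- if (is.null(cfg$n_taps)) sample(5:8, 1L) else as.integer(cfg$n_taps)
    gaps <- runif(n_taps - 1L, cfg$tap_interval_range_s[1], cfg$tap_interval_range_s[2])
    taps <- cfg$lead_in_s + cumsum(c(0, gaps))
    duration <- if (is.null(cfg$duration_s)) taps[n_taps] + cfg$tail_s else cfg$duration_s
    if (duration < taps[n_taps] + 0.5)
      gtr_stop("duration_s too short for the sampled tap schedule", "gtr_generation_error")

    dmin <- cfg$blink_duration_range_s[1]; dmax <- cfg$blink_duration_range_s[2]
    # reflex blinks
    r_time <- numeric(0); r_dur <- numeric(0); r_tap <- integer(0)
    hit <- runif(n_taps) < cfg$p_reflex_per_tap
    lat <- runif(n_taps, cfg$reflex_latency_range_s[1], cfg$reflex_latency_range_s[2])
    for (k in seq_len(n_taps)) {
      if (!hit[k]) next
      t0 <- taps[k] + lat[k]
      r_time <- c(r_time, t0); r_tap <- c(r_tap, k)
    }
    # duration caps keep neighbouring reflex pulses disjoint (margin 0.1 s)
    for (i in seq_along(r_time)) {
      cap <- dmax
      if (i > 1L) cap <- min(cap, (r_time[i] - r_time[i - 1L]) / 2 - 0.05)
      if (i < length(r_time)) cap <- min(cap, (r_time[i + 1L] - r_time[i]) / 2 - 0.05)
      cap <- max(cap, dmin)
      r_dur[i] <- runif(1, dmin, max(dmin, min(dmax, cap)))
    }
    # spontaneous blinks: homogeneous candidates thinned by the reflex
    # windows (0.05 s guard) and a 1 s dead time around any accepted apex
    lo <- 0.6; hi <- duration - 0.6
    s_time <- numeric(0); s_dur <- numeric(0)
    if (cfg$non_reflex_rate_hz > 0 && hi > lo) {
      n_cand <- rpois(1, cfg$non_reflex_rate_hz * (hi - lo))
      cand <- sort(runif(n_cand, lo, hi))
      for (t0 in cand) {
        if (any(t0 >= taps - 0.05 - 0.05 & t0 <= taps + 0.200 + 0.05)) next
        if (any(abs(t0 - c(r_time, s_time)) < 1.0)) next
        s_time <- c(s_time, t0)
        s_dur <- c(s_dur, runif(1, dmin, dmax))
      }
    }
    blinks <- data.frame(
      time_s = c(r_time, s_time),
      category = c(rep("reflex", length(r_time)),
                   ifelse(s_time < taps[1] - 0.05, "pre_first_tap", "non_reflex")),
      duration_s = c(r_dur, s_dur),
      amplitude = cfg$blink_amplitude * runif(length(r_time) + length(s_time), 0.8, 1.2),
      assigned_tap = c(r_tap, ifelse(s_time < taps[1] - 0.05, NA_integer_,
                                     findInterval(s_time, taps))))
    blinks <- blinks[order(blinks$time_s), ]
    rownames(blinks) <- NULL
    structure(list(tap_times_s = taps, blinks = blinks,
                   duration_s = duration, fs = cfg$fs, config = cfg),
              class = "gtr_truth")
  })
}

#' Synthesise the 1D tapping and blinking signals of a session
#'
#' Tapping: skin blue level plus a trapezoid (2-frame ramps) up to the
#' glove level during each contact. Blinking: the sum of raised-cosine
#' pulses whose exact half-maximum width is each blink's true duration.
#' Both channels receive the illumination-flicker sinusoid and Gaussian
#' noise. Noise draws are seeded from the session seed.
#'
#' @param truth a `gtr_truth` from [sample_session()].
#' @param cfg the session's [synthetic_config()] (defaults to the one
#'   stored in `truth`).
#' @return List with raw `tapping` and `blinking` `gtr_signal`s.
#' @export
synthesize_signals <- function(truth, cfg = truth$config) {
  n <- round(truth$duration_s * cfg$fs) + 1L
  t <- (seq_len(n) - 1L) / cfg$fs
  ramp <- 2 / cfg$fs
  tap <- rep(0, n)
  half <- cfg$tap_contact_s / 2
  for (tt in truth$tap_times_s) {
    prof <- pmax(0, pmin(1, (half + ramp - abs(t - tt)) / ramp))
    tap <- pmax(tap, prof)
  }
  tapping <- cfg$skin_blue_level + (cfg$tap_blue_level - cfg$skin_blue_level) * tap
  blinking <- rep(0, n)
  for (i in seq_len(nrow(truth$blinks)))
    blinking <- blinking + raised_cosine_pulse(t, truth$blinks$time_s[i],
                                               truth$blinks$duration_s[i],
                                               truth$blinks$amplitude[i])
  with_seed(cfg$seed + 1L, {
    flick <- cfg$flicker_amplitude * sin(2 * pi * cfg$flicker_hz * t)
    tapping <- tapping + flick + rnorm(n, sd = cfg$noise_sd)
    blinking <- blinking + flick + rnorm(n, sd = cfg$noise_sd)
  })
  list(tapping = gtr_signal(tapping, cfg$fs, channel = "tapping"),
       blinking = gtr_signal(blinking, cfg$fs, channel = "blinking"))
}

# face geometry used by the renderer, in normalised coordinates
synth_geometry <- function() {
  # eyes are drawn large relative to a real face so the aperture spans
  # enough pixel rows for the non-zero-pixel count to track the closure
  # waveform smoothly even at small frame sizes
  list(glabella_center = c(0.50, 0.22),
       glabella_half = c(0.06, 0.04),      # diamond half-extent (x, y)
       right_eye = list(center = c(0.28, 0.55), a = 0.220, b0 = 0.160),
       left_eye = list(center = c(0.74, 0.55), a = 0.170, b0 = 0.120),
       closure_max = 0.9)
}

eye_hexagon <- function(center, a, b) {
  s <- sqrt(3) / 2
  cbind(x = center[1] + c(-a, -a / 2, a / 2, a, a / 2, -a / 2),
        y = center[2] + c(0, -b * s, -b * s, 0, b * s, b * s))
}

#' Render a session to frames and a landmark stream
#'
#' Produces a deliberately schematic clip: a flat skin-tone face patch, an
#' elliptical eye aperture whose height follows the blink waveform for both
#' eyes (the camera-near right eye drawn larger, emulating the 45 degree
#' recording angle), and a blue rectangle over the glabella while the glove
#' is in contact. The landmark stream places the glabellar diamond and the
#' six-point eyelid contours consistently with the rendered geometry in
#' every frame, so the pixel route and the direct signal route can be
#' cross-checked.
#'
#' @param truth a `gtr_truth`.
#' @param cfg the session's [synthetic_config()].
#' @param frame_size `c(height, width)` in pixels, at least 48 each.
#' @return List with `frames` (`gtr_frames`), `landmarks`
#'   (`gtr_landmarks`, provenance `"synthetic"`) and `geometry`
#'   (normalised layout incl. the true glabella centre).
#' @export
render_session <- function(truth, cfg = truth$config, frame_size = c(96, 96)) {
  if (min(frame_size) < 48)
    gtr_stop("frame size too small for the face geometry (min 48 px)",
             "gtr_config_error")
  H <- frame_size[1]; W <- frame_size[2]
  geo <- synth_geometry()
  n <- round(truth$duration_s * cfg$fs) + 1L
  t <- (seq_len(n) - 1L) / cfg$fs
  # closure profile: raised cosine per blink, scaled by the blink's relative
  # amplitude so the pixel route reproduces the same waveform (up to gain)
  # as the direct signal route
  closure <- rep(0, n)
  amp_ref <- cfg$blink_amplitude * 1.2   # upper end of the amplitude jitter
  for (i in seq_len(nrow(truth$blinks)))
    closure <- closure + raised_cosine_pulse(t, truth$blinks$time_s[i],
                                             truth$blinks$duration_s[i],
                                             truth$blinks$amplitude[i] / amp_ref)
  closure <- pmin(closure, 1)
  # glove occlusion fraction per frame: same trapezoid (2-frame ramps) as
  # the direct signal synthesis, so the two routes agree
  ramp <- 2 / cfg$fs
  half <- cfg$tap_contact_s / 2
  tap_prof <- rep(0, n)
  for (tt in truth$tap_times_s)
    tap_prof <- pmax(tap_prof, pmax(0, pmin(1, (half + ramp - abs(t - tt)) / ramp)))

  # static skin base
  base <- array(0L, c(H, W, 3))
  base[, , 1] <- 180L; base[, , 2] <- 140L; base[, , 3] <- as.integer(cfg$skin_blue_level)
  # glove rectangle: bounding box of the glabellar diamond plus 2 px
  gc <- geo$glabella_center * c(W, H); gh <- geo$glabella_half * c(W, H)
  gr <- max(1L, floor(gc[2] - gh[2]) - 2L):min(H, ceiling(gc[2] + gh[2]) + 2L)
  gcl <- max(1L, floor(gc[1] - gh[1]) - 2L):min(W, ceiling(gc[1] + gh[1]) + 2L)

  eye_px <- function(eye, b_norm) {
    cx <- eye$center[1] * W; cy <- eye$center[2] * H
    a <- eye$a * W; b <- max(b_norm * H, 0.5)
    rr <- max(1L, floor(cy - b)):min(H, ceiling(cy + b))
    cc <- max(1L, floor(cx - a)):min(W, ceiling(cx + a))
    xs <- (cc - 0.5 - cx) / a
    ys <- (rr - 0.5 - cy) / b
    mask <- outer(ys^2, xs^2, `+`) <= 1
    list(rows = rr, cols = cc, mask = mask)
  }

  base_points <- {
    id <- 0:467
    cbind(0.2 + 0.6 * ((id %% 26L) / 25), 0.15 + 0.7 * ((id %/% 26L) / 17), 0)
  }
  sets <- default_landmark_sets()
  s3 <- sqrt(3) / 2

  images <- vector("list", n)
  points <- vector("list", n)
  for (k in seq_len(n)) {
    img <- base
    for (eye in list(geo$right_eye, geo$left_eye)) {
      b_now <- eye$b0 * (1 - geo$closure_max * closure[k])
      ep <- eye_px(eye, b_now)
      for (ch in 1:3) {
        plane <- img[ep$rows, ep$cols, ch]
        plane[ep$mask] <- 230L
        img[ep$rows, ep$cols, ch] <- plane
      }
    }
    if (tap_prof[k] > 0) {
      a <- tap_prof[k]
      img[gr, gcl, 1] <- as.integer(round((1 - a) * 180 + a * 60))
      img[gr, gcl, 2] <- as.integer(round((1 - a) * 140 + a * 80))
      img[gr, gcl, 3] <- as.integer(round((1 - a) * cfg$skin_blue_level +
                                            a * cfg$tap_blue_level))
    }
    images[[k]] <- img

    p <- base_points
    p[sets$glabella + 1L, 1:2] <- rbind(
      geo$glabella_center + c(-geo$glabella_half[1], 0),
      geo$glabella_center + c(0, -geo$glabella_half[2]),
      geo$glabella_center + c(geo$glabella_half[1], 0),
      geo$glabella_center + c(0, geo$glabella_half[2]))
    for (side in c("right", "left")) {
      eye <- if (side == "right") geo$right_eye else geo$left_eye
      ids <- if (side == "right") sets$right_eye else sets$left_eye
      b_now <- eye$b0 * (1 - geo$closure_max * closure[k])
      p[ids + 1L, 1] <- eye$center[1] + c(-eye$a, -eye$a / 2, eye$a / 2,
                                          eye$a, eye$a / 2, -eye$a / 2)
      p[ids + 1L, 2] <- eye$center[2] + c(0, -b_now * s3, -b_now * s3,
                                          0, b_now * s3, b_now * s3)
    }
    points[[k]] <- p
  }
  frames <- frame_stream(images, t, expected_min_fps = 0)
  frames$fs <- cfg$fs
  lms <- landmark_stream(points, frames$index, t, fs = cfg$fs,
                         provenance = "synthetic")
  list(frames = frames, landmarks = lms, geometry = geo)
}

#' Write / read a ground-truth schedule as JSON
#'
#' @param truth a `gtr_truth`.
#' @param path JSON path.
#' @return `path` (write) / a `gtr_truth` (read). The config echo survives
#'   the round trip as a plain list.
#' @export
write_truth <- function(truth, path) {
  out <- list(tap_times_s = truth$tap_times_s, blinks = truth$blinks,
              duration_s = truth$duration_s, fs = truth$fs,
              config = truth$config[!vapply(truth$config, is.null, logical(1))])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::fromJSON(path)
  x$blinks <- as.data.frame(x$blinks)
  class(x) <- "gtr_truth"
  x
}
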