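#' Analysis configuration
#'
#' Bundles every tunable constant of the event layer. Defaults encode the
#' recording and analysis protocol: a reflex blink is one whose apex falls
#' from 50 ms before to 200 ms after a tap; signals are low-pass filtered at
#' 0.75 Hz; taps are delivered 5 to 8 times at an irregular rhythm slower
#' than 2 per second (hence a minimum tap separation of 0.4 s by default).
#' Prominence thresholds are fractions of the robust (5th-95th percentile)
#' signal range because both channels are in arbitrary units.
#'
#' @param reflex_window_before_s window extent before a tap, seconds.
#' @param reflex_window_after_s window extent after a tap, seconds.
#' @param lowpass_cutoff_hz analysis low-pass cutoff, Hz.
#' @param min_tap_separation_s minimum separation between detected taps.
#' @param min_blink_separation_s minimum separation between detected blinks.
#' @param tap_prominence_frac tap prominence threshold as a fraction of the
#'   robust range, in (0, 1).
#' @param blink_prominence_frac blink prominence threshold, in (0, 1).
#' @param expected_tap_count_range protocol tap count range.
#' @return A list of class `gtr_analysis_config`.
#' @export
analysis_config <- function(reflex_window_before_s = 0.050,
                            reflex_window_after_s = 0.200,
                            lowpass_cutoff_hz = 0.75,
                            min_tap_separation_s = 0.4,
                            min_blink_separation_s = 0.1,
                            tap_prominence_frac = 0.3,
                            blink_prominence_frac = 0.2,
                            expected_tap_count_range = c(5L, 8L)) {
  stopifnot(reflex_window_before_s > 0, reflex_window_after_s > 0,
            lowpass_cutoff_hz > 0, min_tap_separation_s > 0,
            min_blink_separation_s > 0,
            tap_prominence_frac > 0, tap_prominence_frac < 1,
            blink_prominence_frac > 0, blink_prominence_frac < 1)
  structure(list(reflex_window_before_s = reflex_window_before_s,
                 reflex_window_after_s = reflex_window_after_s,
                 lowpass_cutoff_hz = lowpass_cutoff_hz,
                 min_tap_separation_s = min_tap_separation_s,
                 min_blink_separation_s = min_blink_separation_s,
                 tap_prominence_frac = tap_prominence_frac,
                 blink_prominence_frac = blink_prominence_frac,
                 expected_tap_count_range = expected_tap_count_range),
            class = "gtr_analysis_config")
}

check_conditioned <- function(s, channel) {
  stopifnot(inherits(s, "gtr_signal"))
  if (s$channel != channel)
    gtr_stop(sprintf("expected a %s-channel signal, got %s", channel, s$channel),
             "gtr_contract_error")
  if (s$conditioning != "filtered")
    gtr_stop("event detection expects a conditioned (filtered) signal",
             "gtr_conditioning_error")
}

#' Detect taps on the conditioned tapping signal
#'
#' Taps appear as prominent maxima of the glabellar blue-channel mean while
#' the gloved finger covers the region. Local maxima with topographic
#' prominence of at least `tap_prominence_frac` times the robust signal
#' range are kept, thinned to `min_tap_separation_s`.
#'
#' @param s conditioned tapping `gtr_signal`.
#' @param cfg an [analysis_config()].
#' @return `data.frame` with columns `time_s`, `sample_index`, `prominence`,
#'   sorted by time. Zero detected taps yields an empty frame with a
#'   warning; more than 20 triggers a suspicious-signal warning (protocol
#'   is 5-8 taps).
#' @export
detect_taps <- function(s, cfg = analysis_config()) {
  check_conditioned(s, "tapping")
  pk <- detect_peaks(s, cfg$tap_prominence_frac, cfg$min_tap_separation_s)
  # the glove-contact bump is flat-topped, so the raw argmax is ambiguous
  # at the plateau scale; the centre of the half-prominence interval is the
  # robust tap timepoint
  if (nrow(pk) > 0L) {
    mid <- vapply(pk$sample_index, function(p)
      mean(half_height_interval(s$values, p)), numeric(1))
    pk$time_s <- s$t0 + (mid - 1) / s$fs
  }
  if (nrow(pk) == 0L)
    gtr_warn("no taps detected", "gtr_no_events_warning")
  else if (nrow(pk) > 20L)
    gtr_warn(sprintf("%d taps detected; protocol expects %d-%d - suspicious signal",
                     nrow(pk), cfg$expected_tap_count_range[1],
                     cfg$expected_tap_count_range[2]),
             "gtr_suspicious_signal_warning")
  pk[, c("time_s", "sample_index", "prominence")]
}

#' Detect blinks on the conditioned blinking signal
#'
#' Blink apices are prominent maxima of the inverted eye-pixel-count
#' signal. Each detected blink carries its duration, the width at half
#' prominence.
#'
#' @inheritParams detect_taps
#' @param s conditioned blinking `gtr_signal`.
#' @return `data.frame` with columns `time_s`, `sample_index`, `prominence`,
#'   `width_s` (uncategorised), sorted by time.
#' @export
detect_blinks <- function(s, cfg = analysis_config()) {
  check_conditioned(s, "blinking")
  pk <- detect_peaks(s, cfg$blink_prominence_frac, cfg$min_blink_separation_s)
  if (nrow(pk) == 0L)
    gtr_warn("no blinks detected", "gtr_no_events_warning")
  if (nrow(pk) > 0L) {
    ivs <- vapply(pk$sample_index,
                  function(p) half_height_interval(s$values, p), numeric(2))
    pk$width_s <- (ivs[2, ] - ivs[1, ]) / s$fs
    # apex estimate robust to flat tops: centre of the half-prominence
    # interval (identical to the argmax for a symmetric pulse)
    pk$time_s <- s$t0 + (colMeans(ivs) - 1) / s$fs
  } else pk$width_s <- numeric(0)
  pk[, c("time_s", "sample_index", "prominence", "width_s")]
}

#' Classify blinks as reflex, non-reflex or pre-first-tap
#'
#' A blink whose apex lies inside the closed interval
#' `[tap - reflex_window_before_s, tap + reflex_window_after_s]` of some tap
#' is a reflex blink assigned to that tap; when two windows overlap the
#' nearest tap wins (the earlier on an exact tie). Any other blink after
#' tap k and before tap k+1 (or after the last tap, through the end of the
#' recording) is a non-reflex blink assigned to tap k. Blinks before the
#' first tap's window are `pre_first_tap` and carry no tap assignment.
#'
#' @param blinks `data.frame` from [detect_blinks()].
#' @param taps `data.frame` from [detect_taps()] (sorted by time).
#' @param cfg an [analysis_config()].
#' @return `blinks` with added columns `category` and `assigned_tap`
#'   (1-based tap ordinal, `NA` for pre-first-tap blinks).
#' @export
classify_blinks <- function(blinks, taps, cfg = analysis_config()) {
  n_b <- nrow(blinks)
  category <- character(n_b)
  assigned <- rep(NA_integer_, n_b)
  tap_t <- taps$time_s
  if (length(tap_t) == 0L) {
    if (n_b) gtr_warn("no taps: every blink classified as pre_first_tap",
                      "gtr_no_events_warning")
    blinks$category <- rep("pre_first_tap", n_b)
    blinks$assigned_tap <- assigned
    return(blinks)
  }
  for (i in seq_len(n_b)) {
    t <- blinks$time_s[i]
    inwin <- which(t >= tap_t - cfg$reflex_window_before_s &
                   t <= tap_t + cfg$reflex_window_after_s)
    if (length(inwin)) {
      d <- abs(t - tap_t[inwin])
      k <- inwin[order(d, inwin)[1]]   # nearest tap, earlier on exact tie
      category[i] <- "reflex"; assigned[i] <- k
    } else {
      k <- findInterval(t, tap_t)      # largest k with tap_t[k] <= t
      if (k == 0L) category[i] <- "pre_first_tap"
      else { category[i] <- "non_reflex"; assigned[i] <- k }
    }
  }
  blinks$category <- category
  blinks$assigned_tap <- assigned
  blinks
}

#' Per-tap reflex and non-reflex blink counts
#'
#' @param blinks categorised blinks from [classify_blinks()].
#' @param n_taps number of taps in the session.
#' @return `data.frame` with columns `tap`, `reflex_count`,
#'   `non_reflex_count`; the counts plus the pre-first-tap blinks always sum
#'   to the total number of blinks.
#' @export
tapwise_counts <- function(blinks, n_taps) {
  tab <- data.frame(tap = seq_len(n_taps),
                    reflex_count = 0L, non_reflex_count = 0L)
  for (i in seq_len(nrow(blinks))) {
    k <- blinks$assigned_tap[i]
    if (is.na(k)) next
    if (blinks$category[i] == "reflex")
      tab$reflex_count[k] <- tab$reflex_count[k] + 1L
    else
      tab$non_reflex_count[k] <- tab$non_reflex_count[k] + 1L
  }
  tab
}

#' Assemble and summarise a subject record
#'
#' Rolls one session's events into the per-subject quantities reported per
#' cohort: per-tap counts and the average blink width per category.
#' Category averages are arithmetic means of the half-prominence widths;
#' a category with no blinks yields `NaN` ("there is no blinking").
#' Pre-first-tap blinks are excluded from both the averages and the count
#' table, which is indexed by tap number.
#'
#' @param subject_id identifier.
#' @param group `"iPD_before"`, `"iPD_after"` or `"HC"`.
#' @param taps detected taps.
#' @param blinks categorised blinks.
#' @return A list of class `gtr_subject` with fields `subject_id`, `group`,
#'   `taps`, `blinks`, `tapwise`, `avg_width_reflex_s`,
#'   `avg_width_non_reflex_s`.
#' @export
subject_summary <- function(subject_id, group = c("iPD_before", "iPD_after", "HC"),
                            taps, blinks) {
  group <- match.arg(group)
  if (!"category" %in% names(blinks))
    gtr_stop("blinks must be categorised before summarising", "gtr_contract_error")
  avg <- function(cat) {
    w <- blinks$width_s[blinks$category == cat]
    if (!length(w)) NaN else mean(w)
  }
  structure(list(subject_id = subject_id, group = group,
                 taps = taps, blinks = blinks,
                 tapwise = tapwise_counts(blinks, nrow(taps)),
                 avg_width_reflex_s = avg("reflex"),
                 avg_width_non_reflex_s = avg("non_reflex")),
            class = "gtr_subject")
}

#' Write detected events to CSV
#'
#' One row per event: `subject_id,event_type,time_s,prominence,width_s,category,assigned_tap`.
#'
#' @param subject a `gtr_subject`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(subject, path) {
  stopifnot(inherits(subject, "gtr_subject"))
  taps <- subject$taps; blinks <- subject$blinks
  tab <- rbind(
    data.frame(subject_id = subject$subject_id, event_type = "tap",
               time_s = taps$time_s, prominence = taps$prominence,
               width_s = NA_real_, category = NA_character_,
               assigned_tap = seq_len(nrow(taps))),
    data.frame(subject_id = subject$subject_id, event_type = "blink",
               time_s = blinks$time_s, prominence = blinks$prominence,
               width_s = blinks$width_s, category = blinks$category,
               assigned_tap = blinks$assigned_tap))
  tab <- tab[order(tab$time_s), ]
  data.table::fwrite(tab, path, na = "NA")
  invisible(path)
}
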