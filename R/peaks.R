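# Peak analysis primitives: local maxima, topographic prominence, and width
# at a fraction of prominence. Prominence follows the standard topographic
# definition: the peak height above the higher of the two minima separating
# it from higher terrain (or the signal edge) on either side.

#' Indices of local maxima
#'
#' Plateau-aware: a flat run counts as one maximum, located at its first
#' sample, when the run is higher than the differing samples on both sides
#' (signal edges do not qualify).
#'
#' @param v numeric vector.
#' @return Integer vector of 1-based indices.
#' @export
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  mid <- 2:(k - 1L)
  is_pk <- r$values[mid] > r$values[mid - 1L] & r$values[mid] > r$values[mid + 1L]
  starts[mid][is_pk]
}

#' Topographic prominence of a peak
#'
#' Walks outward from the peak on both sides until a strictly higher sample
#' or the signal edge is met; the minimum over each excursion is that side's
#' base. Prominence is the peak value minus the higher base.
#'
#' @param v numeric vector.
#' @param p 1-based index of a local maximum.
#' @return List with `prominence`, `left_base`, `right_base` (indices of the
#'   side minima).
#' @export
peak_prominence <- function(v, p) {
  if (!(p %in% local_maxima(v)))
    gtr_stop(sprintf("index %d is not a local maximum", p), "gtr_contract_error")
  n <- length(v)
  lmin <- v[p]; lbase <- p
  j <- p - 1L
  while (j >= 1L && v[j] <= v[p]) {
    if (v[j] < lmin) { lmin <- v[j]; lbase <- j }
    j <- j - 1L
  }
  rmin <- v[p]; rbase <- p
  j <- p + 1L
  while (j <= n && v[j] <= v[p]) {
    if (v[j] < rmin) { rmin <- v[j]; rbase <- j }
    j <- j + 1L
  }
  list(prominence = v[p] - max(lmin, rmin), left_base = lbase, right_base = rbase)
}

#' Peak width at a fraction of prominence
#'
#' Measures the horizontal extent of a peak at height
#' `peak - rel_height * prominence` (default half prominence, the blinking
#' duration definition). Crossings are located by linear interpolation
#' between the bracketing samples; if a side never crosses before its
#' prominence base, the width is clipped at that base.
#'
#' @param s a `gtr_signal`, or a plain numeric vector with `fs` supplied.
#' @param peak_index 1-based index of a local maximum.
#' @param rel_height fraction of prominence below the peak at which the
#'   width is measured (default 0.5).
#' @param fs sampling rate in Hz when `s` is a plain vector.
#' @return Width in seconds.
#' @export
width_at_half_prominence <- function(s, peak_index, rel_height = 0.5, fs = NULL) {
  if (inherits(s, "gtr_signal")) { v <- s$values; fs <- s$fs }
  else { v <- as.numeric(s); stopifnot(!is.null(fs)) }
  iv <- half_height_interval(v, peak_index, rel_height)
  (iv[2] - iv[1]) / fs
}

# fractional sample positions (1-based) where the signal crosses
# peak - rel_height * prominence on either side of the peak
half_height_interval <- function(v, peak_index, rel_height = 0.5) {
  pr <- peak_prominence(v, peak_index)
  h <- v[peak_index] - rel_height * pr$prominence
  j <- peak_index
  xl <- pr$left_base
  while (j > pr$left_base) {
    if (v[j - 1L] < h) { xl <- (j - 1L) + (h - v[j - 1L]) / (v[j] - v[j - 1L]); break }
    j <- j - 1L
  }
  j <- peak_index
  xr <- pr$right_base
  while (j < pr$right_base) {
    if (v[j + 1L] < h) { xr <- j + (v[j] - h) / (v[j] - v[j + 1L]); break }
    j <- j + 1L
  }
  c(xl, xr)
}

# Shared peak detector: local maxima with prominence at least `frac` of a
# reference scale, thinned so that surviving peaks are at least `min_sep_s`
# apart; within a conflict the higher-prominence peak wins, the earlier one
# on an exact tie. The reference scale is the larger of the robust signal
# range (5th-95th percentile) and the largest single-peak prominence: on
# sparse-event signals (events occupying < 5% of samples) the robust range
# collapses, and low-pass ringing sidelobes of a large isolated event would
# otherwise pass a threshold anchored to it.
detect_peaks <- function(s, prominence_frac, min_sep_s) {
  v <- s$values
  rng <- unname(diff(quantile(v, c(0.05, 0.95))))
  cand <- local_maxima(v)
  if (!length(cand))
    return(data.frame(sample_index = integer(0), time_s = numeric(0),
                      prominence = numeric(0)))
  proms <- vapply(cand, function(p) peak_prominence(v, p)$prominence, numeric(1))
  ref <- max(rng, proms)
  if (ref <= 0)
    return(data.frame(sample_index = integer(0), time_s = numeric(0),
                      prominence = numeric(0)))
  keep <- proms >= prominence_frac * ref
  cand <- cand[keep]; proms <- proms[keep]
  if (!length(cand))
    return(data.frame(sample_index = integer(0), time_s = numeric(0),
                      prominence = numeric(0)))
  min_sep <- min_sep_s * s$fs
  ord <- order(-proms, cand)
  accepted <- integer(0)
  for (i in ord) {
    if (!length(accepted) || all(abs(cand[accepted] - cand[i]) >= min_sep))
      accepted <- c(accepted, i)
  }
  accepted <- accepted[order(cand[accepted])]
  t <- signal_times(s)
  data.frame(sample_index = cand[accepted], time_s = t[cand[accepted]],
             prominence = proms[accepted])
}
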