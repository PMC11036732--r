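# Independent oracles and small in-code fixtures shared across tests.

# Brute-force topographic prominence: vectorised scan over all samples,
# written independently of the walk-based implementation in the package.
oracle_prominence <- function(v, p) {
  n <- length(v)
  higher_left <- which(v[seq_len(p - 1L)] > v[p])
  lh <- if (length(higher_left)) max(higher_left) else 0L
  lmin <- if (p - 1L >= lh + 1L) min(v[(lh + 1L):(p - 1L)]) else v[p]
  higher_right <- which(v[(p + 1L):n] > v[p])
  rh <- if (length(higher_right)) p + min(higher_right) else n + 1L
  rmin <- if (rh - 1L >= p + 1L) min(v[(p + 1L):(rh - 1L)]) else v[p]
  v[p] - max(lmin, rmin)
}

# Width at half prominence located by a which()-based scan for the nearest
# sub-threshold sample on each side of the peak.
oracle_width <- function(v, p, fs) {
  prom <- oracle_prominence(v, p)
  h <- v[p] - prom / 2
  left <- which(v[seq_len(p - 1L)] < h)
  xl <- if (length(left)) {
    j <- max(left)
    j + (h - v[j]) / (v[j + 1L] - v[j])
  } else NA_real_
  right <- which(v[(p + 1L):length(v)] < h)
  xr <- if (length(right)) {
    j <- p + min(right)
    (j - 1L) + (v[j - 1L] - h) / (v[j - 1L] - v[j])
  } else NA_real_
  (xr - xl) / fs
}

# Exact two-sided rank-sum p by full enumeration of all size-nx subsets.
oracle_rank_sum_p <- function(x, y) {
  nx <- length(x)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  sums <- combn(length(r), nx, function(idx) sum(r[idx]))
  p_low <- mean(sums <= W + 1e-9)
  p_high <- mean(sums >= W - 1e-9)
  min(1, 2 * min(p_low, p_high))
}

# Uniform colour frame stream: n frames of a constant RGB value.
const_frames <- function(n, rgb, H = 48L, W = 48L, fs = 180) {
  img <- array(0L, c(H, W, 3))
  for (ch in 1:3) img[, , ch] <- as.integer(rgb[ch])
  frame_stream(rep(list(img), n), (seq_len(n) - 1) / fs, expected_min_fps = 0)
}

# Landmark matrix with every point at a benign location, selected ids moved.
flat_points <- function() {
  id <- 0:467
  cbind(0.2 + 0.6 * ((id %% 26L) / 25), 0.15 + 0.7 * ((id %/% 26L) / 17), 0)
}

# A conditioned signal object built directly from values (unit-test shortcut
# for the event layer, which requires conditioning = "filtered").
as_filtered <- function(values, fs, channel) {
  gtr_signal(values, fs, channel = channel, conditioning = "filtered")
}

# Quiet wrappers: event detection warns on empty results by design.
quiet_taps <- function(...) suppressWarnings(detect_taps(...))
quiet_blinks <- function(...) suppressWarnings(detect_blinks(...))
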