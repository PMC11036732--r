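test_that("prominence and half-prominence width match the brute-force oracle", {
  set.seed(11)
  for (rep in 1:15) {
    v <- as.numeric(stats::filter(rnorm(400), rep(1 / 8, 8), sides = 2))
    v[is.na(v)] <- 0
    peaks <- local_maxima(v)
    peaks <- peaks[peaks > 5 & peaks < length(v) - 5]
    for (p in peaks) {
      expect_equal(peak_prominence(v, p)$prominence, oracle_prominence(v, p),
                   tolerance = 1e-12)
      w_pkg <- width_at_half_prominence(v, p, fs = 100)
      w_orc <- oracle_width(v, p, 100)
      if (is.finite(w_orc)) expect_equal(w_pkg, w_orc, tolerance = 1e-12)
    }
  }
})

test_that("half-prominence width of canonical shapes is exact", {
  fs <- 100
  # symmetric triangle, base 0.2 s, zero baseline -> half width 0.1 s
  tri <- c(rep(0, 50), seq(0, 1, length.out = 11), seq(0.9, 0, length.out = 10),
           rep(0, 50))
  p <- which.max(tri)
  expect_equal(width_at_half_prominence(tri, p, fs = fs), 0.1, tolerance = 1e-9)

  # raised cosine of width parameter D has half-maximum width exactly D
  fs2 <- 180
  t <- (0:(4 * fs2 - 1)) / fs2
  v <- raised_cosine_pulse(t, 2, 0.15, 30)
  expect_equal(width_at_half_prominence(v, which.max(v), fs = fs2), 0.15,
               tolerance = 1 / fs2)

  # overlapping peaks: smaller peak's prominence is against its saddle
  v2 <- raised_cosine_pulse(t, 2, 0.2, 50) + raised_cosine_pulse(t, 2.3, 0.2, 30)
  pks <- local_maxima(v2)
  pks <- pks[order(v2[pks], decreasing = TRUE)]
  small <- pks[2]
  expect_equal(peak_prominence(v2, small)$prominence,
               oracle_prominence(v2, small), tolerance = 1e-12)
  expect_equal(width_at_half_prominence(v2, small, fs = fs2),
               oracle_width(v2, small, fs2), tolerance = 1e-12)

  expect_error(width_at_half_prominence(v, 3, fs = fs2),
               class = "gtr_contract_error")
})

test_that("width is invariant to amplitude scaling and times to uniform shifts", {
  fs <- 180
  t <- (0:(6 * fs - 1)) / fs
  v <- raised_cosine_pulse(t, 3, 0.22, 40) + 0.01 * sin(2 * pi * 0.3 * t)
  p <- which.max(v)
  expect_equal(width_at_half_prominence(v, p, fs = fs),
               width_at_half_prominence(5 * v, p, fs = fs), tolerance = 1e-12)

  taps <- data.frame(time_s = c(2, 4), sample_index = c(1, 2), prominence = 1)
  blinks <- data.frame(time_s = c(1.2, 2.1, 3.0), sample_index = 1:3,
                       prominence = 1, width_s = 0.1)
  c1 <- classify_blinks(blinks, taps)
  shift <- 11.7
  c2 <- classify_blinks(transform(blinks, time_s = time_s + shift),
                        transform(taps, time_s = time_s + shift))
  expect_identical(c1$category, c2$category)
  expect_identical(c1$assigned_tap, c2$assigned_tap)
})

test_that("tap detection finds programmed taps and applies the separation rule", {
  cfg <- synthetic_config(seed = 5, n_taps = 6, p_reflex_per_tap = 0,
                          non_reflex_rate_hz = 0, flicker_amplitude = 0,
                          noise_sd = 0)
  truth <- sample_session(cfg)
  sig <- synthesize_signals(truth, cfg)
  taps <- detect_taps(condition_signal(sig$tapping, cutoff_hz = 10))
  expect_equal(nrow(taps), 6L)
  expect_lt(max(abs(taps$time_s - truth$tap_times_s)), 1 / cfg$fs)

  flat <- as_filtered(rep(3, 1000), 180, "tapping")
  expect_warning(out <- detect_taps(flat), class = "gtr_no_events_warning")
  expect_equal(nrow(out), 0L)

  # two candidate peaks 0.3 s apart with min separation 0.4 s: higher wins
  fs <- 100
  t <- (0:(6 * fs - 1)) / fs
  v <- raised_cosine_pulse(t, 3.0, 0.06, 10) + raised_cosine_pulse(t, 3.3, 0.06, 7)
  one <- detect_taps(as_filtered(v, fs, "tapping"))
  expect_equal(nrow(one), 1L)
  expect_equal(one$time_s, 3.0, tolerance = 1 / fs)
})

test_that("blink detection recovers programmed blinks and suppresses flicker", {
  cfg <- synthetic_config(seed = 8, n_taps = 8, p_reflex_per_tap = 1,
                          non_reflex_rate_hz = 0.8, flicker_amplitude = 0,
                          noise_sd = 0)
  truth <- sample_session(cfg)
  sig <- synthesize_signals(truth, cfg)
  blinks <- detect_blinks(condition_signal(sig$blinking, cutoff_hz = 10))
  expect_equal(nrow(blinks), nrow(truth$blinks))
  tb <- truth$blinks[order(truth$blinks$time_s), ]
  expect_lt(max(abs(blinks$time_s - tb$time_s)), 1 / cfg$fs)

  expect_warning(detect_blinks(as_filtered(rep(0.5, 500), 180, "blinking")),
                 class = "gtr_no_events_warning")

  # one blink plus 25 Hz flicker at a fifth of its amplitude: default
  # conditioning leaves exactly one event
  fs <- 180
  t <- (0:(20 * fs - 1)) / fs
  raw <- gtr_signal(raised_cosine_pulse(t, 10, 0.3, 50) +
                      10 * sin(2 * pi * 25 * t), fs, channel = "blinking")
  one <- detect_blinks(condition_signal(raw, cutoff_hz = 0.75))
  expect_equal(nrow(one), 1L)
})

test_that("reflex window classification follows the -50/+200 ms closed-interval rules", {
  cfg <- analysis_config()
  taps <- data.frame(time_s = c(8, 10), sample_index = 1:2, prominence = 1)
  bl <- function(t) data.frame(time_s = t, sample_index = 1, prominence = 1,
                               width_s = 0.1)
  # 150 ms after a tap -> reflex, assigned to that tap
  r <- classify_blinks(bl(10.150), taps, cfg)
  expect_identical(r$category, "reflex")
  expect_identical(r$assigned_tap, 2L)
  # 60 ms before a tap is outside the window -> non-reflex in the previous interval
  r <- classify_blinks(bl(9.940), taps, cfg)
  expect_identical(r$category, "non_reflex")
  expect_identical(r$assigned_tap, 1L)
  # exactly at tap + 200 ms -> still reflex (closed interval)
  r <- classify_blinks(bl(10.200), taps, cfg)
  expect_identical(r$category, "reflex")
  # boundary on the early side: exactly tap - 50 ms is reflex
  expect_identical(classify_blinks(bl(7.950), taps, cfg)$category, "reflex")
  # before the first tap's window
  expect_identical(classify_blinks(bl(7.90), taps, cfg)$category, "pre_first_tap")
  # overlapping windows: nearest tap wins, earlier on an exact tie
  near <- data.frame(time_s = c(10.00, 10.18), sample_index = 1:2, prominence = 1)
  expect_identical(classify_blinks(bl(10.16), near, cfg)$assigned_tap, 2L)
  expect_identical(classify_blinks(bl(10.09), near, cfg)$assigned_tap, 1L)
  # no taps at all
  expect_warning(r <- classify_blinks(bl(3), taps[0, ], cfg),
                 class = "gtr_no_events_warning")
  expect_identical(r$category, "pre_first_tap")
})

test_that("tapwise counts conserve blinks and put post-final blinks in the last bin", {
  taps <- data.frame(time_s = c(2, 4, 6, 8, 10, 12), sample_index = 1:6,
                     prominence = 1)
  blinks <- data.frame(time_s = taps$time_s + 0.1, sample_index = 1:6,
                       prominence = 1, width_s = 0.1)
  cat6 <- classify_blinks(blinks, taps)
  tc <- tapwise_counts(cat6, 6)
  expect_equal(tc$reflex_count, rep(1L, 6))
  expect_equal(tc$non_reflex_count, rep(0L, 6))

  mixed <- data.frame(time_s = c(1.0, 2.1, 3.0, 12.9), sample_index = 1:4,
                      prominence = 1, width_s = 0.1)
  catm <- classify_blinks(mixed, taps)
  tcm <- tapwise_counts(catm, 6)
  expect_equal(sum(tcm$reflex_count) + sum(tcm$non_reflex_count) +
                 sum(catm$category == "pre_first_tap"), nrow(mixed))
  expect_equal(tcm$non_reflex_count[6], 1L)  # blink after the final tap

  set.seed(21)
  rnd <- data.frame(time_s = runif(30, 0, 14), sample_index = 1:30,
                    prominence = 1, width_s = 0.1)
  catr <- classify_blinks(rnd, taps)
  tcr <- tapwise_counts(catr, 6)
  expect_equal(sum(tcr$reflex_count) + sum(tcr$non_reflex_count) +
                 sum(catr$category == "pre_first_tap"), 30L)
})

test_that("subject summaries average widths per category with NaN for empty ones", {
  taps <- data.frame(time_s = c(2, 4), sample_index = 1:2, prominence = 1)
  blinks <- data.frame(time_s = c(2.1, 4.1, 1.0), sample_index = 1:3,
                       prominence = 1, width_s = c(0.1, 0.2, 0.9))
  rec <- subject_summary("P1", "iPD_before", taps, classify_blinks(blinks, taps))
  expect_equal(rec$avg_width_reflex_s, 0.15)
  expect_true(is.nan(rec$avg_width_non_reflex_s))
  # the pre-first-tap blink (width 0.9) is excluded everywhere
  expect_equal(sum(rec$tapwise$reflex_count), 2L)
  expect_equal(sum(rec$tapwise$non_reflex_count), 0L)

  # patient-2-like session: reflex widths chosen to average the printed
  # per-patient cell (0.058 s) reproduce it exactly in the summary
  b2 <- data.frame(time_s = c(2.05, 4.05), sample_index = 1:2, prominence = 1,
                   width_s = c(0.050, 0.066))
  rec2 <- subject_summary("P2", "iPD_before", taps, classify_blinks(b2, taps))
  expect_equal(rec2$avg_width_reflex_s, 0.058)
})
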