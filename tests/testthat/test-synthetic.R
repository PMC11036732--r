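test_that("the generator is deterministic in its seed at every level", {
  cfg <- synthetic_config(seed = 3, n_taps = 5)
  t1 <- sample_session(cfg)
  t2 <- sample_session(cfg)
  expect_equal(t1, t2)
  s1 <- synthesize_signals(t1, cfg)
  s2 <- synthesize_signals(t2, cfg)
  expect_equal(s1$tapping$values, s2$tapping$values)
  expect_equal(s1$blinking$values, s2$blinking$values)

  short <- synthetic_config(seed = 3, n_taps = 5, duration_s = NULL,
                            tap_interval_range_s = c(0.6, 0.8),
                            flicker_amplitude = 0, noise_sd = 0)
  tr <- sample_session(short)
  r1 <- render_session(tr, short, frame_size = c(64, 64))
  r2 <- render_session(tr, short, frame_size = c(64, 64))
  expect_identical(r1$frames$images[[10]], r2$frames$images[[10]])

  t3 <- sample_session(synthetic_config(seed = 4, n_taps = 5))
  expect_false(isTRUE(all.equal(t1$tap_times_s, t3$tap_times_s)))
})

test_that("degenerate rates produce the degenerate schedules they promise", {
  cfg <- synthetic_config(seed = 1, n_taps = 6, p_reflex_per_tap = 1,
                          non_reflex_rate_hz = 0)
  truth <- sample_session(cfg)
  expect_equal(length(truth$tap_times_s), 6L)
  expect_equal(nrow(truth$blinks), 6L)
  expect_true(all(truth$blinks$category == "reflex"))
  lat <- truth$blinks$time_s - truth$tap_times_s[truth$blinks$assigned_tap]
  expect_true(all(lat > 0.010 - 1e-12 & lat < 0.180 + 1e-12))

  zero <- synthetic_config(seed = 1, n_taps = 5, p_reflex_per_tap = 0,
                           non_reflex_rate_hz = 0, flicker_amplitude = 0,
                           noise_sd = 0)
  tz <- sample_session(zero)
  expect_equal(nrow(tz$blinks), 0L)
  sz <- synthesize_signals(tz, zero)
  expect_true(all(sz$blinking$values == 0))
  off_tap <- !vapply(seq_along(sz$tapping$values), function(k) {
    t <- (k - 1) / zero$fs
    any(abs(t - tz$tap_times_s) < zero$tap_contact_s / 2 + 2 / zero$fs)
  }, logical(1))
  expect_true(all(abs(sz$tapping$values[off_tap] - zero$skin_blue_level) < 1e-9))
})

test_that("tap schedules respect the protocol rhythm and reflex fractions are calibrated", {
  hits <- 0L; total <- 0L
  for (i in 1:300) {
    cfg <- synthetic_config(seed = 1000 + i, p_reflex_per_tap = 0.5,
                            non_reflex_rate_hz = 0)
    tr <- sample_session(cfg)
    gaps <- diff(tr$tap_times_s)
    expect_true(all(gaps >= 0.6 - 1e-12 & gaps <= 2.5 + 1e-12))
    n <- length(tr$tap_times_s)
    expect_true(n >= 5L && n <= 8L)
    total <- total + n
    hits <- hits + nrow(tr$blinks)
  }
  se <- sqrt(0.5 * 0.5 / total)
  expect_lt(abs(hits / total - 0.5), 3 * se)
})

test_that("synthesised blink pulses carry their programmed half-maximum width", {
  cfg <- synthetic_config(seed = 2, fs = 180, flicker_amplitude = 0, noise_sd = 0)
  truth <- structure(list(
    tap_times_s = 2, duration_s = 6, fs = 180,
    blinks = data.frame(time_s = 4, category = "non_reflex", duration_s = 0.2,
                        amplitude = 50, assigned_tap = 1L),
    config = cfg), class = "gtr_truth")
  sig <- synthesize_signals(truth, cfg)
  v <- sig$blinking$values
  expect_equal(width_at_half_prominence(v, which.max(v), fs = 180), 0.2,
               tolerance = 1 / 180)
})

test_that("conditioning removes synthetic flicker to below 1e-3 of its amplitude", {
  amp <- 6
  cfg <- synthetic_config(seed = 9, n_taps = 5, p_reflex_per_tap = 0,
                          non_reflex_rate_hz = 0, flicker_amplitude = amp,
                          noise_sd = 0)
  tr <- sample_session(cfg)
  sig <- synthesize_signals(tr, cfg)
  f <- condition_signal(sig$blinking)   # default 0.75 Hz cutoff
  n <- length(f$values)
  core <- seq(round(n * 0.2), round(n * 0.8))
  # residual oscillation; the percentile baseline leaves a harmless DC offset
  expect_lt((max(f$values[core]) - min(f$values[core])) / 2, 1e-3 * amp)
})

test_that("width recovery over many seeded blinks stays within one frame interval", {
  errs <- c()
  i <- 0L
  while (length(errs) < 200L) {
    i <- i + 1L
    cfg <- synthetic_config(seed = 5000 + i, p_reflex_per_tap = 1,
                            non_reflex_rate_hz = 0.5, flicker_amplitude = 0,
                            noise_sd = 0)
    truth <- sample_session(cfg)
    sig <- synthesize_signals(truth, cfg)
    blinks <- quiet_blinks(condition_signal(sig$blinking, cutoff_hz = 10))
    tb <- truth$blinks[order(truth$blinks$time_s), ]
    if (nrow(blinks) != nrow(tb)) next
    errs <- c(errs, abs(blinks$width_s - tb$duration_s))
  }
  expect_lt(mean(errs), 1 / 180)
})

test_that("packaged tables load with verbatim printed values and NaN markers", {
  fx <- load_paper_fixtures()
  hc_reflex <- fx$table1$value[fx$table1$group == "HC" &
                                 fx$table1$category == "reflex"]
  expect_equal(hc_reflex[1:2], c(0.727, 0.545))
  expect_equal(fx$table2[fx$table2$patient == 3,
                         c("width_reflex_bm", "width_reflex_am")],
               data.frame(width_reflex_bm = 0.362, width_reflex_am = 0.301,
                          row.names = 3L))
  expect_equal(sum(is.nan(fx$table3$width_reflex_s)), 2L)
  expect_equal(sum(is.nan(fx$table3$width_nonreflex_s)), 4L)
})

test_that("rendered sessions honour the pixel contracts of both channels", {
  cfg <- synthetic_config(seed = 12, n_taps = 5, p_reflex_per_tap = 1,
                          non_reflex_rate_hz = 0,
                          tap_interval_range_s = c(0.6, 0.9),
                          flicker_amplitude = 0, noise_sd = 0)
  truth <- sample_session(cfg)
  rend <- render_session(truth, cfg, frame_size = c(64, 64))
  sig <- extract_signals(rend$frames, rend$landmarks)

  # tap frames: glabellar blue mean at the glove level
  k_tap <- round(truth$tap_times_s[1] * cfg$fs) + 1L
  expect_gte(sig$tapping$values[k_tap], cfg$tap_blue_level - 2)
  k_off <- round((truth$tap_times_s[1] - 0.4) * cfg$fs) + 1L
  expect_equal(sig$tapping$values[k_off], cfg$skin_blue_level, tolerance = 1e-9)

  # maximal closure frame (deepest blink): eye pixel count at its session
  # minimum, i.e. the inverted blinking signal at its maximum
  deepest <- which.max(truth$blinks$amplitude)
  k_apex <- round(truth$blinks$time_s[deepest] * cfg$fs) + 1L
  expect_equal(max(sig$blinking$values[k_apex + (-1:1)]),
               max(sig$blinking$values))

  expect_error(render_session(truth, cfg, frame_size = c(40, 40)),
               class = "gtr_config_error")
})

test_that("pixel-extracted signals agree with directly synthesised ones", {
  cfg <- synthetic_config(seed = 13, n_taps = 5, p_reflex_per_tap = 1,
                          non_reflex_rate_hz = 0,
                          tap_interval_range_s = c(0.6, 0.9),
                          flicker_amplitude = 0, noise_sd = 0)
  truth <- sample_session(cfg)
  rend <- render_session(truth, cfg, frame_size = c(96, 96))
  px <- extract_signals(rend$frames, rend$landmarks)
  ds <- synthesize_signals(truth, cfg)
  norm_shape <- function(s, cutoff) {
    f <- condition_signal(s, cutoff_hz = cutoff)$values
    f / max(f)
  }
  a <- norm_shape(px$blinking, 10)
  b <- norm_shape(ds$blinking, 10)
  expect_lt(max(abs(a - b)), 0.02)
  ta <- norm_shape(px$tapping, 10)
  tb <- norm_shape(ds$tapping, 10)
  expect_lt(max(abs(ta - tb)), 0.02)
})

test_that("truth schedules round-trip through their JSON file", {
  cfg <- synthetic_config(seed = 6, n_taps = 5)
  truth <- sample_session(cfg)
  path <- tempfile(fileext = ".json")
  write_truth(truth, path)
  r <- read_truth(path)
  expect_equal(r$tap_times_s, truth$tap_times_s, tolerance = 1e-12)
  expect_equal(r$blinks$time_s, truth$blinks$time_s, tolerance = 1e-12)
  expect_equal(r$blinks$category, truth$blinks$category)
})
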