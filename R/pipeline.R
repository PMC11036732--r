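#' Resolved pipeline run configuration
#'
#' Union of the analysis constants, the synthetic-generator settings and
#' I/O choices, with unknown keys rejected so that typos fail loudly. The
#' resolved configuration is echoed into every report for provenance.
#'
#' @param ... named overrides; recognised keys are `seed`, `out_dir`,
#'   `render`, `frame_size`, `backend`, `landmark_path`, `frames_dir`,
#'   `validation_cutoff_hz`, `subject_id`, `group`, `log_level`, every
#'   argument of [analysis_config()] and every argument of
#'   [synthetic_config()].
#' @return Named list of class `gtr_run_config`.
#' @export
run_config <- function(...) {
  overrides <- list(...)
  base <- list(seed = 1L, out_dir = ".", render = FALSE,
               frame_size = c(96L, 96L), backend = "synthetic",
               landmark_path = NULL, frames_dir = NULL,
               validation_cutoff_hz = NULL,
               subject_id = "S1", group = "HC", log_level = "info")
  acfg <- formals(analysis_config)
  scfg <- formals(synthetic_config)
  known <- c(names(base), names(acfg), names(scfg))
  unknown <- setdiff(names(overrides), known)
  if (length(unknown))
    gtr_stop(sprintf("unknown configuration key(s): %s",
                     paste(unknown, collapse = ", ")), "gtr_config_error")
  cfg <- utils::modifyList(base, overrides, keep.null = TRUE)
  structure(cfg, class = "gtr_run_config")
}

cfg_subset <- function(cfg, fn) {
  keys <- intersect(names(formals(fn)), names(cfg))
  cfg[keys]
}

pipeline_log <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf(...))
}

#' Run the analysis pipeline
#'
#' Wires the stages together with file handoffs in `out_dir` so each step
#' is independently invocable:
#' \describe{
#'   \item{simulate}{sample a ground-truth session and write `truth.json`
#'     plus raw `tapping.csv` / `blinking.csv` (with JSON sidecars); with
#'     `render = TRUE` also a PNG frame sequence and `landmarks.csv`.}
#'   \item{extract}{rebuild the two raw signals from a frame directory and
#'     a landmark source (`backend` + `landmark_path`).}
#'   \item{detect}{condition the raw signals (baseline removal, low-pass at
#'     `lowpass_cutoff_hz` or `validation_cutoff_hz` when set), detect and
#'     classify events, and write `events.csv` and `subject.json`.}
#'   \item{stats}{summarise the packaged reference tables into `report/`.}
#'   \item{all}{simulate, then detect, then a single-subject report.}
#' }
#' Artifacts are written atomically; re-running a stage with identical
#' configuration and inputs reproduces identical outputs.
#'
#' @param stage one of `"simulate"`, `"extract"`, `"detect"`, `"stats"`,
#'   `"all"`.
#' @param cfg a [run_config()].
#' @return Invisible list of artifact paths (and, for in-memory use, the
#'   last stage's objects). Missing stage inputs raise a usage error
#'   (`gtr_usage_error`); validation failures raise data errors.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "extract", "detect", "stats"),
                         cfg = run_config()) {
  stage <- match.arg(stage)
  stopifnot(inherits(cfg, "gtr_run_config"))
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()

  if (stage %in% c("simulate", "all")) {
    scfg <- do.call(synthetic_config, cfg_subset(cfg, synthetic_config))
    truth <- sample_session(scfg)
    sig <- synthesize_signals(truth, scfg)
    write_atomic(file.path(out, "truth.json"), function(p) write_truth(truth, p))
    for (ch in c("tapping", "blinking"))
      write_atomic(file.path(out, paste0(ch, ".csv")), function(p) {
        write_signal(sig[[ch]], p)
        file.rename(paste0(p, ".json"),
                    file.path(out, paste0(ch, ".csv.json")))
      })
    if (isTRUE(cfg$render)) {
      rend <- render_session(truth, scfg, frame_size = cfg$frame_size)
      write_frames(rend$frames, file.path(out, "frames"))
      write_atomic(file.path(out, "landmarks.csv"), function(p)
        write_landmarks(rend$landmarks, p))
      artifacts$frames <- file.path(out, "frames")
      artifacts$landmarks <- file.path(out, "landmarks.csv")
    }
    artifacts$truth <- file.path(out, "truth.json")
    artifacts$tapping <- file.path(out, "tapping.csv")
    artifacts$blinking <- file.path(out, "blinking.csv")
    pipeline_log(cfg, "simulate: %d taps, %d blinks, %.1f s",
                 length(truth$tap_times_s), nrow(truth$blinks), truth$duration_s)
  }

  if (stage == "extract") {
    frames_dir <- cfg$frames_dir %||% file.path(out, "frames")
    if (!dir.exists(frames_dir))
      gtr_stop(sprintf("extract: missing frame directory '%s'", frames_dir),
               "gtr_usage_error")
    frames <- read_frames(frames_dir, expected_min_fps = 0)
    lm_cfg <- list(path = cfg$landmark_path %||% file.path(out, "landmarks.csv"))
    lms <- provide_landmarks(frames, cfg$backend %||% "fixture-file",
                             config = lm_cfg)
    sig <- extract_signals(frames, lms)
    for (ch in c("tapping", "blinking"))
      write_atomic(file.path(out, paste0(ch, ".csv")), function(p) {
        write_signal(sig[[ch]], p)
        file.rename(paste0(p, ".json"), file.path(out, paste0(ch, ".csv.json")))
      })
    artifacts$tapping <- file.path(out, "tapping.csv")
    artifacts$blinking <- file.path(out, "blinking.csv")
  }

  if (stage %in% c("detect", "all")) {
    for (f in c("tapping.csv", "blinking.csv")) {
      if (!file.exists(file.path(out, f)))
        gtr_stop(sprintf("detect: missing signals file '%s' (run simulate or extract first)",
                         file.path(out, f)), "gtr_usage_error")
      if (!file.exists(file.path(out, paste0(f, ".json"))))
        gtr_stop(sprintf("detect: missing sidecar '%s.json'", file.path(out, f)),
                 "gtr_usage_error")
    }
    read_side <- function(ch) read_signal(file.path(out, paste0(ch, ".csv")))
    acfg <- do.call(analysis_config, cfg_subset(cfg, analysis_config))
    cutoff <- cfg$validation_cutoff_hz %||% acfg$lowpass_cutoff_hz
    tapping <- condition_signal(read_side("tapping"), cutoff_hz = cutoff)
    blinking <- condition_signal(read_side("blinking"), cutoff_hz = cutoff)
    taps <- detect_taps(tapping, acfg)
    blinks <- classify_blinks(detect_blinks(blinking, acfg), taps, acfg)
    subject <- subject_summary(cfg$subject_id, cfg$group, taps, blinks)
    write_atomic(file.path(out, "events.csv"), function(p)
      write_events(subject, p))
    write_atomic(file.path(out, "subject.json"), function(p)
      jsonlite::write_json(list(
        subject_id = subject$subject_id, group = subject$group,
        n_taps = nrow(taps), n_blinks = nrow(blinks),
        tapwise = subject$tapwise,
        avg_width_reflex_s = subject$avg_width_reflex_s,
        avg_width_non_reflex_s = subject$avg_width_non_reflex_s,
        config = unclass(cfg)[!vapply(cfg, is.null, logical(1))]),
        p, auto_unbox = TRUE, digits = NA, na = "string", force = TRUE))
    artifacts$events <- file.path(out, "events.csv")
    artifacts$subject <- file.path(out, "subject.json")
    artifacts$subject_record <- subject
    pipeline_log(cfg, "detect: %d taps, %d blinks (%d reflex)",
                 nrow(taps), nrow(blinks), sum(blinks$category == "reflex"))
  }

  if (stage %in% c("stats", "all")) {
    summary <- summarize_fixtures()
    build_report(summary, file.path(out, "report"),
                 config = unclass(cfg)[!vapply(cfg, is.null, logical(1))])
    artifacts$report <- file.path(out, "report", "report.json")
  }

  invisible(artifacts)
}

#' Extract both channel signals from frames and landmarks
#'
#' Builds the per-frame glabellar and eye ROIs from the landmark stream
#' (frames with a detection gap reuse the previous valid ROI) and reduces
#' the frame raster to the raw tapping and blinking signals.
#'
#' @param frames a `gtr_frames`.
#' @param landmarks a `gtr_landmarks` aligned with `frames`.
#' @param side eye side passed to [eye_roi()].
#' @return List with raw `tapping` and `blinking` `gtr_signal`s.
#' @export
extract_signals <- function(frames, landmarks, side = "auto") {
  d <- dim(frames$images[[1]])[1:2]
  n <- length(frames$images)
  by_index <- vector("list", n)
  for (k in seq_along(landmarks$frame_index)) {
    fi <- landmarks$frame_index[k] + 1L
    if (fi >= 1L && fi <= n) by_index[[fi]] <- landmarks$points[[k]]
  }
  g_rois <- vector("list", n); e_rois <- vector("list", n)
  for (k in seq_len(n)) {
    p <- by_index[[k]]
    if (is.null(p)) next
    g_rois[[k]] <- glabellar_roi(p, d)
    e_rois[[k]] <- eye_roi(p, d, side = side)
  }
  list(tapping = tapping_signal(frames, g_rois),
       blinking = blinking_signal(frames, e_rois))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
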