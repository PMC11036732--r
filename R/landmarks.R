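#' Construct a facial-landmark stream
#'
#' One frame of the face mesh is 468 landmarks, each an `(x, y, z)` triple
#' with `x`, `y` normalised to the frame width/height and `z` a relative
#' depth. Coordinates stay normalised inside the stream and are converted to
#' pixels only when a region of interest is built, which keeps streams
#' resolution independent. Frames where the face detector failed are kept as
#' explicit gaps (`missing`), never silently dropped, because downstream
#' signal extraction assumes uniform sampling.
#'
#' @param points list of `468 x 3` numeric matrices (columns x, y, z), one
#'   per detected frame.
#' @param frame_index integer vector of 0-based frame ordinals for `points`,
#'   strictly increasing.
#' @param timestamp numeric vector of per-frame times in seconds.
#' @param fs sampling rate in Hz; if `NULL`, estimated from timestamps.
#' @param provenance one of `"external-model"`, `"fixture-file"`,
#'   `"synthetic"`.
#' @param missing integer vector of frame ordinals with no detected face.
#' @param missing_timestamp timestamps of the missing frames (same length).
#'
#' @return An object of class `gtr_landmarks`.
#' @export
landmark_stream <- function(points, frame_index, timestamp, fs = NULL,
                            provenance = c("external-model", "fixture-file", "synthetic"),
                            missing = integer(0),
                            missing_timestamp = numeric(0)) {
  provenance <- match.arg(provenance)
  frame_index <- as.integer(frame_index)
  if (length(points) != length(frame_index) || length(points) != length(timestamp))
    gtr_stop("points, frame_index and timestamp lengths differ", "gtr_validation_error")
  if (length(frame_index) && any(diff(frame_index) <= 0))
    gtr_stop("landmark frame indices are not strictly increasing", "gtr_validation_error")
  if (length(missing) != length(missing_timestamp))
    gtr_stop("missing and missing_timestamp lengths differ", "gtr_validation_error")
  for (k in seq_along(points)) {
    p <- points[[k]]
    if (!is.matrix(p) || nrow(p) != 468L || ncol(p) != 3L)
      gtr_stop(sprintf("frame %d: expected 468 x 3 landmark matrix, got %s",
                       frame_index[k], paste(dim(p), collapse = " x ")),
               "gtr_validation_error")
    xy <- p[, 1:2]
    if (any(!is.finite(xy)) || any(xy < -0.5) || any(xy > 1.5))
      gtr_stop(sprintf("frame %d: landmark x/y outside [-0.5, 1.5] or non-finite",
                       frame_index[k]), "gtr_validation_error")
  }
  if (is.null(fs)) {
    ts <- sort(c(timestamp, missing_timestamp))
    if (length(ts) < 2L)
      gtr_stop("cannot estimate fs from fewer than 2 timestamps", "gtr_validation_error")
    fs <- (length(ts) - 1) / (ts[length(ts)] - ts[1])
  }
  stopifnot(fs > 0)
  structure(list(points = points, frame_index = frame_index,
                 timestamp = as.numeric(timestamp), fs = fs,
                 provenance = provenance,
                 missing = as.integer(missing),
                 missing_timestamp = as.numeric(missing_timestamp)),
            class = "gtr_landmarks")
}

#' @export
print.gtr_landmarks <- function(x, ...) {
  cat(sprintf("<gtr_landmarks> %d frames (+%d gaps), fs = %.2f Hz, provenance = %s\n",
              length(x$points), length(x$missing), x$fs, x$provenance))
  invisible(x)
}

# --- provider registry -------------------------------------------------------

.gtr_backends <- new.env(parent = emptyenv())

#' Register a landmark provider backend
#'
#' The pipeline never depends on a particular face-mesh implementation: any
#' function that maps a frame stream to a `gtr_landmarks` object can be
#' registered under a name and selected in [provide_landmarks()]. The
#' built-in backends are `"fixture-file"` (verbatim read of a landmark
#' file, see [read_landmarks()]) and `"synthetic"` (pass-through of a
#' generator-produced stream). An external face-mesh model would be plugged
#' in the same way.
#'
#' @param name backend identifier.
#' @param fun `function(frames, config)` returning a `gtr_landmarks`.
#' @export
register_landmark_backend <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  assign(name, fun, envir = .gtr_backends)
  invisible(name)
}

#' Obtain per-frame landmarks for a frame stream
#'
#' @param frames a `gtr_frames` stream (may be `NULL` for file-only work).
#' @param backend registered backend name.
#' @param config backend configuration list. The `fixture-file` backend
#'   requires `config$path`; the `synthetic` backend requires
#'   `config$stream`.
#' @return A `gtr_landmarks` stream aligned with `frames`:
#'   `detected frames + recorded gaps == video frames`.
#' @export
provide_landmarks <- function(frames, backend, config = list()) {
  if (!exists(backend, envir = .gtr_backends, inherits = FALSE))
    gtr_stop(sprintf("landmark backend '%s' is not registered", backend),
             "gtr_config_error")
  fun <- get(backend, envir = .gtr_backends, inherits = FALSE)
  lm <- fun(frames, config)
  if (!inherits(lm, "gtr_landmarks"))
    gtr_stop(sprintf("backend '%s' did not return a landmark stream", backend),
             "gtr_config_error")
  if (!is.null(frames)) {
    n_lm <- length(lm$points) + length(lm$missing)
    n_fr <- length(frames$images)
    if (n_lm != n_fr)
      gtr_stop(sprintf("landmark/frame misalignment: %d landmark frames (incl. gaps) vs %d video frames",
                       n_lm, n_fr), "gtr_alignment_error")
  }
  lm
}

local({
  register_landmark_backend("fixture-file", function(frames, config) {
    if (is.null(config$path))
      gtr_stop("fixture-file backend needs config$path", "gtr_config_error")
    read_landmarks(config$path)
  })
  register_landmark_backend("synthetic", function(frames, config) {
    if (is.null(config$stream))
      gtr_stop("synthetic backend needs config$stream", "gtr_config_error")
    config$stream
  })
})

# --- serialization -----------------------------------------------------------

#' Write a landmark stream to CSV or JSON-lines
#'
#' CSV dialect: header `frame_index,timestamp,landmark_id,x,y,z`, one row per
#' landmark per frame with 0-based `landmark_id`; a frame with no detected
#' face is a single row with `landmark_id = -1` and empty coordinates.
#' JSON-lines dialect (`.jsonl`): one object per line with the same field
#' names, points as a 468-row array, gaps as `{"frame_index":k,"timestamp":t,"missing":true}`.
#' Round-tripping preserves every coordinate to within 1e-9.
#'
#' @param stream a `gtr_landmarks`.
#' @param path output file; format chosen by extension (`.csv` or `.jsonl`).
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(stream, path) {
  stopifnot(inherits(stream, "gtr_landmarks"))
  if (grepl("\\.jsonl$", path)) {
    con <- file(path, "w")
    on.exit(close(con))
    all_idx <- order(c(stream$frame_index, stream$missing))
    recs <- c(
      lapply(seq_along(stream$points), function(k)
        list(frame_index = stream$frame_index[k], timestamp = stream$timestamp[k],
             points = stream$points[[k]])),
      lapply(seq_along(stream$missing), function(k)
        list(frame_index = stream$missing[k], timestamp = stream$missing_timestamp[k],
             missing = TRUE)))
    for (r in recs[all_idx])
      writeLines(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA), con)
    return(invisible(path))
  }
  n <- length(stream$points)
  tabs <- vector("list", n + length(stream$missing))
  for (k in seq_len(n)) {
    p <- stream$points[[k]]
    tabs[[k]] <- data.table::data.table(
      frame_index = stream$frame_index[k], timestamp = stream$timestamp[k],
      landmark_id = 0:467, x = p[, 1], y = p[, 2], z = p[, 3])
  }
  for (k in seq_along(stream$missing)) {
    tabs[[n + k]] <- data.table::data.table(
      frame_index = stream$missing[k], timestamp = stream$missing_timestamp[k],
      landmark_id = -1L, x = NA_real_, y = NA_real_, z = NA_real_)
  }
  tab <- data.table::rbindlist(tabs)
  tab <- tab[order(tab$frame_index), ]
  data.table::fwrite(tab, path, na = "")
  invisible(path)
}

#' Read a landmark stream written by [write_landmarks()]
#'
#' @param path CSV or JSON-lines landmark file.
#' @param provenance provenance label to attach (default `"fixture-file"`).
#' @return A `gtr_landmarks`.
#' @export
read_landmarks <- function(path, provenance = "fixture-file") {
  if (!file.exists(path))
    gtr_stop(sprintf("landmark file '%s' does not exist", path), "gtr_parse_error")
  if (grepl("\\.jsonl$", path)) {
    lines <- readLines(path)
    points <- list(); fidx <- integer(0); ts <- numeric(0)
    miss <- integer(0); miss_ts <- numeric(0)
    for (i in seq_along(lines)) {
      r <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e)
        gtr_stop(sprintf("line %d: malformed JSON record", i), "gtr_parse_error"))
      if (isTRUE(r$missing)) {
        miss <- c(miss, r$frame_index); miss_ts <- c(miss_ts, r$timestamp)
      } else {
        p <- as.matrix(r$points)
        if (nrow(p) != 468L || ncol(p) != 3L)
          gtr_stop(sprintf("line %d: expected 468 x 3 points", i), "gtr_parse_error")
        points <- c(points, list(unname(p)))
        fidx <- c(fidx, r$frame_index); ts <- c(ts, r$timestamp)
      }
    }
    return(landmark_stream(points, fidx, ts, provenance = provenance,
                           missing = miss, missing_timestamp = miss_ts))
  }
  tab <- tryCatch(data.table::fread(path, na.strings = ""),
                  error = function(e) gtr_stop(sprintf("cannot parse '%s': %s", path,
                                                       conditionMessage(e)), "gtr_parse_error"))
  need <- c("frame_index", "timestamp", "landmark_id", "x", "y", "z")
  if (!identical(names(tab), need))
    gtr_stop(sprintf("'%s': expected header %s", path, paste(need, collapse = ",")),
             "gtr_parse_error")
  bad <- which(tab$landmark_id >= 0 & (!is.finite(tab$x) | !is.finite(tab$y)))
  if (length(bad))
    gtr_stop(sprintf("'%s': non-numeric coordinate at data line %d", path, bad[1]),
             "gtr_parse_error")
  is_miss <- tab$landmark_id == -1L
  miss <- tab$frame_index[is_miss]
  miss_ts <- tab$timestamp[is_miss]
  det <- tab[!is_miss, ]
  fidx <- unique(det$frame_index)
  points <- vector("list", length(fidx)); ts <- numeric(length(fidx))
  for (k in seq_along(fidx)) {
    rows <- det[det$frame_index == fidx[k], ]
    if (nrow(rows) != 468L)
      gtr_stop(sprintf("'%s': frame %d has %d landmarks, expected 468",
                       path, fidx[k], nrow(rows)), "gtr_validation_error")
    rows <- rows[order(rows$landmark_id), ]
    points[[k]] <- unname(cbind(rows$x, rows$y, rows$z))
    ts[k] <- rows$timestamp[1]
  }
  landmark_stream(points, fidx, ts, provenance = provenance,
                  missing = miss, missing_timestamp = miss_ts)
}
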