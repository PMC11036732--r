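# Regions of interest are built in pixel coordinates with the dominant raster
# convention: 0-based, x rightward, y downward, half-open pixel boxes; pixel
# (row i, col j) covers [j, j+1) x [i, i+1) and has centre (j + 0.5, i + 0.5).

#' Default face-mesh landmark index sets
#'
#' 0-based indices into the 468-point face mesh. The glabellar set is the
#' midline/medial-brow diamond around the glabella (left inner brow, midline
#' above the nasion, right inner brow, nasion). The eyelid sets are the
#' six-point lid contours commonly used for eye-aperture measures. Indices
#' are mesh-version dependent and therefore configuration, not code.
#'
#' @return A named list with elements `glabella`, `right_eye`, `left_eye`.
#' @export
default_landmark_sets <- function() {
  list(glabella = c(55L, 9L, 285L, 8L),
       right_eye = c(33L, 160L, 158L, 133L, 153L, 144L),
       left_eye = c(362L, 385L, 387L, 263L, 373L, 380L))
}

shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

lm_to_px <- function(points, ids0, frame_size) {
  # frame_size = c(height, width); normalized x scales by width, y by height
  if (any(ids0 < 0L) || any(ids0 > 467L))
    gtr_stop(sprintf("landmark index out of range [0, 467]: %s",
                     paste(ids0[ids0 < 0L | ids0 > 467L], collapse = ", ")),
             "gtr_config_error")
  p <- points[ids0 + 1L, , drop = FALSE]
  cbind(x = p[, 1] * frame_size[2], y = p[, 2] * frame_size[1])
}

#' Glabellar region of interest
#'
#' Builds the polygon spanning the inter-eyebrow region (between the medial
#' brow heads, above the nasion) from configured glabellar landmark indices,
#' converted from normalised coordinates to pixels.
#'
#' @param points `468 x 3` landmark matrix of one frame.
#' @param frame_size `c(height, width)` in pixels.
#' @param landmark_ids 0-based landmark indices tracing the polygon (default
#'   `default_landmark_sets()$glabella`).
#' @return An object of class `gtr_roi_polygon` with fields `vertices`
#'   (matrix of pixel x, y), `source_landmark_ids`.
#' @export
glabellar_roi <- function(points, frame_size,
                          landmark_ids = default_landmark_sets()$glabella) {
  v <- lm_to_px(points, landmark_ids, frame_size)
  if (nrow(v) < 3L || shoelace_area(v[, 1], v[, 2]) <= 0)
    gtr_stop("degenerate glabellar polygon (area 0)", "gtr_geometry_error")
  structure(list(vertices = v, source_landmark_ids = landmark_ids),
            class = "gtr_roi_polygon")
}

#' Eye region of interest
#'
#' The eye ROI is the tight axis-aligned bounding box of the eyelid
#' landmarks plus a margin, together with the lid contour polygon used to
#' zero out non-eye pixels. `side = "auto"` picks the eye whose lid-contour
#' area is larger, which at the protocol's 45 degree recording angle is the
#' camera-near eye.
#'
#' @inheritParams glabellar_roi
#' @param side `"left"`, `"right"` or `"auto"`.
#' @param margin_px margin added on every side of the bounding box
#'   (default 2).
#' @param landmark_sets named list with `left_eye` / `right_eye` indices.
#' @return An object of class `gtr_eye_roi` with fields `bounding_box`
#'   (`c(x0, y0, x1, y1)` pixels), `lid_contour` (polygon matrix), `side`.
#' @export
eye_roi <- function(points, frame_size, side = c("auto", "left", "right"),
                    margin_px = 2,
                    landmark_sets = default_landmark_sets()) {
  side <- match.arg(side)
  contour_of <- function(ids) lm_to_px(points, ids, frame_size)
  if (side == "auto") {
    aL <- shoelace_area(contour_of(landmark_sets$left_eye)[, 1],
                        contour_of(landmark_sets$left_eye)[, 2])
    aR <- shoelace_area(contour_of(landmark_sets$right_eye)[, 1],
                        contour_of(landmark_sets$right_eye)[, 2])
    side <- if (aR >= aL) "right" else "left"
  }
  ids <- if (side == "left") landmark_sets$left_eye else landmark_sets$right_eye
  ct <- contour_of(ids)
  box <- c(min(ct[, 1]) - margin_px, min(ct[, 2]) - margin_px,
           max(ct[, 1]) + margin_px, max(ct[, 2]) + margin_px)
  if (box[3] <= box[1] || box[4] <= box[2])
    gtr_stop("degenerate eye bounding box", "gtr_geometry_error")
  structure(list(bounding_box = box, lid_contour = ct, side = side,
                 source_landmark_ids = ids),
            class = "gtr_eye_roi")
}

# Logical mask of pixels whose centres fall inside a polygon, restricted to
# the polygon's bounding box intersected with the frame. Returns a list with
# the row/col index ranges (1-based) and the mask matrix.
polygon_mask <- function(vertices, frame_size) {
  H <- frame_size[1]; W <- frame_size[2]
  c0 <- max(1L, floor(min(vertices[, 1])) + 1L)
  c1 <- min(W, ceiling(max(vertices[, 1])))
  r0 <- max(1L, floor(min(vertices[, 2])) + 1L)
  r1 <- min(H, ceiling(max(vertices[, 2])))
  if (c1 < c0 || r1 < r0)
    return(list(rows = integer(0), cols = integer(0), mask = NULL))
  cc <- c0:c1; rr <- r0:r1
  cx <- rep(cc - 0.5, each = length(rr))
  cy <- rep(rr - 0.5, times = length(cc))
  inside <- pracma::inpolygon(cx, cy, vertices[, 1], vertices[, 2],
                              boundary = TRUE)
  list(rows = rr, cols = cc,
       mask = matrix(inside, nrow = length(rr), ncol = length(cc)))
}
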