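# Pluggable landmark-provider layer standing in for the learned detection
# stages, plus the segmentation gate: a femoral-head-center landmark (C) is
# only trusted when a femoral-head segmentation ROI exists for that side.
# In young infants the ossific nucleus is often invisible and keypoint
# detectors emit false C points; the high-specificity head segmentation
# vetoes them.

#' Femoral head region of interest
#'
#' @param side `"left"` or `"right"`.
#' @param bbox `(x_min, y_min, x_max, y_max)` in pixels.
#' @param mask_area segmented head area in pixels squared (0 when only a box
#'   is available).
#' @param confidence detection confidence in \[0, 1\].
#' @return Object of class `femoral_head_roi`.
#' @export
femoral_head_roi <- function(side, bbox, mask_area = 0, confidence = 1) {
  side <- match.arg(side, c("left", "right"))
  bbox <- as.numeric(bbox)
  if (length(bbox) != 4L || bbox[1] >= bbox[3] || bbox[2] >= bbox[4])
    stop("invalid bbox: need x_min < x_max and y_min < y_max")
  if (mask_area < 0) stop("mask_area must be nonnegative")
  if (confidence < 0 || confidence > 1) stop("confidence must be in [0, 1]")
  structure(list(side = side, bbox = bbox, mask_area = mask_area,
                 confidence = confidence),
            class = "femoral_head_roi")
}

#' Detection bundle: landmarks + head ROIs + optional bone contours
#'
#' The contract every landmark provider must satisfy. `landmarks` may carry
#' spurious C points; `head_rois` may be empty; `contours` is an optional
#' per-side list of named point arrays (e.g. `pubic_arc`, `neck_arc`,
#' `femoral_head`).
#'
#' @param landmarks a `landmark_set`.
#' @param head_rois list of `femoral_head_roi` (at most one per side).
#' @param contours optional named list (`left`, `right`).
#' @param image_id optional identifier carried through reports.
#' @return Object of class `detection_bundle`.
#' @export
detection_bundle <- function(landmarks, head_rois = list(), contours = NULL,
                             image_id = NULL) {
  stopifnot(inherits(landmarks, "landmark_set"))
  sides <- vapply(head_rois, function(r) {
    if (!inherits(r, "femoral_head_roi")) stop("head_rois must contain femoral_head_roi objects")
    r$side
  }, character(1))
  if (anyDuplicated(sides)) stop("head_rois: duplicate ROI for side ", sides[duplicated(sides)][1])
  structure(list(landmarks = landmarks, head_rois = head_rois,
                 contours = contours, image_id = image_id,
                 suppression_log = character()),
            class = "detection_bundle")
}

#' Validate a detection bundle against the provider contract
#'
#' @param bundle object to check.
#' @return `bundle`, invisibly; stops with the offending field on violation.
#' @export
validate_bundle <- function(bundle) {
  if (!inherits(bundle, "detection_bundle")) stop("not a detection_bundle")
  if (!inherits(bundle$landmarks, "landmark_set")) stop("field landmarks: not a landmark_set")
  sides <- vapply(bundle$head_rois, `[[`, character(1), "side")
  if (anyDuplicated(sides)) stop("field head_rois: duplicate side")
  invisible(bundle)
}

roi_for_side <- function(bundle, side, conf_threshold = 0.5) {
  for (r in bundle$head_rois)
    if (identical(r$side, side) && r$confidence >= conf_threshold) return(r)
  NULL
}

#' Suppress untrusted femoral-head-center landmarks
#'
#' Removes the C landmark of any hip for which no femoral-head ROI was
#' detected (confidence at or above `conf_threshold`); E, Y and H are never
#' touched and no point is ever added, so the operation is idempotent. In
#' `"global"` mode a single missing side wipes C bilaterally.
#'
#' @param bundle a `detection_bundle`.
#' @param conf_threshold minimum ROI confidence to count as detected.
#' @param mode `"per_side"` (default) or `"global"`.
#' @return The gated `landmark_set`; suppression events are recorded in its
#'   `"suppression_log"` attribute.
#' @export
suppress_point_c <- function(bundle, conf_threshold = 0.5,
                             mode = c("per_side", "global")) {
  validate_bundle(bundle)
  mode <- match.arg(mode)
  lm <- bundle$landmarks
  log <- character()
  has_roi <- vapply(c("left", "right"), function(s)
    !is.null(roi_for_side(bundle, s, conf_threshold)), logical(1))
  for (s in c("left", "right")) {
    keep <- if (mode == "global") all(has_roi) else has_roi[[s]]
    if (!keep && !is.null(lm[[s]]$C)) {
      lm[[s]]$C <- NULL
      log <- c(log, sprintf("suppressed C on %s hip: no femoral-head ROI", s))
    }
  }
  attr(lm, "suppression_log") <- log
  lm
}

#' Apply the gate to a bundle
#'
#' Convenience wrapper around [suppress_point_c()] returning a new bundle
#' with the gated landmarks and an appended suppression log.
#'
#' @inheritParams suppress_point_c
#' @return Gated `detection_bundle`.
#' @export
gate_bundle <- function(bundle, conf_threshold = 0.5, mode = c("per_side", "global")) {
  lm <- suppress_point_c(bundle, conf_threshold, mode)
  log <- attr(lm, "suppression_log")
  attr(lm, "suppression_log") <- NULL
  bundle$landmarks <- lm
  bundle$suppression_log <- c(bundle$suppression_log, log)
  bundle
}

#' Head radius from a femoral-head ROI
#'
#' The equivalent-circle radius of the segmented mask area; when only a
#' bounding box is available, a quarter of the mean box side (the radius of
#' a circle inscribed in the mean box dimension).
#'
#' @param roi a `femoral_head_roi`.
#' @return Radius in pixels.
#' @export
head_radius_from_roi <- function(roi) {
  stopifnot(inherits(roi, "femoral_head_roi"))
  if (roi$mask_area > 0) return(sqrt(roi$mask_area / pi))
  w <- roi$bbox[3] - roi$bbox[1]; h <- roi$bbox[4] - roi$bbox[2]
  if (w <= 0 || h <= 0) stop("degenerate bounding box")
  mean(c(w, h)) / 4
}

#' Extract a square local patch around a hip region
#'
#' Mirrors the local-patch stage of a two-stage detector: a `size` x `size`
#' window centered on the hip, clipped to the image bounds, together with
#' the offset that maps patch coordinates back to canvas coordinates
#' (`canvas = patch + offset`).
#'
#' @param image numeric matrix (rows = y).
#' @param center `(x, y)` patch center in 0-based pixels; must lie inside
#'   the image.
#' @param size requested side length in pixels, default 256.
#' @return List with `patch` (matrix) and `offset` (`c(x, y)`).
#' @export
extract_patch <- function(image, center, size = 256) {
  stopifnot(is.matrix(image))
  center <- as_pt(center)
  w <- ncol(image); h <- nrow(image)
  if (center[1] < 0 || center[1] > w - 1 || center[2] < 0 || center[2] > h - 1)
    stop("patch center lies outside the image")
  half <- floor(size / 2)
  x0 <- max(0, round(center[1]) - half); x1 <- min(w - 1, x0 + size - 1)
  y0 <- max(0, round(center[2]) - half); y1 <- min(h - 1, y0 + size - 1)
  x0 <- max(0, min(x0, x1 - size + 1)); y0 <- max(0, min(y0, y1 - size + 1))
  list(patch = image[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), drop = FALSE],
       offset = c(x = x0, y = y0))
}

#' Landmark providers
#'
#' A landmark provider is any function of one argument (the preprocessed
#' image, ignored by the bundled implementations) returning a valid
#' `detection_bundle`. Two implementations ship with the package:
#' `make_oracle_provider()` reads the ground truth of a synthetic case and
#' optionally perturbs every landmark with isotropic Gaussian jitter
#' (emulating detector error); `make_file_provider()` reads a landmark JSON
#' file.
#'
#' @param case a `synthetic_case`.
#' @param sigma jitter standard deviation in pixels per coordinate.
#' @param seed optional RNG seed for reproducible jitter.
#' @return A provider function.
#' @export
make_oracle_provider <- function(case, sigma = 0, seed = NULL) {
  stopifnot(inherits(case, "synthetic_case"), sigma >= 0)
  force(case); force(sigma); force(seed)
  function(image = NULL) {
    lm <- jitter_landmark_set(case$bundle$landmarks, sigma, seed)
    b <- detection_bundle(lm, head_rois = case$bundle$head_rois,
                          contours = case$bundle$contours,
                          image_id = case$bundle$image_id)
    validate_bundle(b)
  }
}

#' @rdname make_oracle_provider
#' @param path landmark JSON file path.
#' @export
make_file_provider <- function(path) {
  force(path)
  function(image = NULL) validate_bundle(read_landmark_json(path))
}
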