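# Landmark JSON dialect -- the interchange format between all modules:
# {
#   "image_id": "...", "pixel_spacing_mm": 0.2 | null,
#   "hips": {"left":  {"E":[x,y], "Y":[x,y], "C":[x,y]|null, "H":[x,y]},
#            "right": {...}},
#   "head_rois": [{"side","bbox":[x0,y0,x1,y1],"mask_area","confidence"}],
#   "contours": {"left": {"pubic_arc": [[x,y],...], ...}, "right": {...}},
#   "canvas_transform": {"scale","pad_x","pad_y","original_size","canvas_size"}
# }
# head_rois, contours and canvas_transform are optional.

json_pt <- function(p) if (is.null(p)) NULL else as.numeric(p)

#' Write a detection bundle (or landmark set) as landmark JSON
#'
#' @param x a `detection_bundle` or `landmark_set`.
#' @param path output path.
#' @param transform optional `canvas_transform` stored for traceability.
#' @return `path`, invisibly.
#' @export
write_landmark_json <- function(x, path, transform = NULL) {
  if (inherits(x, "landmark_set")) x <- detection_bundle(x)
  stopifnot(inherits(x, "detection_bundle"))
  lm <- x$landmarks
  hips <- lapply(c(left = "left", right = "right"), function(s) {
    h <- lm[[s]]
    list(E = json_pt(h$E), Y = json_pt(h$Y), C = json_pt(h$C), H = json_pt(h$H))
  })
  obj <- list(image_id = x$image_id,
              pixel_spacing_mm = lm$pixel_spacing_mm,
              hips = hips)
  if (length(x$head_rois))
    obj$head_rois <- lapply(x$head_rois, function(r)
      list(side = r$side, bbox = r$bbox, mask_area = r$mask_area,
           confidence = r$confidence))
  if (!is.null(x$contours))
    obj$contours <- lapply(x$contours, function(side_list)
      lapply(side_list, function(arc) unname(as.matrix(arc))))
  if (!is.null(transform))
    obj$canvas_transform <- unclass(transform)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a landmark JSON file into a detection bundle
#'
#' @param path landmark JSON path.
#' @return A `detection_bundle`. Malformed files (missing hips or required
#'   landmarks, bad point shapes) raise a schema error naming the field.
#' @export
read_landmark_json <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("malformed landmark JSON: ", conditionMessage(e)))
  if (is.null(obj$hips)) stop("landmark JSON schema error: missing 'hips'")
  get_pt <- function(side, name, required = TRUE) {
    v <- obj$hips[[side]][[name]]
    if (is.null(v) || (length(v) == 1 && is.na(v))) {
      if (required) stop("landmark JSON schema error: hips.", side, ".", name)
      return(NULL)
    }
    v <- suppressWarnings(as.numeric(v))
    if (length(v) != 2 || !all(is.finite(v)))
      stop("landmark JSON schema error: hips.", side, ".", name, " is not an [x, y] pair")
    v
  }
  mk <- function(side) {
    hip_landmarks(side,
                  E = get_pt(side, "E"), Y = get_pt(side, "Y"),
                  H = get_pt(side, "H"), C = get_pt(side, "C", required = FALSE))
  }
  spacing <- obj$pixel_spacing_mm
  if (!is.null(spacing) && (length(spacing) != 1 || is.na(spacing))) spacing <- NULL
  lm <- landmark_set(mk("left"), mk("right"), pixel_spacing_mm = spacing)
  rois <- list()
  if (!is.null(obj$head_rois)) {
    rr <- obj$head_rois
    if (is.data.frame(rr)) rr <- split(rr, seq_len(nrow(rr)))
    rois <- lapply(rr, function(r)
      femoral_head_roi(as.character(r$side), unlist(r$bbox),
                       mask_area = if (is.null(r$mask_area)) 0 else as.numeric(r$mask_area),
                       confidence = if (is.null(r$confidence)) 1 else as.numeric(r$confidence)))
    names(rois) <- NULL
  }
  contours <- NULL
  if (!is.null(obj$contours))
    contours <- lapply(obj$contours, function(side_list)
      lapply(side_list, function(arc) {
        m <- as.matrix(arc)
        if (ncol(m) != 2) stop("landmark JSON schema error: contour arcs must be n x 2")
        m
      }))
  detection_bundle(lm, head_rois = rois, contours = contours,
                   image_id = obj$image_id)
}

#' Write a measurement report CSV
#'
#' One row per hip with all measurement fields and grades; grades appear as
#' integers (Toennis) and Roman numerals (IHDI); boundary flags as a
#' semicolon-joined token list.
#'
#' @param report data.frame from [measure_landmark_set()] /
#'   [measure_bundle()] / [measure_cohort()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE, na = "")
  invisible(path)
}
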