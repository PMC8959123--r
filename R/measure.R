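# Assembly of the per-hip measurement record: the three numeric indices plus
# the Shenton status, with the absence rules (no C -> no CE angle, no AHI).

#' Measure one hip against a reference frame
#'
#' @param hip `hip_landmarks`.
#' @param frame `reference_frame` built from the same `landmark_set`.
#' @param head_radius femoral head radius in pixels, or `NULL` when no head
#'   circle is available (AHI then reported absent).
#' @param shenton optional list with `pubic_arc` and `neck_arc` (see
#'   [shenton_check()]); when `NULL` the Shenton status is `"indeterminate"`.
#' @param shenton_tol continuity tolerance in pixels.
#' @return List of class `hip_measurements`: `acetabular_index_deg`,
#'   `ce_angle_deg` (`NA` when C absent), `ahi_percent` (`NA` when C or the
#'   head radius is absent), `shenton`.
#' @export
measure_hip <- function(hip, frame, head_radius = NULL, shenton = NULL,
                        shenton_tol = 5) {
  stopifnot(inherits(hip, "hip_landmarks"), inherits(frame, "reference_frame"))
  hline <- frame$hilgenreiner
  ai <- acetabular_index(hip$E, hip$Y, hline)
  ce <- NA_real_; ahi <- NA_real_
  if (!is.null(hip$C)) {
    ce <- center_edge_angle(hip$C, hip$E, hline, hip$lateral_sign)
    if (!is.null(head_radius))
      ahi <- acetabular_head_index(hip$C, head_radius, hip$E, hline, hip$lateral_sign)
  }
  sh <- if (is.null(shenton)) "indeterminate"
        else as.character(shenton_check(shenton$pubic_arc, shenton$neck_arc, tol = shenton_tol))
  structure(list(acetabular_index_deg = ai, ce_angle_deg = ce,
                 ahi_percent = ahi, shenton = sh),
            class = "hip_measurements")
}

#' Measure and grade both hips of a landmark set
#'
#' Runs the full stage-3 engine: builds the reference frame once and returns
#' one row per hip with all indices and grades.
#'
#' @param landmarks a `landmark_set`.
#' @param head_radius named list/vector with per-side radii in pixels
#'   (`left`, `right`), entries may be `NULL`/`NA`.
#' @param shenton optional named list (`left`, `right`) of Shenton input
#'   lists (`pubic_arc`, `neck_arc`).
#' @param shenton_tol continuity tolerance in pixels.
#' @return `data.frame` with columns `side`, `acetabular_index_deg`,
#'   `ce_angle_deg`, `ahi_percent`, `shenton`, `tonnis`, `ihdi`,
#'   `ihdi_roman`, `boundary_flags`, `head_radius_px` and (when
#'   `pixel_spacing_mm` is set) `head_radius_mm`.
#' @export
measure_landmark_set <- function(landmarks, head_radius = list(), shenton = list(),
                                 shenton_tol = 5) {
  stopifnot(inherits(landmarks, "landmark_set"))
  frame <- reference_frame(landmarks)
  rows <- lapply(c("left", "right"), function(s) {
    hip <- landmarks[[s]]
    r <- head_radius[[s]]
    if (!is.null(r) && (!is.finite(r) || r <= 0)) r <- NULL
    m <- measure_hip(hip, frame, head_radius = r, shenton = shenton[[s]],
                     shenton_tol = shenton_tol)
    g <- grade_hip(hip, frame, head_radius = r)
    data.frame(side = s,
               acetabular_index_deg = m$acetabular_index_deg,
               ce_angle_deg = m$ce_angle_deg,
               ahi_percent = m$ahi_percent,
               shenton = m$shenton,
               tonnis = g$tonnis,
               ihdi = g$ihdi,
               ihdi_roman = g$ihdi_roman,
               boundary_flags = paste(g$boundary_flags, collapse = ";"),
               head_radius_px = if (is.null(r)) NA_real_ else r,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(landmarks$pixel_spacing_mm))
    out$head_radius_mm <- out$head_radius_px * landmarks$pixel_spacing_mm
  out
}
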