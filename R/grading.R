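# Rule-based dislocation grading. Both graders work in the
# Hilgenreiner-horizontal frame; ties "at a line" resolve toward the lower
# grade and are recorded in boundary_flags for auditability.

.flag_eps <- 1e-9

side_line <- function(frame, what, side) frame[[paste(what, side, sep = "_")]]

#' IHDI grade of one hip
#'
#' Classifies the H point (midpoint of the superior margin of the ossified
#' femoral metaphysis) into the four IHDI quadrant grades, using the
#' Hilgenreiner line (H-line), the Perkin line (P-line) and the 45 degree
#' inferolateral diagonal (D-line) from the H-P junction:
#' grade I when H is at or medial to the P-line; II when lateral to the
#' P-line but at or medial to the D-line; III when lateral to the D-line but
#' at or inferior to the H-line; IV when superior to the H-line. Points
#' exactly on a line take the lower grade and the event is recorded.
#'
#' @param H metaphysis midpoint landmark.
#' @param frame a `reference_frame`.
#' @param side `"left"` or `"right"`.
#' @param lateral_sign +1/-1 for this hip.
#' @return List with integer `grade` (1-4) and character `boundary_flags`.
#' @export
ihdi_grade <- function(H, frame, side, lateral_sign) {
  stopifnot(inherits(frame, "reference_frame"))
  side <- match.arg(side, c("left", "right"))
  hline <- frame$hilgenreiner
  Hh <- to_hframe(H, hline)
  Jh <- to_hframe(side_line(frame, "dline", side)$anchor, hline)
  l <- lateral_sign * (Hh[1] - Jh[1])  # + lateral of the Perkin line
  s <- Jh[2] - Hh[2]                   # + superior to the Hilgenreiner line
  flags <- character()
  if (abs(l) < .flag_eps) flags <- c(flags, "on_perkin")
  if (abs(l + s) < .flag_eps) flags <- c(flags, "on_dline")
  if (abs(s) < .flag_eps) flags <- c(flags, "on_hline")
  grade <-
    if (l <= 0) 1L
    else if (l + s <= 0) 2L
    else if (s <= 0) 3L
    else 4L
  list(grade = grade, boundary_flags = flags)
}

#' Toennis grade of one hip
#'
#' Classifies the femoral head ossific nucleus center C against the Perkin
#' line and the level of the acetabular rim: grade 1 when C is at or medial
#' to the Perkin line; otherwise grade 2 when C lies inferior to the rim
#' band, grade 3 within it, grade 4 superior to it. The rim band is the
#' horizontal strip of half-width `head_radius` centered on E's
#' superior-inferior level; it makes the clinical "at the level of the rim"
#' comparison operational for a finite-sized nucleus. Ties take the lower
#' grade.
#'
#' @param C femoral head center.
#' @param head_radius femoral head radius in pixels (> 0).
#' @param frame a `reference_frame`.
#' @param E lateral acetabular margin of the same hip.
#' @param side `"left"` or `"right"`.
#' @param lateral_sign +1/-1 for this hip.
#' @return List with integer `grade` (1-4) and character `boundary_flags`.
#' @export
tonnis_grade <- function(C, head_radius, frame, E, side, lateral_sign) {
  stopifnot(inherits(frame, "reference_frame"))
  if (!is.finite(head_radius) || head_radius <= 0) stop("head_radius must be positive")
  side <- match.arg(side, c("left", "right"))
  hline <- frame$hilgenreiner
  Ch <- to_hframe(C, hline); Eh <- to_hframe(E, hline)
  l <- lateral_sign * (Ch[1] - Eh[1])  # + lateral of the Perkin line
  dy <- Ch[2] - Eh[2]                  # + inferior to the rim level
  flags <- character()
  if (abs(l) < .flag_eps) flags <- c(flags, "on_perkin")
  if (abs(dy - head_radius) < .flag_eps || abs(dy + head_radius) < .flag_eps)
    flags <- c(flags, "rim_band")
  grade <-
    if (l <= 0) 1L
    else if (dy >= head_radius) 2L
    else if (dy >= -head_radius) 3L
    else 4L
  list(grade = grade, boundary_flags = flags)
}

#' Shenton's line continuity check
#'
#' Geometric proxy for the radiologist's judgment: Shenton's line is intact
#' when the medial femoral neck border continues the arc of the inferior
#' border of the superior pubic ramus. A circle is fitted to the pubic arc by
#' algebraic least squares (Kasa fit); the line is called intact when the
#' largest absolute radial residual of the neck-arc points from that circle
#' is at most `tol` pixels.
#'
#' @param pubic_arc n x 2 matrix (or list of points) along the inferior
#'   border of the superior pubic ramus, n >= 3.
#' @param neck_arc m x 2 matrix along the medial femoral neck border, m >= 3.
#' @param tol continuity tolerance in pixels (> 0), default 5.
#' @return `"intact"`, `"disrupted"`, or `"indeterminate"` (collinear pubic
#'   arc, circle fit singular). The fitted circle and the maximum residual
#'   are attached as attributes `circle` and `max_residual`.
#' @export
shenton_check <- function(pubic_arc, neck_arc, tol = 5) {
  if (!is.finite(tol) || tol <= 0) stop("tol must be positive")
  pubic_arc <- as_arc(pubic_arc); neck_arc <- as_arc(neck_arc)
  fit <- fit_circle(pubic_arc)
  if (is.null(fit)) {
    return(structure("indeterminate", circle = NULL, max_residual = NA_real_))
  }
  r <- sqrt((neck_arc[, 1] - fit$center[1])^2 + (neck_arc[, 2] - fit$center[2])^2)
  mres <- max(abs(r - fit$radius))
  structure(if (mres <= tol) "intact" else "disrupted",
            circle = fit, max_residual = mres)
}

as_arc <- function(a) {
  if (is.list(a) && !is.data.frame(a)) a <- do.call(rbind, a)
  a <- as.matrix(a)
  if (ncol(a) != 2L || nrow(a) < 3L || !all(is.finite(a)))
    stop("an arc needs at least 3 finite (x, y) points")
  a
}

# Algebraic (Kasa) least-squares circle: minimize ||x^2+y^2 + a x + b y + c||.
# Returns NULL when the points are (numerically) collinear.
fit_circle <- function(xy) {
  X <- cbind(xy[, 1], xy[, 2], 1)
  z <- -(xy[, 1]^2 + xy[, 2]^2)
  qr_x <- qr(X)
  if (qr_x$rank < 3L) return(NULL)
  abc <- qr.coef(qr_x, z)
  r2 <- abc[1]^2 / 4 + abc[2]^2 / 4 - abc[3]
  if (!is.finite(r2) || r2 <= .flag_eps) return(NULL)
  list(center = c(x = -abc[1] / 2, y = -abc[2] / 2), radius = sqrt(r2))
}

#' Grade one hip (Toennis + IHDI)
#'
#' Assembles the full grading record for a hip: the Toennis grade is absent
#' when the femoral head center C is absent (ossific nucleus not visible);
#' the IHDI grade only needs H and is always computed.
#'
#' @param hip `hip_landmarks`.
#' @param frame `reference_frame` built from the same landmark set.
#' @param head_radius femoral head radius in pixels, or `NULL`.
#' @return List of class `grading_result`: `tonnis` (integer or `NA`),
#'   `ihdi` (integer 1-4), `ihdi_roman`, `boundary_flags`.
#' @export
grade_hip <- function(hip, frame, head_radius = NULL) {
  stopifnot(inherits(hip, "hip_landmarks"))
  ih <- ihdi_grade(hip$H, frame, hip$side, hip$lateral_sign)
  flags <- ih$boundary_flags
  tn <- NA_integer_
  if (!is.null(hip$C) && !is.null(head_radius)) {
    t <- tonnis_grade(hip$C, head_radius, frame, hip$E, hip$side, hip$lateral_sign)
    tn <- t$grade
    flags <- union(flags, t$boundary_flags)
  }
  structure(list(tonnis = tn, ihdi = ih$grade,
                 ihdi_roman = as.character(utils::as.roman(ih$grade)),
                 boundary_flags = flags),
            class = "grading_result")
}
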