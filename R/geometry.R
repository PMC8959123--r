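# Core 2D geometry in image coordinates: x increases rightward (columns),
# y increases downward (rows), 0-based pixels. "Superior" therefore means
# smaller y. All angle work happens in the Hilgenreiner-horizontal frame.

#' Construct a 2D point
#'
#' Points live in image coordinates: `x` is the column (rightward), `y` the
#' row (downward), both in pixels.
#'
#' @param x,y finite numeric coordinates in pixels.
#' @return Named numeric vector `c(x =, y =)`.
#' @export
pt <- function(x, y) {
  p <- c(x = as.numeric(x)[1], y = as.numeric(y)[1])
  if (!all(is.finite(p))) stop("point coordinates must be finite")
  p
}

as_pt <- function(p) {
  if (is.null(p)) return(NULL)
  p <- as.numeric(p)
  if (length(p) != 2L || !all(is.finite(p))) stop("expected a finite (x, y) pair")
  c(x = p[1], y = p[2])
}

#' Construct an infinite 2D line
#'
#' @param anchor point on the line.
#' @param direction direction vector; normalized to unit length.
#' @return Object of class `line2d` with fields `anchor` and `direction`
#'   (unit vector).
#' @export
line2d <- function(anchor, direction) {
  anchor <- as_pt(anchor)
  direction <- as.numeric(direction)
  n <- sqrt(sum(direction^2))
  if (!is.finite(n) || n < 1e-12) stop("line direction is degenerate")
  structure(list(anchor = anchor, direction = c(x = direction[1], y = direction[2]) / n),
            class = "line2d")
}

#' @export
print.line2d <- function(x, ...) {
  cat(sprintf("<line2d> anchor (%.3f, %.3f), direction (%.6f, %.6f)\n",
              x$anchor[1], x$anchor[2], x$direction[1], x$direction[2]))
  invisible(x)
}

#' Per-hip landmark record
#'
#' The four named landmarks of one hip on an AP pelvic radiograph:
#' E (superolateral margin of the bony acetabulum), Y (tri-radiate cartilage
#' center), C (femoral head center; may be absent when the ossific nucleus is
#' not visible), and H (midpoint of the superior margin of the ossified
#' femoral metaphysis).
#'
#' `lateral_sign` is the sign of the image-x direction that points away from
#' the body midline for this hip (+1 for the patient-left hip on a
#' conventionally displayed AP film, -1 for the patient-right hip). It is
#' stored explicitly so that no geometry ever infers laterality from pixel
#' position.
#'
#' @param side `"left"` or `"right"` (patient side).
#' @param E,Y,H landmark points (`x`, `y` pairs).
#' @param C femoral head center, or `NULL` when absent.
#' @param lateral_sign `+1` or `-1`.
#' @return Object of class `hip_landmarks`.
#' @export
hip_landmarks <- function(side, E, Y, H, C = NULL,
                          lateral_sign = if (identical(side, "left")) 1 else -1) {
  side <- match.arg(side, c("left", "right"))
  E <- as_pt(E); Y <- as_pt(Y); H <- as_pt(H); C <- if (is.null(C)) NULL else as_pt(C)
  if (!lateral_sign %in% c(-1, 1)) stop("lateral_sign must be +1 or -1")
  if (sqrt(sum((E - Y)^2)) < 1e-9) stop("E and Y must be distinct")
  structure(list(side = side, E = E, Y = Y, C = C, H = H,
                 lateral_sign = lateral_sign),
            class = "hip_landmarks")
}

#' Bilateral landmark set
#'
#' @param left,right `hip_landmarks` for each patient side.
#' @param pixel_spacing_mm optional isotropic pixel spacing in mm/px.
#' @return Object of class `landmark_set`.
#' @export
landmark_set <- function(left, right, pixel_spacing_mm = NULL) {
  stopifnot(inherits(left, "hip_landmarks"), inherits(right, "hip_landmarks"))
  if (!identical(left$side, "left") || !identical(right$side, "right"))
    stop("landmark_set expects a left and a right hip, in that order")
  if (sqrt(sum((left$Y - right$Y)^2)) < 1e-9)
    stop("coincident tri-radiate centers: Hilgenreiner's line is undefined")
  if (!is.null(pixel_spacing_mm) && (!is.finite(pixel_spacing_mm) || pixel_spacing_mm <= 0))
    stop("pixel_spacing_mm must be a positive number")
  structure(list(left = left, right = right, pixel_spacing_mm = pixel_spacing_mm),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set>\n")
  for (s in c("left", "right")) {
    h <- x[[s]]
    cat(sprintf("  %s: E(%.1f,%.1f) Y(%.1f,%.1f) C(%s) H(%.1f,%.1f)\n", s,
                h$E[1], h$E[2], h$Y[1], h$Y[2],
                if (is.null(h$C)) "absent" else sprintf("%.1f,%.1f", h$C[1], h$C[2]),
                h$H[1], h$H[2]))
  }
  invisible(x)
}

#' Hilgenreiner's line through both tri-radiate cartilage centers
#'
#' The horizontal reference of the pelvis. The returned direction is
#' canonicalized to have a non-negative x component so that the
#' Hilgenreiner-horizontal frame preserves image left/right orientation.
#'
#' @param Y_left,Y_right tri-radiate cartilage centers of the two hips.
#' @return `line2d` anchored at the midpoint of the two Y points.
#' @export
hilgenreiner_line <- function(Y_left, Y_right) {
  Y_left <- as_pt(Y_left); Y_right <- as_pt(Y_right)
  d <- Y_right - Y_left
  if (sqrt(sum(d^2)) < 1e-9) stop("coincident tri-radiate centers")
  if (d[1] < 0) d <- -d
  line2d((Y_left + Y_right) / 2, d)
}

#' Perkin's line: perpendicular to Hilgenreiner's line through E
#'
#' @param E lateral acetabular margin landmark.
#' @param hline Hilgenreiner `line2d`.
#' @return `line2d` through `E` perpendicular to `hline`.
#' @export
perkin_line <- function(E, hline) {
  stopifnot(inherits(hline, "line2d"))
  u <- hline$direction
  line2d(E, c(-u[2], u[1]))
}

# Rotate+translate points into the frame where the Hilgenreiner line is the
# horizontal axis (anchor at the origin). `p` is a length-2 point or an
# n x 2 matrix. With the canonical direction (x >= 0) the frame keeps the
# image's left/right and superior/inferior orientation.
to_hframe <- function(p, hline) {
  u <- hline$direction
  rot <- rbind(c(u[1], u[2]), c(-u[2], u[1]))  # rotation by -theta
  if (is.matrix(p)) {
    sweep(p, 2, hline$anchor) %*% t(rot)
  } else {
    as.numeric(rot %*% (as_pt(p) - hline$anchor))
  }
}

#' Acetabular index
#'
#' Angle between the acetabular roof segment (Y to E) and Hilgenreiner's
#' line, in degrees. Positive when E lies superior to the line through Y
#' parallel to Hilgenreiner (the normal configuration); larger values mean a
#' shallower, more dysplastic socket.
#'
#' @param E lateral acetabular margin.
#' @param Y tri-radiate cartilage center of the same hip.
#' @param hline Hilgenreiner `line2d`.
#' @return Angle in degrees, in (-90, 90) for non-vertical roofs.
#' @export
acetabular_index <- function(E, Y, hline) {
  Eh <- to_hframe(E, hline); Yh <- to_hframe(Y, hline)
  v <- Eh - Yh
  if (sqrt(sum(v^2)) < 1e-9) stop("degenerate acetabular roof: E coincides with Y")
  ang <- atan2(abs(v[2]), abs(v[1])) * 180 / pi
  if (v[2] > 0) ang <- -ang  # E inferior to Y-parallel: negative index
  ang
}

#' Center-edge angle of Wiberg
#'
#' Angle at the femoral head center C between the superior perpendicular to
#' Hilgenreiner's line and the ray from C to the lateral acetabular margin E.
#' Positive when E is lateral of that perpendicular (good coverage); values
#' near zero or negative indicate an uncovered head.
#'
#' @param C femoral head center.
#' @param E lateral acetabular margin.
#' @param hline Hilgenreiner `line2d`.
#' @param lateral_sign +1/-1, image-x direction away from the midline.
#' @return Angle in degrees.
#' @export
center_edge_angle <- function(C, E, hline, lateral_sign) {
  Ch <- to_hframe(C, hline); Eh <- to_hframe(E, hline)
  w <- Eh - Ch
  if (sqrt(sum(w^2)) < 1e-9) stop("degenerate geometry: C coincides with E")
  atan2(lateral_sign * w[1], -w[2]) * 180 / pi
}

#' Acetabular head index (AHI)
#'
#' Percent of the femoral head width covered by the acetabulum: with the
#' Hilgenreiner line horizontal, the head spans `2 * head_radius` along the
#' line and the covered part runs from the medial head (circle) edge to the
#' projection of E. Values near 100 mean full coverage; the result is not
#' clipped, so a laterally displaced head can score below 0 and an over-
#' covered one above 100.
#'
#' @param C femoral head center.
#' @param head_radius femoral head radius in pixels (> 0).
#' @param E lateral acetabular margin.
#' @param hline Hilgenreiner `line2d`.
#' @param lateral_sign +1/-1, image-x direction away from the midline.
#' @return Coverage percentage.
#' @export
acetabular_head_index <- function(C, head_radius, E, hline, lateral_sign) {
  if (!is.finite(head_radius) || head_radius <= 0) stop("head_radius must be positive")
  Ch <- to_hframe(C, hline); Eh <- to_hframe(E, hline)
  covered <- lateral_sign * (Eh[1] - Ch[1]) + head_radius
  100 * covered / (2 * head_radius)
}

#' Build the full reference frame for a landmark set
#'
#' Constructs Hilgenreiner's line, a Perkin line per hip, and the per-hip
#' IHDI diagonal ("D") line: the 45 degree inferolateral ray from the
#' Hilgenreiner-Perkin junction (the projection of E onto Hilgenreiner's
#' line).
#'
#' @param landmarks a `landmark_set`.
#' @return Object of class `reference_frame` with fields `hilgenreiner`,
#'   `perkin_left`, `perkin_right`, `dline_left`, `dline_right`.
#' @export
reference_frame <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  hline <- hilgenreiner_line(landmarks$left$Y, landmarks$right$Y)
  u <- hline$direction
  n_inf <- c(-u[2], u[1])  # inferior normal (y increases downward)
  one_side <- function(hip) {
    t_along <- sum((hip$E - hline$anchor) * u)
    junction <- hline$anchor + t_along * u
    list(perkin = perkin_line(hip$E, hline),
         dline = line2d(junction, hip$lateral_sign * u + n_inf))
  }
  l <- one_side(landmarks$left); r <- one_side(landmarks$right)
  structure(list(hilgenreiner = hline,
                 perkin_left = l$perkin, perkin_right = r$perkin,
                 dline_left = l$dline, dline_right = r$dline),
            class = "reference_frame")
}

#' Reflect a landmark set about a vertical midline
#'
#' Utility for symmetry checks and display-convention conversion: mirrors all
#' points about `x = midline_x` and swaps the hips (the mirrored patient-left
#' hip becomes the patient-right hip, with flipped `lateral_sign`).
#'
#' @param landmarks a `landmark_set`.
#' @param midline_x x coordinate of the mirror axis in pixels.
#' @return Mirrored `landmark_set`.
#' @export
reflect_landmark_set <- function(landmarks, midline_x) {
  stopifnot(inherits(landmarks, "landmark_set"))
  mir <- function(p) if (is.null(p)) NULL else c(x = 2 * midline_x - p[1], y = p[2])
  flip <- function(hip, new_side) {
    hip_landmarks(new_side, E = mir(hip$E), Y = mir(hip$Y), H = mir(hip$H),
                  C = mir(hip$C), lateral_sign = -hip$lateral_sign)
  }
  landmark_set(left = flip(landmarks$right, "left"),
               right = flip(landmarks$left, "right"),
               pixel_spacing_mm = landmarks$pixel_spacing_mm)
}
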