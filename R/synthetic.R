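# Parametric synthetic pelvis: bilateral landmark geometry with known
# generating parameters, so every downstream measurement can be checked by
# inverse consistency. Scene scale roughly matches a pediatric AP pelvis on
# a 1333 x 800 canvas: tri-radiate centers 100 px from the midline, femoral
# head radius 20 px.

deg2rad <- function(d) d * pi / 180

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

per_side <- function(x, default) {
  if (is.null(x)) x <- default
  if (is.list(x)) {
    if (!all(c("left", "right") %in% names(x))) stop("per-side parameter needs left and right")
    return(x)
  }
  if (length(x) == 1L) list(left = x, right = x)
  else if (!is.null(names(x)) && all(c("left", "right") %in% names(x)))
    list(left = unname(x[["left"]]), right = unname(x[["right"]]))
  else list(left = x[1], right = x[2])
}

# per-side parameter whose value is itself a length-2 vector (e.g. the
# (lateral, superior) displacement): only a list distinguishes the sides
per_side_vec <- function(x, default) {
  if (is.null(x)) x <- default
  if (is.list(x)) {
    if (!all(c("left", "right") %in% names(x))) stop("per-side parameter needs left and right")
    lapply(x[c("left", "right")], as.numeric)
  } else {
    x <- as.numeric(x)
    if (length(x) != 2L) stop("expected a (lateral, superior) pair")
    list(left = x, right = x)
  }
}

#' Synthetic pelvis parameters
#'
#' Generating parameters of one bilateral case. Per-hip parameters accept a
#' scalar (both hips), a named vector, or a `list(left =, right =)`.
#'
#' @param ai_deg acetabular index per hip, degrees.
#' @param ce_deg center-edge angle per hip, degrees (drives the undisplaced
#'   femoral-head-center position).
#' @param head_radius femoral head radius, px (> 0).
#' @param hip_halfwidth distance from the midline to each tri-radiate
#'   center, px.
#' @param roof_length length of the acetabular roof segment Y-E, px.
#' @param c_to_e_dist distance from the undisplaced head center to E, px.
#' @param metaphysis_offset `(lateral_px, inferior_px)` from C to H.
#' @param pelvic_rotation_deg in-plane rotation of the whole scene,
#'   |rotation| < 30.
#' @param displacement per hip `(lateral_px, superior_px)` applied to C and
#'   H; this is what drives the Toennis/IHDI grade.
#' @param noise_sigma_px landmark jitter SD per coordinate applied to the
#'   detection bundle (ground truth stays clean), emulating detector error.
#' @param c_visible per hip: is the ossific nucleus visible? When `FALSE`
#'   the truth has no C, but the bundle still carries a (spurious) C with no
#'   head ROI on that side, so the segmentation gate must remove it.
#' @param center scene center `(x, y)` on the canvas, px.
#' @param pixel_spacing_mm optional isotropic pixel spacing.
#' @param seed optional RNG seed for the jitter.
#' @return Object of class `pelvis_params`.
#' @export
pelvis_params <- function(ai_deg = 25, ce_deg = 19, head_radius = 20,
                          hip_halfwidth = 100, roof_length = 35,
                          c_to_e_dist = 1.8 * head_radius,
                          metaphysis_offset = c(0, 25),
                          pelvic_rotation_deg = 0,
                          displacement = c(0, 0),
                          noise_sigma_px = 0,
                          c_visible = TRUE,
                          center = c(666, 400),
                          pixel_spacing_mm = NULL,
                          seed = NULL) {
  p <- list(ai_deg = per_side(ai_deg, 25), ce_deg = per_side(ce_deg, 19),
            head_radius = head_radius, hip_halfwidth = hip_halfwidth,
            roof_length = roof_length, c_to_e_dist = c_to_e_dist,
            metaphysis_offset = as.numeric(metaphysis_offset),
            pelvic_rotation_deg = pelvic_rotation_deg,
            displacement = per_side_vec(displacement, c(0, 0)),
            noise_sigma_px = noise_sigma_px,
            c_visible = per_side(c_visible, TRUE),
            center = as.numeric(center),
            pixel_spacing_mm = pixel_spacing_mm, seed = seed)
  if (!is.finite(p$head_radius) || p$head_radius <= 0) stop("head_radius must be positive")
  if (abs(p$pelvic_rotation_deg) >= 30) stop("|pelvic_rotation_deg| must be below 30")
  if (p$noise_sigma_px < 0) stop("noise_sigma_px must be nonnegative")
  for (s in c("left", "right")) {
    if (abs(p$ai_deg[[s]]) >= 90) stop("ai_deg must lie in (-90, 90)")
    if (abs(p$ce_deg[[s]]) >= 90) stop("ce_deg must lie in (-90, 90)")
    if (p$ai_deg[[s]] > 0 && p$roof_length * sin(deg2rad(p$ai_deg[[s]])) < 0)
      stop("infeasible roof geometry")
  }
  if (p$hip_halfwidth <= 0 || p$roof_length <= 0 || p$c_to_e_dist <= 0)
    stop("hip_halfwidth, roof_length and c_to_e_dist must be positive")
  structure(p, class = "pelvis_params")
}

rot_about <- function(p, center, theta) {
  if (theta == 0) return(p)
  ct <- cos(theta); st <- sin(theta)
  d <- p - center
  center + c(ct * d[1] - st * d[2], st * d[1] + ct * d[2])
}

rot_arc <- function(m, center, theta) {
  if (theta == 0) return(m)
  t(apply(m, 1, function(p) rot_about(p, center, theta)))
}

# Clean (unrotated, undisplaced frame) geometry of one hip.
hip_points_raw <- function(p, side, displacement) {
  ls <- if (side == "left") 1 else -1
  cx <- p$center[1]; cy <- p$center[2]
  ai <- deg2rad(p$ai_deg[[side]]); ce <- deg2rad(p$ce_deg[[side]])
  Y <- c(cx + ls * p$hip_halfwidth, cy)
  E <- Y + c(ls * p$roof_length * cos(ai), -p$roof_length * sin(ai))
  C0 <- E + c(-ls * p$c_to_e_dist * sin(ce), p$c_to_e_dist * cos(ce))
  C <- C0 + c(ls * displacement[1], -displacement[2])
  H <- C + c(ls * p$metaphysis_offset[1], p$metaphysis_offset[2])
  list(Y = Y, E = E, C0 = C0, C = C, H = H, lateral_sign = ls)
}

shenton_arcs_raw <- function(p, side, displacement) {
  g <- hip_points_raw(p, side, c(0, 0))
  ls <- g$lateral_sign
  O <- g$C0 + c(-ls * 10, 30)
  Rs <- 55
  arc <- function(phis) cbind(O[1] - ls * Rs * sin(phis), O[2] - Rs * cos(phis))
  pubic <- arc(deg2rad(seq(25, 70, length.out = 12)))
  neck <- arc(deg2rad(seq(-45, -5, length.out = 10)))
  shift <- c(ls * displacement[1], -displacement[2])
  neck <- sweep(neck, 2, shift, `+`)
  list(pubic_arc = pubic, neck_arc = neck)
}

jitter_landmark_set <- function(lm, sigma, seed = NULL) {
  if (sigma == 0) return(lm)
  with_seed(seed, {
    for (s in c("left", "right")) {
      for (nm in c("E", "Y", "C", "H")) {
        if (!is.null(lm[[s]][[nm]]))
          lm[[s]][[nm]] <- lm[[s]][[nm]] + stats::rnorm(2, 0, sigma)
      }
    }
    lm
  })
}

#' Generate one synthetic pelvis case
#'
#' Builds clean ground-truth landmarks from the generating parameters,
#' derives the detection bundle (with optional Gaussian landmark jitter and
#' with a spurious C / missing head ROI when the nucleus is invisible), and
#' records the ground-truth measurements and grades computed on the clean
#' points.
#'
#' @param params a `pelvis_params`.
#' @return Object of class `synthetic_case` with fields `params`, `truth`
#'   (`landmark_set`), `bundle` (`detection_bundle`), `truth_measurements`
#'   and `truth_grades` (per-side lists).
#' @export
generate_case <- function(params) {
  stopifnot(inherits(params, "pelvis_params"))
  theta <- deg2rad(params$pelvic_rotation_deg)
  ctr <- params$center
  truth_hips <- list(); bundle_hips <- list(); rois <- list(); contours <- list()
  for (s in c("left", "right")) {
    g <- hip_points_raw(params, s, params$displacement[[s]])
    pts <- lapply(g[c("E", "Y", "C", "H")], rot_about, center = ctr, theta = theta)
    visible <- isTRUE(params$c_visible[[s]])
    truth_hips[[s]] <- hip_landmarks(s, E = pts$E, Y = pts$Y, H = pts$H,
                                     C = if (visible) pts$C else NULL,
                                     lateral_sign = g$lateral_sign)
    # the bundle always carries C: when the nucleus is invisible this is the
    # spurious detection the segmentation gate must suppress
    bundle_hips[[s]] <- hip_landmarks(s, E = pts$E, Y = pts$Y, H = pts$H,
                                      C = pts$C, lateral_sign = g$lateral_sign)
    if (visible) {
      r <- params$head_radius
      rois[[length(rois) + 1L]] <- femoral_head_roi(
        s, bbox = c(pts$C[1] - r, pts$C[2] - r, pts$C[1] + r, pts$C[2] + r),
        mask_area = pi * r^2, confidence = 1)
    }
    arcs <- shenton_arcs_raw(params, s, params$displacement[[s]])
    contours[[s]] <- list(pubic_arc = rot_arc(arcs$pubic_arc, ctr, theta),
                          neck_arc = rot_arc(arcs$neck_arc, ctr, theta))
  }
  truth <- landmark_set(truth_hips$left, truth_hips$right,
                        pixel_spacing_mm = params$pixel_spacing_mm)
  blm <- landmark_set(bundle_hips$left, bundle_hips$right,
                      pixel_spacing_mm = params$pixel_spacing_mm)
  blm <- jitter_landmark_set(blm, params$noise_sigma_px, params$seed)
  bundle <- detection_bundle(blm, head_rois = rois, contours = contours)
  frame <- reference_frame(truth)
  tm <- list(); tg <- list()
  for (s in c("left", "right")) {
    r <- if (isTRUE(params$c_visible[[s]])) params$head_radius else NULL
    tm[[s]] <- measure_hip(truth[[s]], frame, head_radius = r, shenton = contours[[s]])
    tg[[s]] <- grade_hip(truth[[s]], frame, head_radius = r)
  }
  structure(list(params = params, truth = truth, bundle = bundle,
                 truth_measurements = tm, truth_grades = tg),
            class = "synthetic_case")
}

#' Sample a synthetic cohort with a target grade mix
#'
#' Draws per-hip acetabular-index and CE-angle parameters from truncated
#' normal distributions (clinically plausible pediatric ranges) and, for
#' each hip, rejection-samples a femoral displacement until the clean-truth
#' IHDI grade matches a target drawn from `grade_mix`. Rejection against the
#' grading module itself keeps that module the single source of truth for
#' the region boundaries, so cohort labels agree with it by construction.
#'
#' @param n number of cases (>= 1).
#' @param grade_mix probability over IHDI grades I-IV, summing to 1.
#' @param noise_sigma_px landmark jitter SD applied to each case's bundle.
#' @param seed RNG seed for the whole cohort.
#' @param ai_mean,ai_sd,ce_mean,ce_sd sampling distribution of the per-hip
#'   index parameters, degrees.
#' @param c_invisible_rate probability that a hip's ossific nucleus is
#'   invisible (spurious-C + missing-ROI case), default 0.
#' @return List of `synthetic_case` objects.
#' @export
sample_cohort <- function(n, grade_mix = c(0.4, 0.3, 0.2, 0.1),
                          noise_sigma_px = 0, seed = NULL,
                          ai_mean = 25, ai_sd = 4, ce_mean = 19, ce_sd = 6,
                          c_invisible_rate = 0) {
  stopifnot(n >= 1)
  grade_mix <- as.numeric(grade_mix)
  if (length(grade_mix) != 4L || any(grade_mix < 0) || abs(sum(grade_mix) - 1) > 1e-9)
    stop("grade_mix must be 4 nonnegative probabilities summing to 1")
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      ai <- pmin(pmax(stats::rnorm(2, ai_mean, ai_sd), 5), 45)
      ce <- pmin(pmax(stats::rnorm(2, ce_mean, ce_sd), -5), 40)
      targets <- sample.int(4, 2, replace = TRUE, prob = grade_mix)
      disp <- list()
      base <- pelvis_params(ai_deg = list(left = ai[1], right = ai[2]),
                            ce_deg = list(left = ce[1], right = ce[2]))
      for (k in 1:2) {
        s <- c("left", "right")[k]
        disp[[s]] <- reject_displacement(base, s, targets[k])
      }
      vis <- stats::runif(2) >= c_invisible_rate
      generate_case(pelvis_params(
        ai_deg = list(left = ai[1], right = ai[2]),
        ce_deg = list(left = ce[1], right = ce[2]),
        displacement = disp,
        noise_sigma_px = noise_sigma_px,
        c_visible = list(left = vis[1], right = vis[2]),
        seed = NULL))
    })
  })
}

# Rejection sampler: uniform displacement proposals graded by the real
# grading code until the requested IHDI grade is hit.
reject_displacement <- function(base, side, target, max_iter = 5000) {
  hline <- line2d(base$center, c(1, 0))
  for (it in seq_len(max_iter)) {
    cand <- c(stats::runif(1, -5, 90), stats::runif(1, -25, 70))
    g <- hip_points_raw(base, side, cand)
    other <- if (side == "left") "right" else "left"
    go <- hip_points_raw(base, other, c(0, 0))
    lm <- if (side == "left")
      landmark_set(hip_landmarks("left", g$E, g$Y, g$H, g$C),
                   hip_landmarks("right", go$E, go$Y, go$H, go$C))
    else
      landmark_set(hip_landmarks("left", go$E, go$Y, go$H, go$C),
                   hip_landmarks("right", g$E, g$Y, g$H, g$C))
    fr <- reference_frame(lm)
    if (ihdi_grade(g$H, fr, side, g$lateral_sign)$grade == target) return(cand)
  }
  stop("unreachable grade ", target, " under the displacement bounds")
}

#' Render a toy radiograph of a synthetic case
#'
#' Draws filled proxy shapes (iliac wing, pubis/ischium block, femoral head
#' disk, metaphysis) at the ground-truth positions on a dark background.
#' Purely geometric and deterministic -- a fixture for preprocessing and
#' patch tests, not a photorealistic radiograph.
#'
#' @param case a `synthetic_case`.
#' @param canvas `(width, height)` in pixels, default 1333 x 800.
#' @return Numeric matrix in \[0, 1\] (rows = y).
#' @export
render_image <- function(case, canvas = c(1333, 800)) {
  stopifnot(inherits(case, "synthetic_case"))
  cw <- canvas[1]; ch <- canvas[2]
  all_pts <- do.call(rbind, unlist(lapply(c("left", "right"), function(s) {
    h <- case$truth[[s]]
    lapply(Filter(Negate(is.null), h[c("E", "Y", "C", "H")]), rbind)
  }), recursive = FALSE))
  if (any(all_pts[, 1] < 0 | all_pts[, 1] > cw - 1 |
          all_pts[, 2] < 0 | all_pts[, 2] > ch - 1))
    stop("canvas smaller than the scene")
  xs <- matrix(rep(0:(cw - 1), each = ch), nrow = ch)
  ys <- matrix(rep(0:(ch - 1), times = cw), nrow = ch)
  img <- matrix(0, nrow = ch, ncol = cw)
  ellipse <- function(cxy, a, b, value) {
    m <- ((xs - cxy[1]) / a)^2 + ((ys - cxy[2]) / b)^2 <= 1
    img[m] <<- pmax(img[m], value)
  }
  for (s in c("left", "right")) {
    hip <- case$truth[[s]]
    ls <- hip$lateral_sign
    ellipse(hip$Y + c(ls * 20, -60), 45, 70, 0.45)       # iliac wing proxy
    ellipse(hip$Y + c(-ls * 30, 40), 35, 25, 0.40)       # pubis/ischium proxy
    ellipse(hip$H + c(0, 20), 15, 25, 0.60)              # metaphysis proxy
    if (!is.null(hip$C))
      ellipse(hip$C, case$params$head_radius, case$params$head_radius, 0.80)
  }
  img
}

#' Write a cohort to disk (landmark JSON + manifest CSV)
#'
#' One landmark JSON per case plus `manifest.csv` with the generating
#' parameters and ground-truth grades; optionally a rendered PNG per case.
#'
#' @param cases list of `synthetic_case`.
#' @param dir output directory (created if needed).
#' @param render also write toy radiograph PNGs.
#' @return The manifest as a data.frame, invisibly.
#' @export
write_cohort <- function(cases, dir, render = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(cases), function(i) {
    case <- cases[[i]]
    id <- sprintf("case%04d", i)
    case$bundle$image_id <- id
    write_landmark_json(case$bundle, file.path(dir, paste0(id, ".json")))
    if (render)
      png::writePNG(render_image(case), file.path(dir, paste0(id, ".png")))
    p <- case$params
    do.call(rbind, lapply(c("left", "right"), function(s) data.frame(
      case_id = id, side = s,
      ai_deg = p$ai_deg[[s]], ce_deg = p$ce_deg[[s]],
      displacement_lateral = p$displacement[[s]][1],
      displacement_superior = p$displacement[[s]][2],
      noise_sigma_px = p$noise_sigma_px,
      c_visible = isTRUE(p$c_visible[[s]]),
      truth_tonnis = case$truth_grades[[s]]$tonnis,
      truth_ihdi = case$truth_grades[[s]]$ihdi,
      stringsAsFactors = FALSE)))
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
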