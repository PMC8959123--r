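# Independent oracles and fixture builders. Everything here deliberately
# avoids the package's rotation-into-frame code path: the oracles work with
# raw dot/cross products in image coordinates so they can disagree with the
# implementation if either is wrong.

# --- fixture builders ------------------------------------------------------

# symmetric bilateral landmark set: midline at mid_x, Hilgenreiner at y0
make_lmset <- function(mid_x = 300, y0 = 200, halfwidth = 100,
                       ai = 25, ce = 19, r = 20, d = 36, met = c(0, 25),
                       disp_left = c(0, 0), disp_right = c(0, 0),
                       spacing = NULL) {
  mk <- function(side, disp) {
    ls <- if (side == "left") 1 else -1
    a <- ai * pi / 180; ceg <- ce * pi / 180
    Y <- c(mid_x + ls * halfwidth, y0)
    E <- Y + c(ls * 35 * cos(a), -35 * sin(a))
    C <- E + c(-ls * d * sin(ceg), d * cos(ceg)) + c(ls * disp[1], -disp[2])
    H <- C + c(ls * met[1], met[2])
    hip_landmarks(side, E = E, Y = Y, H = H, C = C, lateral_sign = ls)
  }
  landmark_set(mk("left", disp_left), mk("right", disp_right),
               pixel_spacing_mm = spacing)
}

# --- geometric oracles (projection-based, no frame rotation) ---------------

unit_along <- function(Yl, Yr) {
  u <- Yr - Yl
  if (u[1] < 0) u <- -u
  u / sqrt(sum(u^2))
}

# angle of the roof segment against the Y-Y axis via dot/cross products
oracle_acetabular_index <- function(E, Y, Yl, Yr) {
  u <- unit_along(Yl, Yr)
  n_sup <- c(u[2], -u[1])              # superior normal (smaller y)
  v <- E - Y
  along <- abs(sum(v * u))
  perp <- sum(v * n_sup)
  atan2(abs(perp), along) * 180 / pi * sign(perp + (perp == 0))
}

oracle_ce_angle <- function(C, E, Yl, Yr, ls) {
  u <- unit_along(Yl, Yr)
  n_sup <- c(u[2], -u[1])
  w <- E - C
  lat <- ls * sum(w * u)
  sup <- sum(w * n_sup)
  atan2(lat, sup) * 180 / pi
}

oracle_ahi <- function(C, r, E, Yl, Yr, ls) {
  u <- unit_along(Yl, Yr)
  100 * (ls * sum((E - C) * u) + r) / (2 * r)
}

# --- brute-force region classifiers ---------------------------------------

# IHDI from the quadrant inequalities, via projections onto the Y-Y axis
oracle_ihdi <- function(H, E, Yl, Yr, ls) {
  u <- unit_along(Yl, Yr)
  n_sup <- c(u[2], -u[1])
  anchor <- (Yl + Yr) / 2
  junction <- anchor + sum((E - anchor) * u) * u
  l <- ls * sum((H - junction) * u)
  s <- sum((H - junction) * n_sup)
  if (l <= 0) 1L else if (l + s <= 0) 2L else if (s <= 0) 3L else 4L
}

# Toennis from the Perkin line and the rim band of half-width r around E
oracle_tonnis <- function(C, r, E, Yl, Yr, ls) {
  u <- unit_along(Yl, Yr)
  n_sup <- c(u[2], -u[1])
  l <- ls * sum((C - E) * u)
  sup <- sum((C - E) * n_sup)     # + superior to the rim level
  if (l <= 0) 1L else if (sup <= -r) 2L else if (sup < r) 3L else 4L
}

# --- statistics oracles ----------------------------------------------------

# weighted kappa as an explicit double sum over cells
oracle_weighted_kappa <- function(cm) {
  k <- nrow(cm); n <- sum(cm)
  num <- 0; den <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    w <- 1 - abs(i - j) / (k - 1)
    num <- num + w * cm[i, j] / n
    den <- den + w * sum(cm[i, ]) * sum(cm[, j]) / n^2
  }
  (num - den) / (1 - den)
}

# points sampled on a circle, for Shenton fixtures
circle_points <- function(center, radius, angles_deg) {
  a <- angles_deg * pi / 180
  cbind(center[1] + radius * cos(a), center[2] + radius * sin(a))
}

rigid_motion <- function(theta_deg, t) {
  th <- theta_deg * pi / 180
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  function(p) as.numeric(R %*% p) + t
}

apply_motion_lmset <- function(lm, f) {
  mv <- function(hip) hip_landmarks(hip$side, E = f(hip$E), Y = f(hip$Y),
                                    H = f(hip$H),
                                    C = if (is.null(hip$C)) NULL else f(hip$C),
                                    lateral_sign = hip$lateral_sign)
  landmark_set(mv(lm$left), mv(lm$right), pixel_spacing_mm = lm$pixel_spacing_mm)
}
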