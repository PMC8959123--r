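test_that("Hilgenreiner line passes through both tri-radiate centers", {
  h <- hilgenreiner_line(c(-50, 0), c(50, 0))
  expect_equal(unname(h$anchor), c(0, 0))
  expect_equal(unname(h$direction), c(1, 0))

  h2 <- hilgenreiner_line(c(0, 0), c(100, 20))
  expect_equal(unname(h2$direction), c(100, 20) / sqrt(100^2 + 20^2),
               tolerance = 1e-12)

  expect_error(hilgenreiner_line(c(5, 5), c(5, 5)), "coincident")
})

test_that("Perkin line is perpendicular to the Hilgenreiner line", {
  h <- hilgenreiner_line(c(0, 0), c(10, 0))
  p <- perkin_line(c(30, -40), h)
  expect_equal(unname(p$anchor), c(30, -40))
  expect_equal(abs(unname(p$direction)), c(0, 1))

  h45 <- line2d(c(0, 0), c(1, 1))
  p45 <- perkin_line(c(0, 0), h45)
  expect_equal(abs(sum(p45$direction * h45$direction)), 0, tolerance = 1e-12)

  set.seed(11)
  for (i in 1:50) {
    hl <- hilgenreiner_line(runif(2, -100, 100), runif(2, -100, 100))
    pk <- perkin_line(runif(2, -100, 100), hl)
    expect_lt(abs(sum(pk$direction * hl$direction)), 1e-9)
    expect_equal(sum(pk$direction^2), 1, tolerance = 1e-9)
  }
})

test_that("acetabular index matches hand values and the projection oracle", {
  h <- hilgenreiner_line(c(-100, 0), c(100, 0))
  expect_equal(acetabular_index(E = c(-30, -30), Y = c(0, 0), h), 45)
  expect_equal(acetabular_index(E = c(40, 0), Y = c(0, 0), h), 0)
  expect_error(acetabular_index(E = c(0, 0), Y = c(0, 0), h), "degenerate")

  set.seed(21)
  for (i in 1:100) {
    Yl <- runif(2, 0, 50); Yr <- Yl + c(runif(1, 50, 200), runif(1, -40, 40))
    Y <- Yr + runif(2, -5, 5); E <- Y + c(runif(1, -60, 60), runif(1, -60, 60))
    if (sqrt(sum((E - Y)^2)) < 1) next
    hl <- hilgenreiner_line(Yl, Yr)
    expect_equal(acetabular_index(E, Y, hl),
                 oracle_acetabular_index(E, Y, Yl, Yr), tolerance = 1e-9)
  }
})

test_that("center-edge angle matches hand values and the projection oracle", {
  h <- hilgenreiner_line(c(-100, 0), c(100, 0))
  expect_equal(center_edge_angle(C = c(0, 0), E = c(0, -20), h, lateral_sign = -1), 0)
  expect_equal(center_edge_angle(C = c(0, 0), E = c(-20, -20), h, lateral_sign = -1), 45)
  expect_error(center_edge_angle(C = c(1, 1), E = c(1, 1), h, 1), "degenerate")

  set.seed(22)
  for (i in 1:100) {
    Yl <- runif(2, 0, 50); Yr <- Yl + c(runif(1, 50, 200), runif(1, -40, 40))
    C <- Yr + runif(2, -40, 40); E <- C + c(runif(1, -50, 50), runif(1, -50, -5))
    ls <- sample(c(-1, 1), 1)
    hl <- hilgenreiner_line(Yl, Yr)
    expect_equal(center_edge_angle(C, E, hl, ls),
                 oracle_ce_angle(C, E, Yl, Yr, ls), tolerance = 1e-9)
  }
})

test_that("acetabular head index covers the 0/50/100 anchor cases", {
  h <- hilgenreiner_line(c(-100, 0), c(100, 0))
  C <- c(0, 30); r <- 20
  # patient-right hip displayed on image-left: lateral is -x
  expect_equal(acetabular_head_index(C, r, E = c(-20, -10), h, lateral_sign = -1), 100)
  expect_equal(acetabular_head_index(C, r, E = c(0, -10), h, lateral_sign = -1), 50)
  expect_equal(acetabular_head_index(C, r, E = c(20, -10), h, lateral_sign = -1), 0)
  expect_error(acetabular_head_index(C, 0, E = c(0, 0), h, -1), "positive")

  set.seed(23)
  for (i in 1:50) {
    Yl <- c(0, 0); Yr <- c(runif(1, 100, 200), runif(1, -30, 30))
    C <- c(runif(1, 0, 100), runif(1, 10, 60)); E <- C + runif(2, -40, 40)
    r <- runif(1, 5, 30); ls <- sample(c(-1, 1), 1)
    hl <- hilgenreiner_line(Yl, Yr)
    expect_equal(acetabular_head_index(C, r, E, hl, ls),
                 oracle_ahi(C, r, E, Yl, Yr, ls), tolerance = 1e-9)
  }
})

test_that("measure_hip reports CE angle and AHI absent when C is absent", {
  lm <- make_lmset()
  lm$left$C <- NULL
  fr <- reference_frame(lm)
  m <- measure_hip(lm$left, fr, head_radius = 20)
  expect_false(is.na(m$acetabular_index_deg))
  expect_true(is.na(m$ce_angle_deg))
  expect_true(is.na(m$ahi_percent))
  expect_identical(m$shenton, "indeterminate")
})

test_that("indices are invariant under global rigid motion", {
  lm <- make_lmset(ai = 28, ce = 15, disp_left = c(12, 5))
  base <- measure_landmark_set(lm, head_radius = list(left = 20, right = 20))
  set.seed(31)
  for (i in 1:20) {
    f <- rigid_motion(runif(1, -80, 80), runif(2, -500, 500))
    moved <- measure_landmark_set(apply_motion_lmset(lm, f),
                                  head_radius = list(left = 20, right = 20))
    for (col in c("acetabular_index_deg", "ce_angle_deg", "ahi_percent"))
      expect_equal(moved[[col]], base[[col]], tolerance = 1e-9)
    expect_identical(moved$ihdi, base$ihdi)
    expect_identical(moved$tonnis, base$tonnis)
  }
})

test_that("indices are invariant under uniform scaling and mm conversion", {
  lm <- make_lmset(ai = 30, ce = 22)
  base <- measure_landmark_set(lm, head_radius = list(left = 20, right = 20))
  for (s in c(0.25, 3)) {
    f <- function(p) p * s
    scaled <- measure_landmark_set(apply_motion_lmset(lm, f),
                                   head_radius = list(left = 20 * s, right = 20 * s))
    for (col in c("acetabular_index_deg", "ce_angle_deg", "ahi_percent"))
      expect_equal(scaled[[col]], base[[col]], tolerance = 1e-9)
  }
  with_mm <- make_lmset(ai = 30, ce = 22, spacing = 0.2)
  m2 <- measure_landmark_set(with_mm, head_radius = list(left = 20, right = 20))
  expect_equal(m2$acetabular_index_deg, base$acetabular_index_deg)
  expect_equal(m2$head_radius_mm, c(4, 4))
})

test_that("mirroring a landmark set swaps the left/right measurements", {
  lm <- make_lmset(ai = 27, ce = 12, disp_left = c(30, 10))
  mir <- reflect_landmark_set(lm, midline_x = 300)
  a <- measure_landmark_set(lm, head_radius = list(left = 20, right = 20))
  b <- measure_landmark_set(mir, head_radius = list(left = 20, right = 20))
  for (col in c("acetabular_index_deg", "ce_angle_deg", "ahi_percent")) {
    expect_equal(b[[col]][b$side == "left"], a[[col]][a$side == "right"],
                 tolerance = 1e-9)
    expect_equal(b[[col]][b$side == "right"], a[[col]][a$side == "left"],
                 tolerance = 1e-9)
  }
  expect_identical(b$ihdi, rev(a$ihdi))
  expect_identical(b$tonnis, rev(a$tonnis))
})

test_that("reference frame satisfies its angular invariants", {
  lm <- make_lmset(ai = 25, ce = 19)
  lm2 <- apply_motion_lmset(lm, rigid_motion(17, c(40, -30)))
  for (l in list(lm, lm2)) {
    fr <- reference_frame(l)
    u <- fr$hilgenreiner$direction
    for (s in c("left", "right")) {
      expect_lt(abs(sum(fr[[paste0("perkin_", s)]]$direction * u)), 1e-9)
      expect_equal(abs(sum(fr[[paste0("dline_", s)]]$direction * u)),
                   cos(pi / 4), tolerance = 1e-9)
    }
  }
})
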