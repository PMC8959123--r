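# Grading fixtures: a symmetric pelvis with midline x = 300, Hilgenreiner
# at y = 200. The right-hip (image-left, lateral_sign -1) junction sits at
# the projection of E_right onto the Hilgenreiner line.

grading_fixture <- function() {
  lm <- make_lmset()
  list(lm = lm, frame = reference_frame(lm))
}

test_that("IHDI grade follows the quadrant rules on forced cases", {
  fx <- grading_fixture()
  jr <- fx$frame$dline_right$anchor  # right-hip H-P junction
  # medial (toward midline, +x for the right hip) and inferior
  expect_equal(ihdi_grade(jr + c(20, 30), fx$frame, "right", -1)$grade, 1L)
  # superior to the Hilgenreiner line
  expect_equal(ihdi_grade(jr + c(-40, -10), fx$frame, "right", -1)$grade, 4L)
  # just lateral of the Perkin line, far inferior: medial of the D-line
  expect_equal(ihdi_grade(jr + c(-5, 80), fx$frame, "right", -1)$grade, 2L)
  # far lateral, just below the Hilgenreiner line
  expect_equal(ihdi_grade(jr + c(-80, 5), fx$frame, "right", -1)$grade, 3L)
})

test_that("points on a reference line take the lower grade and are flagged", {
  fx <- grading_fixture()
  jr <- fx$frame$dline_right$anchor
  on_perkin <- ihdi_grade(jr + c(0, 50), fx$frame, "right", -1)
  expect_equal(on_perkin$grade, 1L)
  expect_true("on_perkin" %in% on_perkin$boundary_flags)
  on_dline <- ihdi_grade(jr + c(-30, 30), fx$frame, "right", -1)
  expect_equal(on_dline$grade, 2L)
  expect_true("on_dline" %in% on_dline$boundary_flags)
  on_hline <- ihdi_grade(jr + c(-50, 0), fx$frame, "right", -1)
  expect_equal(on_hline$grade, 3L)
  expect_true("on_hline" %in% on_hline$boundary_flags)
})

test_that("IHDI grades agree with the brute-force classifier on a dense grid", {
  fx <- grading_fixture()
  lm <- fx$lm
  for (side in c("left", "right")) {
    hip <- lm[[side]]
    # fractional offsets keep grid points off the exact line equations (exact
    # ties are exercised separately by the boundary-flag tests)
    xs <- seq(hip$E[1] - 120.1237, hip$E[1] + 120, length.out = 41)
    ys <- seq(80.0721, 320, length.out = 41)
    for (x in xs) for (y in ys) {
      H <- c(x, y)
      got <- ihdi_grade(H, fx$frame, side, hip$lateral_sign)$grade
      want <- oracle_ihdi(H, hip$E, lm$left$Y, lm$right$Y, hip$lateral_sign)
      expect_identical(got, want)
    }
  }
})

test_that("Toennis grade follows the Perkin line and rim band rules", {
  fx <- grading_fixture()
  hip <- fx$lm$right; E <- hip$E; r <- 15
  # medial to the Perkin line (toward midline = +x for the right hip)
  expect_equal(tonnis_grade(E + c(10, 40), r, fx$frame, E, "right", -1)$grade, 1L)
  # lateral, well inferior to the rim band
  expect_equal(tonnis_grade(E + c(-10, 3 * r), r, fx$frame, E, "right", -1)$grade, 2L)
  # lateral, at the rim level
  expect_equal(tonnis_grade(E + c(-10, 0), r, fx$frame, E, "right", -1)$grade, 3L)
  # lateral, superior to the band by two radii
  expect_equal(tonnis_grade(E + c(-10, -2 * r), r, fx$frame, E, "right", -1)$grade, 4L)
  expect_error(tonnis_grade(E + c(-10, 0), -3, fx$frame, E, "right", -1), "positive")
})

test_that("Toennis grades agree with the brute-force classifier on a grid", {
  fx <- grading_fixture()
  lm <- fx$lm
  for (side in c("left", "right")) {
    hip <- lm[[side]]
    for (r in c(8, 20)) {
      xs <- seq(hip$E[1] - 100, hip$E[1] + 100, length.out = 29)
      ys <- seq(hip$E[2] - 80, hip$E[2] + 80, length.out = 29)
      for (x in xs) for (y in ys) {
        C <- c(x, y)
        got <- tonnis_grade(C, r, fx$frame, hip$E, side, hip$lateral_sign)$grade
        want <- oracle_tonnis(C, r, hip$E, lm$left$Y, lm$right$Y, hip$lateral_sign)
        expect_identical(got, want)
      }
    }
  }
})

test_that("grades never decrease along lateral/superior displacement rays", {
  fx <- grading_fixture()
  lm <- fx$lm
  set.seed(41)
  for (i in 1:200) {
    side <- sample(c("left", "right"), 1)
    hip <- lm[[side]]; ls <- hip$lateral_sign
    start <- hip$E + c(runif(1, -60, 60), runif(1, -20, 100))
    step <- c(ls * runif(1, 0, 4), -runif(1, 0, 4))  # lateral and superior
    ih <- tn <- integer()
    for (t in 0:25) {
      p <- start + t * step
      ih <- c(ih, ihdi_grade(p, fx$frame, side, ls)$grade)
      tn <- c(tn, tonnis_grade(p, 15, fx$frame, hip$E, side, ls)$grade)
    }
    expect_true(all(diff(ih) >= 0))
    expect_true(all(diff(tn) >= 0))
  }
})

test_that("every finite point receives exactly one grade", {
  fx <- grading_fixture()
  set.seed(42)
  pts <- cbind(runif(500, -1000, 1500), runif(500, -1000, 1500))
  for (i in seq_len(nrow(pts))) {
    g <- ihdi_grade(pts[i, ], fx$frame, "left", 1)$grade
    expect_true(g %in% 1:4)
    t <- tonnis_grade(pts[i, ], 12, fx$frame, fx$lm$left$E, "left", 1)$grade
    expect_true(t %in% 1:4)
  }
})

test_that("grading commutes with midline reflection", {
  lm <- make_lmset(disp_left = c(35, 20), disp_right = c(5, 0))
  mir <- reflect_landmark_set(lm, 300)
  a <- measure_landmark_set(lm, head_radius = list(left = 20, right = 20))
  b <- measure_landmark_set(mir, head_radius = list(left = 20, right = 20))
  expect_identical(b$ihdi, rev(a$ihdi))
  expect_identical(b$tonnis, rev(a$tonnis))
})

test_that("Shenton check accepts a continuous arc and rejects a step-off", {
  O <- c(250, 260); R <- 55
  pubic <- circle_points(O, R, seq(200, 250, length.out = 12))
  neck <- circle_points(O, R, seq(290, 330, length.out = 10))
  expect_identical(as.character(shenton_check(pubic, neck, tol = 5)), "intact")

  shifted <- sweep(neck, 2, c(0, -15), `+`)  # 3 x tol superior step
  expect_identical(as.character(shenton_check(pubic, shifted, tol = 5)), "disrupted")

  set.seed(43)
  jit <- neck + matrix(runif(length(neck), -1.25, 1.25), ncol = 2)
  res <- shenton_check(pubic, jit, tol = 5)
  expect_identical(as.character(res), "intact")
  expect_lt(attr(res, "max_residual"), 5)

  line_arc <- cbind(seq(0, 100, length.out = 8), seq(0, 50, length.out = 8))
  expect_identical(as.character(shenton_check(line_arc, neck, tol = 5)),
                   "indeterminate")
  expect_error(shenton_check(pubic, neck, tol = 0), "positive")
})

test_that("grade_hip omits the Toennis grade when C is absent", {
  lm <- make_lmset()
  lm$left$C <- NULL
  fr <- reference_frame(lm)
  g <- grade_hip(lm$left, fr, head_radius = 20)
  expect_true(is.na(g$tonnis))
  expect_true(g$ihdi %in% 1:4)
  expect_identical(g$ihdi_roman, as.character(utils::as.roman(g$ihdi)))
})
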