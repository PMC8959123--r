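# End-to-end measurement engine: gate -> reference frame -> indices ->
# grades, for one bundle or a whole cohort.

#' Measure and grade a detection bundle
#'
#' Runs the full engine on one bundle: applies the segmentation gate (so
#' untrusted C points are removed first), derives per-side head radii from
#' the femoral-head ROIs, and measures and grades both hips. Hips whose C
#' was suppressed report an absent CE angle, AHI and Toennis grade.
#'
#' @param bundle a `detection_bundle`.
#' @param suppress apply the segmentation gate (default `TRUE`).
#' @param conf_threshold,mode passed to [suppress_point_c()].
#' @param shenton_tol Shenton continuity tolerance in pixels.
#' @return data.frame with one row per hip: all measurement fields, grades,
#'   `head_radius_px`, `suppressed_c`, and `image_id`.
#' @export
measure_bundle <- function(bundle, suppress = TRUE, conf_threshold = 0.5,
                           mode = c("per_side", "global"), shenton_tol = 5) {
  validate_bundle(bundle)
  mode <- match.arg(mode)
  if (suppress) bundle <- gate_bundle(bundle, conf_threshold, mode)
  radii <- lapply(c(left = "left", right = "right"), function(s) {
    roi <- roi_for_side(bundle, s, conf_threshold)
    if (is.null(roi)) NULL else head_radius_from_roi(roi)
  })
  shenton <- if (is.null(bundle$contours)) list() else bundle$contours
  out <- measure_landmark_set(bundle$landmarks, head_radius = radii,
                              shenton = shenton, shenton_tol = shenton_tol)
  out$suppressed_c <- vapply(out$side, function(s)
    any(grepl(paste0("suppressed C on ", s), bundle$suppression_log)), logical(1))
  out$image_id <- if (is.null(bundle$image_id)) NA_character_ else bundle$image_id
  out
}

#' Measure a cohort of synthetic cases or bundles
#'
#' @param cases list of `synthetic_case` or `detection_bundle` objects.
#' @param ... passed to [measure_bundle()].
#' @return data.frame with a `case` index column plus the per-hip rows of
#'   [measure_bundle()].
#' @export
measure_cohort <- function(cases, ...) {
  rows <- lapply(seq_along(cases), function(i) {
    b <- cases[[i]]
    if (inherits(b, "synthetic_case")) b <- b$bundle
    df <- measure_bundle(b, ...)
    df$case <- i
    df
  })
  do.call(rbind, rows)
}

#' Test-retest reliability of repeated measurement runs
#'
#' Assembles the subjects x runs matrix for a numeric indicator from two or
#' more cohort reports (same cases, same order) and computes Cronbach's
#' alpha. Subjects are case-hip pairs; hips with the indicator absent in any
#' run are dropped.
#'
#' @param runs list of data.frames from [measure_cohort()].
#' @param indicator column name, e.g. `"acetabular_index_deg"` or
#'   `"ce_angle_deg"`.
#' @return List with `alpha`, `n_subjects`, `interpretation`.
#' @export
test_retest_alpha <- function(runs, indicator = "acetabular_index_deg") {
  if (length(runs) < 2L) stop("need at least two runs")
  m <- vapply(runs, function(df) df[[indicator]], numeric(nrow(runs[[1]])))
  keep <- stats::complete.cases(m)
  a <- cronbach_alpha(m[keep, , drop = FALSE])
  list(alpha = a, n_subjects = sum(keep), interpretation = interpret_alpha(a))
}
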