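# Validation machinery: landmark error, reliability coefficients, agreement
# statistics and confusion-matrix metrics.

#' Per-landmark mean Euclidean distance error (MDE)
#'
#' Compares predicted landmark sets against ground truth, case by case, and
#' reports the arithmetic mean Euclidean distance per named landmark per
#' side (4 landmarks x 2 sides). A landmark present in the truth but absent
#' in the prediction is a miss: it is excluded from the mean and counted
#' separately.
#'
#' @param truth,pred equal-length, aligned lists of `landmark_set`.
#' @return data.frame with columns `landmark`, `side`, `mde`, `n`, `misses`.
#' @export
mean_distance_error <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("truth and pred must have equal length")
  rows <- list()
  for (s in c("left", "right")) {
    for (nm in c("E", "Y", "C", "H")) {
      d <- c(); misses <- 0L
      for (i in seq_along(truth)) {
        tp <- truth[[i]][[s]][[nm]]; pp <- pred[[i]][[s]][[nm]]
        if (is.null(tp)) next
        if (is.null(pp)) { misses <- misses + 1L; next }
        d <- c(d, sqrt(sum((tp - pp)^2)))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        landmark = nm, side = s,
        mde = if (length(d)) mean(d) else NA_real_,
        n = length(d), misses = misses, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability of a subjects x raters matrix:
#' `alpha = k/(k-1) * (1 - sum(var_i) / var_total)` with `k` raters,
#' `var_i` the sample variance of rater `i` across subjects and `var_total`
#' the sample variance of the per-subject rater sums (denominator `n - 1`
#' throughout). Values at or above 0.75 are conventionally considered
#' satisfactory for this kind of measurement reliability.
#'
#' @param m numeric matrix, subjects in rows, raters (or repeated runs) in
#'   columns; at least 2 of each, no missing cells.
#' @return The alpha coefficient; `NA` with a warning when the total
#'   variance is zero (all subjects identical).
#' @export
cronbach_alpha <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L || nrow(m) < 2L) stop("need at least 2 raters and 2 subjects")
  if (anyNA(m)) stop("missing cells are not allowed")
  vt <- stats::var(rowSums(m))
  if (vt < .Machine$double.eps) {
    warning("zero total variance: alpha undefined")
    return(NA_real_)
  }
  k <- ncol(m)
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / vt)
}

#' @rdname cronbach_alpha
#' @param alpha an alpha coefficient.
#' @return `interpret_alpha()`: `"satisfactory"` when `alpha >= 0.75`, else
#'   `"unsatisfactory"`.
#' @export
interpret_alpha <- function(alpha) {
  if (!is.finite(alpha)) return(NA_character_)
  if (alpha >= 0.75) "satisfactory" else "unsatisfactory"
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measures ICC. Provided
#' as a clearly labeled alternative to [cronbach_alpha()]; the package's
#' reliability reports use alpha by default.
#'
#' @param m numeric matrix, subjects in rows, raters in columns.
#' @return The ICC(2,1) coefficient.
#' @export
icc2_1 <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("need at least 2 raters and 2 subjects")
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((m - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Build a confusion matrix from paired labels
#'
#' @param reference,prediction equal-length vectors of category labels.
#' @param labels category order (ordered for graded scales); defaults to the
#'   sorted union of observed labels.
#' @return k x k integer matrix of counts, reference in rows, prediction in
#'   columns.
#' @export
confusion_matrix <- function(reference, prediction, labels = NULL) {
  if (length(reference) != length(prediction)) stop("length mismatch")
  if (is.null(labels)) labels <- sort(unique(c(reference, prediction)))
  unclass(table(factor(reference, levels = labels),
                factor(prediction, levels = labels)))
}

check_square <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  if (any(cm < 0) || sum(cm) <= 0) stop("confusion matrix needs nonnegative counts, total > 0")
  cm
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with
#' `p_o = trace/N` and `p_e = sum(row_i * col_i) / N^2`.
#'
#' @param cm square confusion matrix of counts.
#' @return The kappa coefficient; `NA` with a warning when `p_e = 1` (all
#'   mass in a single category).
#' @export
cohen_kappa <- function(cm) {
  cm <- check_square(cm)
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - pe) < .Machine$double.eps) {
    warning("degenerate single-category table: kappa undefined")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Linearly weighted kappa
#'
#' Weighted kappa for ordered categories with linear agreement weights
#' `w_ij = 1 - |i - j| / (k - 1)` applied to both the observed and the
#' chance-expected proportions. For k = 2 it equals Cohen's kappa.
#'
#' @param cm square confusion matrix of counts over ordered categories.
#' @return The weighted kappa coefficient.
#' @export
weighted_linear_kappa <- function(cm) {
  cm <- check_square(cm)
  k <- nrow(cm); n <- sum(cm)
  idx <- seq_len(k)
  w <- 1 - abs(outer(idx, idx, `-`)) / (k - 1)
  p <- cm / n
  pe <- outer(rowSums(cm), colSums(cm)) / n^2
  po_w <- sum(w * p); pe_w <- sum(w * pe)
  if (abs(1 - pe_w) < .Machine$double.eps) {
    warning("degenerate table: weighted kappa undefined")
    return(NA_real_)
  }
  (po_w - pe_w) / (1 - pe_w)
}

#' Kappa interpretation bands
#'
#' `kappa <= 0.40`: poor-to-slight agreement; `0.40 < kappa <= 0.75`:
#' moderate; `kappa > 0.75`: perfect.
#'
#' @param value kappa in \[-1, 1\].
#' @return One of `"poor_to_slight"`, `"moderate"`, `"perfect"`.
#' @export
interpret_kappa <- function(value) {
  if (!is.finite(value) || value < -1 || value > 1)
    stop("kappa must lie in [-1, 1]")
  if (value <= 0.40) "poor_to_slight"
  else if (value <= 0.75) "moderate"
  else "perfect"
}

#' Binary classification metrics from a 2x2 table
#'
#' @param cm 2x2 confusion matrix, reference in rows, prediction in columns.
#' @param positive index (1 or 2) or row name of the positive class.
#' @return List with `accuracy`, `sensitivity`, `specificity`,
#'   `missed_diagnosis_rate` (= 1 - sensitivity). Components with an empty
#'   margin are `NA` with a warning.
#' @export
binary_metrics <- function(cm, positive = 1) {
  cm <- check_square(cm)
  if (nrow(cm) != 2L) stop("binary_metrics needs a 2x2 table")
  if (is.character(positive)) positive <- match(positive, rownames(cm))
  if (!positive %in% 1:2) stop("positive class not found")
  neg <- 3L - positive
  tp <- cm[positive, positive]; fn <- cm[positive, neg]
  tn <- cm[neg, neg]; fp <- cm[neg, positive]
  sens <- if (tp + fn > 0) tp / (tp + fn) else { warning("empty positive margin"); NA_real_ }
  spec <- if (tn + fp > 0) tn / (tn + fp) else { warning("empty negative margin"); NA_real_ }
  list(accuracy = (tp + tn) / sum(cm),
       sensitivity = sens, specificity = spec,
       missed_diagnosis_rate = 1 - sens)
}
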