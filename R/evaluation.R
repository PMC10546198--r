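#' Confusion counts at a decision threshold
#'
#' Plus is the positive class; a probability at or above the threshold
#' predicts plus.
#'
#' @param probs Predicted plus-probabilities.
#' @param labels True labels (`no_plus`/`plus` factor, strings, or 0/1).
#' @param threshold Decision threshold (default 0.5, as used for the
#'   reported accuracy/sensitivity/specificity).
#' @return A `confusion_counts` tibble row: `tp`, `fp`, `tn`, `fn`,
#'   `threshold`.
#' @export
confusion_counts <- function(probs, labels, threshold = 0.5) {
  if (length(probs) == 0)
    abort("Empty input.", class = "fundusplus_parameter_error")
  if (length(probs) != length(labels))
    abort("probs and labels differ in length.",
          class = "fundusplus_validation_error")
  y <- if (is.numeric(labels) && all(labels %in% c(0, 1))) as.integer(labels)
       else label_to_y(labels)
  pred <- as.integer(probs >= threshold)
  out <- tibble::tibble(
    tp = sum(pred == 1 & y == 1), fp = sum(pred == 1 & y == 0),
    tn = sum(pred == 0 & y == 0), fn = sum(pred == 0 & y == 1),
    threshold = threshold
  )
  class(out) <- c("confusion_counts", class(out))
  out
}

#' Metrics from a confusion matrix
#'
#' Standard definitions: accuracy `(tp+tn)/n`, sensitivity (= recall)
#' `tp/(tp+fn)`, specificity `tn/(tn+fp)`, precision `tp/(tp+fp)`,
#' `F1 = 2*precision*recall/(precision+recall)`. A ratio with a zero
#' denominator is reported as `NA` (undefined), never silently as 0.
#'
#' @param counts A `confusion_counts` row, or a list/row with `tp`, `fp`,
#'   `tn`, `fn`.
#' @return One-row tibble: `accuracy`, `sensitivity`, `specificity`,
#'   `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  n <- tp + fp + tn + fn
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- safe(tp, tp + fn)
  prec <- safe(tp, tp + fp)
  f1 <- if (!is.na(prec) && !is.na(sens) && (prec + sens) > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  tibble::tibble(
    accuracy = safe(tp + tn, n), sensitivity = sens,
    specificity = safe(tn, tn + fp), precision = prec, recall = sens, f1 = f1
  )
}

#' Empirical ROC curve
#'
#' Step curve over all observed score thresholds with equal scores grouped
#' (ties move diagonally); AUC by the trapezoidal rule, which equals the
#' Mann-Whitney pair-counting statistic with ties counted one half.
#'
#' @param scores Classifier scores (higher = more plus-like).
#' @param labels True labels (factor/strings/0-1).
#' @return A `roc_curve` object: tibble of `(fpr, tpr, threshold)` points
#'   from (0,0) to (1,1), `auc`, and `method = "empirical"`.
#' @export
roc_empirical <- function(scores, labels) {
  y <- if (is.numeric(labels) && all(labels %in% c(0, 1))) as.integer(labels)
       else label_to_y(labels)
  npos <- sum(y == 1); nneg <- sum(y == 0)
  if (npos == 0 || nneg == 0)
    abort("Both classes must be present for a ROC curve.",
          class = "fundusplus_parameter_error")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  grp <- cumsum(!duplicated(s))
  tp <- as.numeric(tapply(yy == 1, grp, sum))
  fp <- as.numeric(tapply(yy == 0, grp, sum))
  tpr <- c(0, cumsum(tp) / npos)
  fpr <- c(0, cumsum(fp) / nneg)
  thr <- c(Inf, unname(unique(s)))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(points = tibble::tibble(fpr = fpr, tpr = tpr, threshold = thr),
                 auc = auc, method = "empirical", n_pos = npos, n_neg = nneg),
            class = "roc_curve")
}

#' Binormal (parametric) ROC curve
#'
#' Fits class-conditional normal distributions to the scores and derives
#' the parametric ROC; the area is the closed form
#' `AUC = pnorm((mu1 - mu0) / sqrt(sd0^2 + sd1^2))`. Bounded probability
#' scores are first mapped to an unbounded scale with the probit transform
#' (`transform = "probit"`, the default); pass `"none"` for scores already
#' on an unbounded scale.
#'
#' @inheritParams roc_empirical
#' @param transform `"probit"` or `"none"`.
#' @param n_grid Number of threshold grid points for the curve.
#' @return A `roc_curve` object with `method = "binormal"` and the fitted
#'   `mu0`, `mu1`, `sd0`, `sd1`.
#' @export
roc_binormal <- function(scores, labels, transform = c("probit", "none"),
                         n_grid = 512) {
  transform <- match.arg(transform)
  y <- if (is.numeric(labels) && all(labels %in% c(0, 1))) as.integer(labels)
       else label_to_y(labels)
  if (sum(y == 1) < 2 || sum(y == 0) < 2)
    abort("Each class needs >= 2 samples for the binormal fit.",
          class = "fundusplus_parameter_error")
  s <- scores
  if (transform == "probit") s <- qnorm(pmin(1 - 1e-7, pmax(1e-7, s)))
  mu0 <- mean(s[y == 0]); mu1 <- mean(s[y == 1])
  sd0 <- sd(s[y == 0]); sd1 <- sd(s[y == 1])
  if (sd0 < .Machine$double.eps || sd1 < .Machine$double.eps)
    abort("Zero within-class score variance: binormal ROC undefined.",
          class = "fundusplus_degenerate_error")
  auc <- pnorm((mu1 - mu0) / sqrt(sd0^2 + sd1^2))
  lo <- min(mu0 - 5 * sd0, mu1 - 5 * sd1)
  hi <- max(mu0 + 5 * sd0, mu1 + 5 * sd1)
  t <- seq(hi, lo, length.out = n_grid)
  pts <- tibble::tibble(
    fpr = c(0, 1 - pnorm((t - mu0) / sd0), 1),
    tpr = c(0, 1 - pnorm((t - mu1) / sd1), 1),
    threshold = c(Inf, t, -Inf)
  )
  structure(list(points = pts, auc = auc, method = "binormal",
                 mu0 = mu0, mu1 = mu1, sd0 = sd0, sd1 = sd1,
                 n_pos = sum(y == 1), n_neg = sum(y == 0)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %s AUC = %.4f (%d pos / %d neg)\n",
              x$method, x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Real-world dollar cost per sample
#'
#' `(w_fn * FN + w_fp * FP) / n`: the average per-screened-infant cost of
#' classification errors under the chosen dollar weights.
#'
#' @param counts A `confusion_counts` row.
#' @param w A [cost_weights()].
#' @return Dollars per sample (scalar).
#' @export
real_world_cost <- function(counts, w = cost_weights()) {
  n <- counts$tp + counts$fp + counts$tn + counts$fn
  if (n == 0) abort("Empty confusion matrix.", class = "fundusplus_parameter_error")
  (w$w_fn * counts$fn + w$w_fp * counts$fp) / n
}

#' Cohort misdiagnosis projection
#'
#' Scales the average per-fold false-negative count to a screening cohort:
#' `round_half_up(cohort_size * prevalence * avg_fn / fold_plus_count)`
#' infants with plus disease that would be missed. With test
#' folds holding 11 plus cases each, a cohort of 1000 at 12.5% prevalence and an
#' average of 3.3 false negatives gives 38 missed infants; 2.65 gives 30.
#'
#' @param cohort_size Number of infants screened.
#' @param prevalence Plus-disease prevalence (fraction in (0, 1)).
#' @param fold_plus_count Plus cases per test fold (default 11: 55 cases
#'   stratified over 5 folds).
#' @param avg_fn Mean false negatives per test fold.
#' @return Projected count of misdiagnosed infants (integer-valued,
#'   half-up rounding).
#' @export
cohort_projection <- function(cohort_size, prevalence, fold_plus_count = 11,
                              avg_fn) {
  if (!(prevalence > 0 && prevalence < 1))
    abort("prevalence must be in (0, 1).", class = "fundusplus_parameter_error")
  if (fold_plus_count <= 0)
    abort("fold_plus_count must be > 0.", class = "fundusplus_parameter_error")
  round_half_up(cohort_size * prevalence * avg_fn / fold_plus_count)
}

#' Dollar impact of reduced misdiagnoses
#'
#' `(n1 - n2) * w_fn`: the saving from lowering the number of missed cases
#' from `n1` to `n2` at a false-negative cost of `w_fn` dollars.
#'
#' @param n1,n2 Misdiagnosed counts (`n1 >= n2`).
#' @param w_fn Dollar cost of one false negative.
#' @return Dollars (scalar).
#' @export
cost_delta <- function(n1, n2, w_fn = 1700000) {
  if (n1 < n2) abort("n1 must be >= n2.", class = "fundusplus_parameter_error")
  (n1 - n2) * w_fn
}

#' Vertically averaged cross-validation ROC
#'
#' Averages several empirical ROC curves by interpolating each curve's TPR
#' on a common FPR grid and reporting the mean and standard deviation per
#' grid point (the usual way fold-wise ROC curves are pooled).
#'
#' @param rocs List of `roc_curve` objects.
#' @param grid FPR grid.
#' @return Tibble with `fpr`, `tpr_mean`, `tpr_sd`, plus mean AUC as
#'   attribute `auc_mean`.
#' @export
roc_average <- function(rocs, grid = seq(0, 1, by = 0.01)) {
  tprs <- vapply(rocs, function(r) {
    stats::approx(r$points$fpr, r$points$tpr, xout = grid, ties = max,
                  yleft = 0, yright = 1)$y
  }, numeric(length(grid)))
  tibble::tibble(fpr = grid,
                 tpr_mean = rowMeans(tprs),
                 tpr_sd = apply(tprs, 1, sd)) |>
    structure(auc_mean = mean(vapply(rocs, `[[`, numeric(1), "auc")))
}
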