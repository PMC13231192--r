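# Patient-level discrimination and operating-point metrics.

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' Equals the probability that a randomly chosen positive outscores a
#' randomly chosen negative, with ties credited 1/2 (midranks). Invariant
#' under strictly monotone transforms of the scores.
#'
#' @param scores numeric vector of malignancy scores.
#' @param labels binary vector (1 = positive), same length.
#' @return AUROC in `[0, 1]`.
#' @export
#' @examples
#' auroc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))  # 0.75
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUROC undefined: both classes must be present")
  r <- rank(scores)                           # midranks
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (step summation)
#'
#' Non-interpolated step-wise summation `sum_k (R_k - R_{k-1}) * P_k` over
#' descending distinct score thresholds (ties enter together), which avoids
#' the optimistic bias of trapezoidal PR interpolation.
#'
#' @inheritParams auroc
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1)
  if (n_pos == 0L) stop("AUPRC undefined: no positive labels")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  keep <- c(s[-1] != s[-length(s)], TRUE)     # last index of each tie group
  tp <- cumsum(y)[keep]
  fp <- cumsum(1 - y)[keep]
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Sensitivity, specificity, PPV and NPV at an operating point
#'
#' A bag is called positive when its score is at or above `threshold`.
#' Ratios with a zero denominator are reported as `NA` with the
#' corresponding `*_defined` flag set to `FALSE`, never silently as 0.
#'
#' @inheritParams auroc
#' @param threshold operating point on the score scale.
#' @return A one-row tibble: `threshold`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`, their `*_defined` flags, and the 2x2 counts.
#' @export
operating_point_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2L)
    stop("operating-point metrics need both classes present")
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0); fp <- sum(pred == 1 & labels == 0)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble::tibble(
    threshold = threshold,
    sensitivity = safe(tp, tp + fn), specificity = safe(tn, tn + fp),
    ppv = safe(tp, tp + fp), npv = safe(tn, tn + fn),
    ppv_defined = tp + fp > 0, npv_defined = tn + fn > 0,
    tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Full per-fold metrics report
#'
#' @inheritParams operating_point_metrics
#' @param fold_index optional fold identifier column.
#' @return A one-row tibble with `auroc`, `auprc`, the operating-point
#'   metrics, `n_pos`, `n_neg` and `fold_index`.
#' @export
metrics_report <- function(scores, labels, threshold = 0.5,
                           fold_index = NA_integer_) {
  op <- operating_point_metrics(scores, labels, threshold)
  tibble::tibble(
    fold_index = fold_index,
    auroc = auroc(scores, labels), auprc = auprc(scores, labels),
    sensitivity = op$sensitivity, specificity = op$specificity,
    ppv = op$ppv, npv = op$npv, threshold = threshold,
    n_pos = sum(labels == 1), n_neg = sum(labels == 0))
}

#' Summarise per-fold metric reports as mean and standard deviation
#'
#' @param reports tibble of per-fold rows from [metrics_report()] (or any
#'   tibble of numeric metric columns).
#' @param metrics columns to summarise.
#' @return Tibble with `metric`, `mean`, `sd` (sample sd, `n - 1`
#'   denominator; `NA` when fewer than 2 folds) and `n_folds`.
#' @export
#' @examples
#' summarize_folds(tibble::tibble(auroc = c(0.7, 0.8)))
summarize_folds <- function(reports,
                            metrics = intersect(c("auroc", "auprc",
                                                  "sensitivity", "specificity",
                                                  "ppv", "npv"),
                                                names(reports))) {
  n <- nrow(reports)
  purrr::map_dfr(metrics, function(m) {
    v <- reports[[m]]
    tibble::tibble(metric = m, mean = mean(v, na.rm = TRUE),
                   sd = if (n >= 2L) stats::sd(v) else NA_real_,
                   n_folds = n)
  })
}

#' Youden-optimal threshold on a validation set
#'
#' Optional alternative to the default 0.5 operating point: the threshold
#' maximising sensitivity + specificity - 1 over the observed scores
#' (earliest maximiser on ties).
#'
#' @inheritParams auroc
#' @return A scalar threshold.
#' @export
youden_threshold <- function(scores, labels) {
  cand <- sort(unique(scores))
  j <- vapply(cand, function(t) {
    op <- operating_point_metrics(scores, labels, t)
    op$sensitivity + op$specificity - 1
  }, numeric(1))
  cand[which.max(j)]
}
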