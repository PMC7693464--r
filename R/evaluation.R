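# Evaluation stack: confusion counts, identification-rate metrics, fold
# aggregation, pooled ROC/AUC with DeLong confidence intervals, and the
# stepwise (Ryan) multiple comparison of network accuracies.
#
# Convention throughout: rest = negative class, clench = positive class.

#' Confusion counts from a prediction set
#'
#' @param preds data.frame with columns `label` and `pred`, both in
#'   `c("rest", "clench")`.
#' @return an object of class `confusion_counts`: named integer vector
#'   `TN`, `FP`, `FN`, `TP`.
#' @export
confusion_counts <- function(preds) {
  lv <- c("rest", "clench")
  if (!all(preds$label %in% lv) || !all(preds$pred %in% lv)) {
    nc_stop("labels and predictions must be rest/clench", "nc_input_error")
  }
  tn <- sum(preds$label == "rest" & preds$pred == "rest")
  fp <- sum(preds$label == "rest" & preds$pred == "clench")
  fn <- sum(preds$label == "clench" & preds$pred == "rest")
  tp <- sum(preds$label == "clench" & preds$pred == "clench")
  structure(c(TN = tn, FP = fp, FN = fn, TP = tp),
            class = "confusion_counts")
}

#' Identification-rate metrics from confusion counts
#'
#' Accuracy = (TN+TP)/(TN+TP+FN+FP); Recall = TP/(TP+FN);
#' Specificity = TN/(FP+TN); Precision = TP/(FP+TP);
#' F-value = 2*Recall*Precision/(Recall+Precision). Metrics whose denominator
#' is zero are returned as `NA` and flagged in the `undefined` attribute —
#' never silently reported as 0.
#'
#' @param cc a [confusion_counts()] (or named vector with TN/FP/FN/TP).
#' @return an object of class `metric_set`: named numeric vector (proportions
#'   in `[0, 1]`) with elements `accuracy`, `recall`, `specificity`,
#'   `precision`, `f_value`; attribute `undefined` names any flagged metric.
#' @export
compute_metrics <- function(cc) {
  tn <- cc[["TN"]]; fp <- cc[["FP"]]; fn <- cc[["FN"]]; tp <- cc[["TP"]]
  total <- tn + fp + fn + tp
  if (total == 0) nc_stop("empty confusion table", "nc_input_error")
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  acc <- safe_div(tn + tp, total)
  rec <- safe_div(tp, tp + fn)
  spc <- safe_div(tn, fp + tn)
  prc <- safe_div(tp, fp + tp)
  f <- if (is.na(rec) || is.na(prc) || rec + prc == 0) NA_real_ else
    2 * rec * prc / (rec + prc)
  out <- c(accuracy = acc, recall = rec, specificity = spc, precision = prc,
           f_value = f)
  structure(out, undefined = names(out)[is.na(out)], class = "metric_set")
}

#' F-value from recall and precision
#'
#' Harmonic mean of recall and precision; accepts percent or proportion scale
#' (both arguments must be on the same scale).
#'
#' @param recall,precision numeric, percent (0-100) or proportion (0-1).
#' @return F-value as a proportion in `[0, 1]`.
#' @export
f_value <- function(recall, precision) {
  if (any(recall > 1) || any(precision > 1)) {
    recall <- recall / 100
    precision <- precision / 100
  }
  2 * recall * precision / (recall + precision)
}

#' Aggregate per-fold metrics into macro mean and SD
#'
#' Unweighted (macro) mean over folds with the sample SD (n-1 denominator).
#'
#' @param metric_list list of `metric_set` objects (>= 2 folds).
#' @return data.frame with columns `metric`, `mean`, `sd`.
#' @export
aggregate_folds <- function(metric_list) {
  if (length(metric_list) < 2) nc_stop("need >= 2 folds", "nc_input_error")
  m <- do.call(rbind, lapply(metric_list, unclass))
  data.frame(metric = colnames(m),
             mean = colMeans(m),
             sd = apply(m, 2, stats::sd),
             row.names = NULL)
}

#' Pooled (micro) accuracy of a prediction set
#'
#' @param preds data.frame with `label` and `pred` columns.
#' @return proportion correct.
#' @export
pooled_accuracy <- function(preds) mean(preds$pred == preds$label)

#' Empirical ROC curve and AUC with DeLong confidence interval
#'
#' Sweeps all score thresholds (clench = positive); AUC by the trapezoidal
#' rule, which equals the normalized Mann-Whitney U statistic. The 95 percent
#' CI and the two-sided p-value against AUC = 0.5 use DeLong's placement
#' variance estimator.
#'
#' @param labels character vector in `c("rest", "clench")`.
#' @param scores clench-class scores in `[0, 1]`.
#' @param conf confidence level (default 0.95).
#' @return an object of class `roc_result`: `points` (data.frame `threshold`,
#'   `fpr`, `tpr`, from (0,0) to (1,1)), `auc`, `ci` (length 2), `se`,
#'   `p_value`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(labels, scores, conf = 0.95) {
  pos <- scores[labels == "clench"]
  neg <- scores[labels == "rest"]
  m <- length(pos); n <- length(neg)
  if (m == 0 || n == 0) nc_stop("both classes must be present",
                                "nc_roc_error")
  # curve: thresholds descending; predict positive when score >= threshold
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(neg >= t), numeric(1))
  points <- data.frame(threshold = c(Inf, th, -Inf),
                       fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  # AUC via midranks (ties counted 1/2)
  r <- rank(c(pos, neg))
  auc <- (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  # DeLong placements
  v10 <- (rank(c(pos, neg))[seq_len(m)] - rank(pos)) / n
  v01 <- 1 - (rank(c(neg, pos))[seq_len(n)] - rank(neg)) / m
  s10 <- if (m > 1) stats::var(v10) else 0
  s01 <- if (n > 1) stats::var(v01) else 0
  se <- sqrt(s10 / m + s01 / n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- c(max(0, auc - z * se), min(1, auc + z * se))
  p <- if (se == 0) if (auc == 0.5) 1 else 0 else
    2 * stats::pnorm(-abs((auc - 0.5) / se))
  structure(list(points = points, auc = auc, ci = ci, se = se, p_value = p,
                 n_pos = m, n_neg = n),
            class = "roc_result")
}

#' Stepwise (Ryan) multiple comparison of network accuracies
#'
#' All pairwise two-proportion chi-square tests among k networks, judged at
#' the stepwise-adjusted level `alpha' = 2*alpha / (k * m)`, where m is the
#' number of rank-ordered proportions spanned by the pair. Stepwise
#' protection: a pair inside a span already declared non-significant is not
#' declared significant.
#'
#' @param correct integer vector of correctly identified counts.
#' @param total integer vector of totals.
#' @param names network names (default `net1..netk`).
#' @param alpha familywise level (default 0.05).
#' @param continuity logical, continuity correction in the chi-square test
#'   (default FALSE).
#' @return data.frame, one row per pair: `a`, `b`, `prop_a`, `prop_b`, `span`,
#'   `p_raw`, `alpha_adj`, `significant`.
#' @export
ryan_compare <- function(correct, total, names = NULL, alpha = 0.05,
                         continuity = FALSE) {
  k <- length(correct)
  if (k < 2 || length(total) != k) nc_stop("need >= 2 networks",
                                           "nc_input_error")
  if (any(total <= 0) || any(correct > total) || any(correct < 0)) {
    nc_stop("invalid correct/total counts", "nc_input_error")
  }
  names <- names %||% paste0("net", seq_len(k))
  p_hat <- correct / total
  ord <- order(p_hat, decreasing = TRUE)   # rank 1 = largest proportion
  rank_of <- match(seq_len(k), ord)

  pairs <- utils::combn(k, 2)
  res <- data.frame(a = names[pairs[1, ]], b = names[pairs[2, ]],
                    prop_a = p_hat[pairs[1, ]], prop_b = p_hat[pairs[2, ]],
                    span = abs(rank_of[pairs[1, ]] - rank_of[pairs[2, ]]) + 1L,
                    p_raw = NA_real_, alpha_adj = NA_real_,
                    significant = NA)
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    pt <- suppressWarnings(
      stats::prop.test(c(correct[i1], correct[i2]), c(total[i1], total[i2]),
                       correct = continuity))
    res$p_raw[j] <- pt$p.value
    res$alpha_adj[j] <- 2 * alpha / (k * res$span[j])
  }
  # stepwise: widest spans first; a non-significant span blocks nested pairs
  res$significant <- res$p_raw < res$alpha_adj
  for (j in order(res$span, decreasing = TRUE)) {
    if (!res$significant[j]) {
      lo <- min(rank_of[match(c(res$a[j], res$b[j]), names)])
      hi <- max(rank_of[match(c(res$a[j], res$b[j]), names)])
      inside <- vapply(seq_len(nrow(res)), function(jj) {
        r <- rank_of[match(c(res$a[jj], res$b[jj]), names)]
        min(r) >= lo && max(r) <= hi
      }, logical(1))
      res$significant[inside] <- FALSE
    }
  }
  res
}
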