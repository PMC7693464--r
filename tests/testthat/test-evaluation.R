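# Confusion counts, metric formulas, fold aggregation, ROC/AUC, Ryan
# comparison.

test_that("confusion counts follow the rest=negative / clench=positive convention", {
  all_right <- data.frame(label = rep(c("rest", "clench"), each = 10),
                          pred = rep(c("rest", "clench"), each = 10))
  cc <- confusion_counts(all_right)
  expect_equal(unclass(cc), c(TN = 10L, FP = 0L, FN = 0L, TP = 10L),
               ignore_attr = TRUE)
  all_clench <- data.frame(label = rep(c("rest", "clench"), each = 10),
                           pred = "clench")
  cc2 <- confusion_counts(all_clench)
  expect_equal(cc2[["FP"]], 10L)
  expect_equal(cc2[["TP"]], 10L)
  # brute-force tally of a 20-row toy set
  set.seed(2)
  toy <- data.frame(label = c(rep("rest", 10), rep("clench", 10)),
                    pred = c(rep("rest", 8), rep("clench", 2),
                             rep("rest", 1), rep("clench", 9)))
  cc3 <- confusion_counts(toy)
  manual <- c(TN = 0L, FP = 0L, FN = 0L, TP = 0L)
  for (i in seq_len(20)) {
    key <- if (toy$label[i] == "rest") {
      if (toy$pred[i] == "rest") "TN" else "FP"
    } else {
      if (toy$pred[i] == "rest") "FN" else "TP"
    }
    manual[key] <- manual[key] + 1L
  }
  expect_equal(unclass(cc3), manual, ignore_attr = TRUE)
})

test_that("the five identification-rate formulas evaluate exactly", {
  m <- compute_metrics(c(TN = 8L, FP = 2L, FN = 1L, TP = 9L))
  expect_equal(m[["accuracy"]], 17 / 20)
  expect_equal(m[["recall"]], 9 / 10)
  expect_equal(m[["specificity"]], 8 / 10)
  expect_equal(m[["precision"]], 9 / 11)
  expect_equal(m[["f_value"]], 2 * (9 / 10) * (9 / 11) / (9 / 10 + 9 / 11))
  expect_equal(round(100 * m[["accuracy"]], 1), 85.0)
  expect_equal(round(100 * m[["precision"]], 1), 81.8)
  expect_equal(round(m[["f_value"]], 3), 0.857)
  # symmetric table: everything 50%
  sym <- compute_metrics(c(TN = 5L, FP = 5L, FN = 5L, TP = 5L))
  expect_equal(unname(unclass(sym)[1:4]), rep(0.5, 4))
  # zero denominators flagged, not zeroed
  und <- compute_metrics(c(TN = 10L, FP = 0L, FN = 0L, TP = 0L))
  expect_true(is.na(und[["recall"]]))
  expect_true("recall" %in% attr(und, "undefined"))
  expect_error(compute_metrics(c(TN = 0L, FP = 0L, FN = 0L, TP = 0L)),
               class = "nc_input_error")
})

test_that("fold aggregation is macro mean with sample SD", {
  ms <- lapply(c(0.78, 0.844, 0.881, 0.984, 0.853), function(a) {
    structure(c(accuracy = a, recall = a, specificity = a, precision = a,
                f_value = a), class = "metric_set")
  })
  agg <- aggregate_folds(ms)
  acc <- agg[agg$metric == "accuracy", ]
  expect_equal(acc$mean, mean(c(0.78, 0.844, 0.881, 0.984, 0.853)))
  expect_equal(acc$sd, stats::sd(c(0.78, 0.844, 0.881, 0.984, 0.853)))
  # identical folds -> SD 0
  agg0 <- aggregate_folds(ms[c(1, 1)])
  expect_equal(agg0$sd, rep(0, 5))
  expect_error(aggregate_folds(ms[1]), class = "nc_input_error")
})

test_that("AUC equals the brute-force pairwise statistic", {
  # toy set: rest 0.1, 0.4; clench 0.35, 0.8 -> clench wins 3 of 4 pairs
  # (0.35 vs 0.4 is a strict loss)
  labels <- c("rest", "rest", "clench", "clench")
  scores <- c(0.1, 0.4, 0.35, 0.8)
  r <- roc_auc(labels, scores)
  expect_equal(r$auc, 3 / 4)
  # brute force over all pos x neg pairs on a larger random set, with ties
  set.seed(12)
  lab2 <- sample(c("rest", "clench"), 60, replace = TRUE)
  sc2 <- round(stats::runif(60), 2)   # rounding makes ties likely
  pos <- sc2[lab2 == "clench"]; neg <- sc2[lab2 == "rest"]
  brute <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(roc_auc(lab2, sc2)$auc, brute)
})

test_that("ROC curve endpoints, CI and p-value behave", {
  set.seed(13)
  n <- 200
  labels <- rep(c("rest", "clench"), each = n / 2)
  # perfectly separated scores -> AUC 1
  perfect <- c(stats::runif(n / 2, 0, 0.4), stats::runif(n / 2, 0.6, 1))
  rp <- roc_auc(labels, perfect)
  expect_equal(rp$auc, 1.0)
  expect_equal(rp$points$fpr[1], 0)
  expect_equal(rp$points$tpr[1], 0)
  expect_equal(rp$points$fpr[nrow(rp$points)], 1)
  expect_equal(rp$points$tpr[nrow(rp$points)], 1)
  # label-independent scores -> AUC ~ 0.5, CI straddles 0.5, p large
  rnd <- stats::runif(n)
  rr <- roc_auc(labels, rnd)
  expect_lt(abs(rr$auc - 0.5), 0.12)
  expect_true(rr$ci[1] <= rr$auc && rr$auc <= rr$ci[2])
  expect_gt(rr$p_value, 0.001)
  # informative scores: significantly above chance
  inf <- ifelse(labels == "clench", stats::runif(n, 0.3, 1),
                stats::runif(n, 0, 0.7))
  ri <- roc_auc(labels, inf)
  expect_lt(ri$p_value, 1e-6)
  expect_gt(ri$ci[1], 0.5)
  expect_error(roc_auc(rep("rest", 5), stats::runif(5)),
               class = "nc_roc_error")
})

test_that("DeLong CI agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  labels <- rep(c("rest", "clench"), each = 150)
  scores <- ifelse(labels == "clench", stats::rbeta(150, 3, 2),
                   stats::rbeta(150, 2, 3))
  mine <- roc_auc(labels, scores)
  ref <- pROC::roc(response = labels, predictor = scores,
                   levels = c("rest", "clench"), direction = "<",
                   quiet = TRUE)
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(mine$ci[1], ci[1], tolerance = 1e-6)
  expect_equal(mine$ci[2], ci[3], tolerance = 1e-6)
})

test_that("Ryan comparison: identical proportions are never significant", {
  r <- ryan_compare(c(500, 500), c(1000, 1000))
  expect_false(any(r$significant))
  # clearly different proportions are, at the adjusted level
  r2 <- ryan_compare(c(900, 500), c(1000, 1000))
  expect_true(all(r2$significant))
  expect_equal(r2$alpha_adj, 2 * 0.05 / (2 * 2))
  # stepwise protection: a pair nested in a non-significant span stays
  # non-significant even if its raw p dips below its own adjusted level
  r3 <- ryan_compare(c(520, 510, 500), c(1000, 1000, 1000))
  expect_false(any(r3$significant))
  expect_error(ryan_compare(c(10), c(20)), class = "nc_input_error")
  expect_error(ryan_compare(c(30, 5), c(20, 20)), class = "nc_input_error")
})

test_that("balanced test sets satisfy accuracy = (recall + specificity) / 2", {
  set.seed(15)
  n <- 100
  preds <- data.frame(label = rep(c("rest", "clench"), each = n),
                      pred = sample(c("rest", "clench"), 2 * n,
                                    replace = TRUE))
  m <- compute_metrics(confusion_counts(preds))
  expect_equal(m[["accuracy"]], (m[["recall"]] + m[["specificity"]]) / 2)
})
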