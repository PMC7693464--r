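# End-to-end orchestration: simulate -> preprocess -> encode -> balance ->
# grouped CV training -> evaluation -> channel statistics, driven by one
# declarative configuration with a single master seed.

#' Pipeline configuration
#'
#' @param cohort a [cohort_config()].
#' @param cutoff,filter_order low-pass filter settings (Hz / order).
#' @param scheme a [grayscale_scheme()].
#' @param layout a `channel_layout` (or path to a layout JSON).
#' @param modalities subset of `c("oxy", "deoxy", "od")`.
#' @param frame_stride keep every `stride`-th 10 Hz sample when building
#'   frames (1 = full frame set; desk-scale runs use larger strides).
#' @param balance_mode `"cohort"` or `"per-subject"` (see
#'   [balance_classes()]).
#' @param spec a [network_spec()].
#' @param train a [train_config()].
#' @param seed master seed; fold, balancing and training seeds derive from it.
#' @param out_dir optional output directory for artifact files (`NULL` keeps
#'   everything in memory).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            cutoff = 0.2, filter_order = 4,
                            scheme = grayscale_scheme(),
                            layout = default_channel_layout(),
                            modalities = c("oxy", "deoxy", "od"),
                            frame_stride = 1L,
                            balance_mode = "cohort",
                            spec = network_spec("tiny"),
                            train = train_config(),
                            seed = 1L, out_dir = NULL) {
  if (is.character(layout)) layout <- read_channel_layout(layout)
  structure(list(cohort = cohort, cutoff = cutoff,
                 filter_order = filter_order, scheme = scheme,
                 layout = layout, modalities = modalities,
                 frame_stride = as.integer(frame_stride),
                 balance_mode = balance_mode, spec = spec, train = train,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Evaluate a cross-validated prediction set
#'
#' Per-fold confusion counts and identification-rate metrics, their macro
#' aggregation (mean and sample SD over folds), the pooled (micro) accuracy
#' and correct/total counts, and the pooled ROC/AUC.
#'
#' @param preds data.frame from [crossvalidate_cnn()].
#' @return list with `per_fold` (data.frame of metrics by fold), `macro`
#'   (data.frame `metric`, `mean`, `sd`), `micro` (list `correct`, `total`,
#'   `accuracy`) and `roc` (a `roc_result`).
#' @export
evaluate_predictions <- function(preds) {
  folds <- sort(unique(preds$fold))
  msets <- lapply(folds, function(f) {
    compute_metrics(confusion_counts(preds[preds$fold == f, ]))
  })
  per_fold <- do.call(rbind, lapply(seq_along(folds), function(i) {
    data.frame(fold = folds[i], t(unclass(msets[[i]])))
  }))
  correct <- sum(preds$pred == preds$label)
  list(per_fold = per_fold,
       macro = aggregate_folds(msets),
       micro = list(correct = correct, total = nrow(preds),
                    accuracy = correct / nrow(preds)),
       roc = roc_auc(preds$label, preds$score))
}

#' Run the full pipeline
#'
#' Executes synthetic cohort generation, preprocessing, frame encoding,
#' counterbalancing, subject-grouped five-fold CV training per modality,
#' evaluation, the cross-network proportion comparison and the conventional
#' channel statistics. Deterministic given the configuration.
#'
#' @param config a [pipeline_config()].
#' @param cohort optionally, a pre-generated `hb_cohort` (skips simulation;
#'   used to reuse one cohort across configurations).
#' @return an object of class `pipeline_manifest`: counts per stage,
#'   predictions, evaluation per modality, Ryan comparison across modalities,
#'   channel statistics tables, fold plan and seeds.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  cohort <- cohort %||% generate_cohort(config$cohort)
  eds <- preprocess_cohort(cohort, cutoff = config$cutoff,
                           order = config$filter_order)
  imgset <- combine_image_sets(lapply(eds, build_image_set,
                                      layout = config$layout,
                                      scheme = config$scheme,
                                      modalities = config$modalities,
                                      stride = config$frame_stride))
  subjects <- vapply(cohort$recordings, `[[`, character(1), "subject_id")
  plan <- make_fold_plan(subjects, seed = derive_seed(config$seed, 11L))

  meta <- imgset$meta
  meta$frame <- seq_len(nrow(meta))
  results <- list(); preds_all <- list(); balanced_counts <- list()
  for (mod in config$modalities) {
    sub <- meta[meta$modality == mod, , drop = FALSE]
    balanced <- balance_classes(sub, seed = derive_seed(config$seed, 13L),
                                mode = config$balance_mode)
    balanced_counts[[mod]] <- table(balanced$label)
    cfg <- config$train
    cfg$seed <- derive_seed(config$seed, 17L, match(mod, config$modalities))
    preds <- crossvalidate_cnn(imgset, balanced, plan, config$spec, cfg)
    preds_all[[mod]] <- preds
    results[[mod]] <- evaluate_predictions(preds)
  }

  ryan <- if (length(config$modalities) >= 2) {
    ryan_compare(vapply(results, function(r) r$micro$correct, numeric(1)),
                 vapply(results, function(r) r$micro$total, numeric(1)),
                 names = names(results))
  } else NULL

  manifest <- structure(list(
    seed = config$seed,
    counts = imgset$counts,
    balanced = balanced_counts,
    fold_plan = plan,
    predictions = preds_all,
    evaluation = results,
    ryan = ryan,
    channel_stats = channel_changes(cohort, cutoff = config$cutoff,
                                    order = config$filter_order),
    wall_clock_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "pipeline_manifest")
  if (!is.null(config$out_dir)) write_manifest(manifest, config$out_dir)
  manifest
}

# write the report files: metrics CSVs (rows = folds + Average+-SD), ROC
# points, channel tables, fold plan and a JSON summary
write_manifest <- function(manifest, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (mod in names(manifest$evaluation)) {
    ev <- manifest$evaluation[[mod]]
    pf <- ev$per_fold
    pct <- function(x) round(100 * x, 1)
    tab <- data.frame(group = pf$fold,
                      accuracy = pct(pf$accuracy), recall = pct(pf$recall),
                      specificity = pct(pf$specificity),
                      precision = pct(pf$precision),
                      f_value = round(pf$f_value, 3))
    avg <- ev$macro
    fmt_avg <- function(metric, digits, scale) {
      r <- avg[avg$metric == metric, ]
      paste0(round(scale * r$mean, digits), " +- ", round(scale * r$sd, digits))
    }
    tab <- rbind(tab, data.frame(
      group = "Average +- SD",
      accuracy = fmt_avg("accuracy", 1, 100),
      recall = fmt_avg("recall", 1, 100),
      specificity = fmt_avg("specificity", 1, 100),
      precision = fmt_avg("precision", 1, 100),
      f_value = fmt_avg("f_value", 3, 1)))
    utils::write.csv(tab, file.path(dir, paste0("metrics_", mod, ".csv")),
                     row.names = FALSE)
    utils::write.csv(ev$roc$points,
                     file.path(dir, paste0("roc_", mod, ".csv")),
                     row.names = FALSE)
    utils::write.csv(manifest$predictions[[mod]],
                     file.path(dir, paste0("predictions_", mod, ".csv")),
                     row.names = FALSE)
  }
  for (sp in c("oxy", "deoxy")) {
    utils::write.csv(manifest$channel_stats[[sp]],
                     file.path(dir, paste0("channel_stats_", sp, ".csv")),
                     row.names = FALSE)
  }
  write_fold_plan(manifest$fold_plan, file.path(dir, "fold_plan.json"))
  summary <- list(
    seed = manifest$seed,
    counts = manifest$counts,
    auc = lapply(manifest$evaluation, function(ev) {
      list(auc = ev$roc$auc, ci = ev$roc$ci, p_value = ev$roc$p_value)
    }),
    micro = lapply(manifest$evaluation, `[[`, "micro"),
    ryan = manifest$ryan,
    wall_clock_s = manifest$wall_clock_s
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat("fNIRS rest/clench pipeline run (seed ", x$seed, ")\n", sep = "")
  cat("frames (candidates/valid):\n")
  print(x$counts, row.names = FALSE)
  for (mod in names(x$evaluation)) {
    ev <- x$evaluation[[mod]]
    acc <- ev$macro[ev$macro$metric == "accuracy", ]
    cat(sprintf("%-6s macro accuracy %.1f +- %.1f %%, micro %.1f %%, AUC %.3f (95%% CI %.3f-%.3f)\n",
                mod, 100 * acc$mean, 100 * acc$sd,
                100 * ev$micro$accuracy, ev$roc$auc, ev$roc$ci[1],
                ev$roc$ci[2]))
  }
  invisible(x)
}
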