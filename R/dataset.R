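# Class counterbalancing and the subject-grouped five-fold cross-validation
# plan. Balancing happens once per modality over the whole cohort, before
# fold splitting; grouping by subject makes leakage of a test subject's
# frames into training impossible by construction.

#' Counterbalance class sizes by random undersampling
#'
#' The majority class is randomly downsampled (without replacement, seeded)
#' until the two classes are equal; the minority class is untouched. In
#' `"cohort"` mode the removals are apportioned across subjects proportionally
#' to each subject's share of the majority class (largest-remainder rounding),
#' so no subject is disproportionately pruned; `"per-subject"` mode balances
#' within every subject independently.
#'
#' @param meta data.frame with at least `subject`, `label` (`"rest"`/
#'   `"clench"`) and `valid` columns (e.g. `hb_image_set$meta` for one
#'   modality). Only valid rows participate; invalid rows are dropped.
#' @param seed RNG seed for the downsampling.
#' @param mode `"cohort"` (default) or `"per-subject"`.
#' @return the balanced subset of `meta` rows, with an added integer column
#'   `frame` holding the original row index of `meta`.
#' @export
balance_classes <- function(meta, seed = 1L, mode = c("cohort",
                                                      "per-subject")) {
  mode <- match.arg(mode)
  if (is.null(meta$frame)) meta$frame <- seq_len(nrow(meta))
  meta <- meta[meta$valid, , drop = FALSE]
  counts <- table(factor(meta$label, levels = c("rest", "clench")))
  if (any(counts == 0)) nc_stop("both classes must be non-empty",
                                "nc_dataset_error")
  if (counts["rest"] == counts["clench"]) return(meta)
  maj <- if (counts["rest"] > counts["clench"]) "rest" else "clench"
  excess <- abs(counts["rest"] - counts["clench"])
  set.seed(derive_seed(seed, 211L))

  drop_rows <- integer(0)
  if (mode == "per-subject") {
    for (s in unique(meta$subject)) {
      sel <- meta$subject == s
      n_r <- sum(sel & meta$label == "rest")
      n_c <- sum(sel & meta$label == "clench")
      if (n_r == n_c) next
      m <- if (n_r > n_c) "rest" else "clench"
      rows <- which(sel & meta$label == m)
      drop_rows <- c(drop_rows, sample(rows, abs(n_r - n_c)))
    }
  } else {
    rows_by_subj <- split(which(meta$label == maj), meta$subject[meta$label == maj])
    sizes <- lengths(rows_by_subj)
    share <- as.numeric(excess) * sizes / sum(sizes)
    take <- pmin(floor(share), sizes)
    rem <- as.integer(excess) - sum(take)
    # distribute the remainder by largest fractional part, capped at capacity
    frac <- share - floor(share)
    ord <- order(frac, decreasing = TRUE)
    i <- 1L
    while (rem > 0L) {
      j <- ord[(i - 1L) %% length(ord) + 1L]
      if (take[j] < sizes[j]) { take[j] <- take[j] + 1L; rem <- rem - 1L }
      i <- i + 1L
    }
    for (j in seq_along(rows_by_subj)) {
      if (take[j] > 0L) {
        drop_rows <- c(drop_rows, sample(rows_by_subj[[j]], take[j]))
      }
    }
  }
  out <- meta[setdiff(seq_len(nrow(meta)), drop_rows), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subject-grouped five-fold cross-validation plan
#'
#' Randomly partitions the subjects into 5 equal groups; fold g holds group g
#' out for testing and trains on the other four. Generalizes to any subject
#' count divisible by 5.
#'
#' @param subject_ids character vector of subject identifiers.
#' @param seed RNG seed for the partition.
#' @return an object of class `fold_plan`: `groups` (list of 5 subject-id
#'   vectors) and `folds` (list of 5 lists with `train` and `test` subject
#'   sets), plus the seed.
#' @export
make_fold_plan <- function(subject_ids, seed = 1L) {
  n <- length(subject_ids)
  if (n %% 5L != 0L || n == 0L) {
    nc_stop("subject count must be a positive multiple of 5", "nc_plan_error")
  }
  if (anyDuplicated(subject_ids)) {
    nc_stop("subject ids must be unique", "nc_plan_error")
  }
  set.seed(derive_seed(seed, 307L))
  shuffled <- sample(subject_ids)
  groups <- split(shuffled, rep(1:5, each = n / 5L))
  names(groups) <- LETTERS[1:5]
  folds <- lapply(1:5, function(g) {
    list(test = groups[[g]], train = unlist(groups[-g], use.names = FALSE))
  })
  names(folds) <- LETTERS[1:5]
  structure(list(groups = groups, folds = folds, seed = as.integer(seed)),
            class = "fold_plan")
}

#' Serialize / load a fold plan as JSON
#'
#' @param plan a `fold_plan`.
#' @param path JSON file path.
#' @return `write_fold_plan`: the path invisibly; `read_fold_plan`: a
#'   `fold_plan`.
#' @export
write_fold_plan <- function(plan, path) {
  jsonlite::write_json(list(groups = plan$groups, seed = plan$seed), path,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_fold_plan
#' @export
read_fold_plan <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  groups <- j$groups
  folds <- lapply(seq_along(groups), function(g) {
    list(test = groups[[g]], train = unlist(groups[-g], use.names = FALSE))
  })
  names(folds) <- names(groups)
  structure(list(groups = groups, folds = folds,
                 seed = as.integer(j$seed)), class = "fold_plan")
}
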