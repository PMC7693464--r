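# Conventional channel-wise hemoglobin analysis: clench-minus-rest mean
# changes per channel with paired t-tests and uncapped Bonferroni adjustment.
# This stage uses the full 1-minute clench window (600 samples at 10 Hz),
# unlike the imaging stage which drops the first 5 s.

#' Per-channel clench-minus-rest changes with paired t-tests
#'
#' For each subject and channel, the mean over the full 60 s clench window
#' minus the mean over the 60 s rest window immediately before it, per Hb
#' species. Across subjects: mean, sample SD, two-sided paired t-test
#' (equivalently a one-sample t on the differences) and Bonferroni-adjusted
#' p = raw p x 22, deliberately uncapped (values above 1 are reported as
#' such). A zero-variance channel yields `NA` p-values, flagged rather than
#' silently zeroed.
#'
#' @param cohort an `hb_cohort` (>= 2 subjects).
#' @param cutoff low-pass cutoff applied before windowing, Hz (`NULL`
#'   disables).
#' @param order filter order.
#' @return list with elements `oxy` and `deoxy`, each a data.frame
#'   `channel`, `change_mean`, `change_sd`, `p_raw`, `p_adj`, `region`.
#' @export
channel_changes <- function(cohort, cutoff = 0.2, order = 4) {
  stopifnot(inherits(cohort, "hb_cohort"))
  if (length(cohort$recordings) < 2) {
    nc_stop("need >= 2 subjects for the paired t-test", "nc_stats_error")
  }
  diffs <- lapply(cohort$recordings, function(rec) {
    if (!is.null(cutoff)) {
      rec$oxy <- lowpass_filter(rec$oxy, cutoff, rec$fs, order)
      rec$deoxy <- lowpass_filter(rec$deoxy, cutoff, rec$fs, order)
    }
    tc <- time_course(rec$events$clench_onset)
    n <- nrow(rec$oxy)
    ir <- window_idx(tc$rest, rec$fs, n)
    ic <- window_idx(tc$clench_full, rec$fs, n)
    list(oxy = colMeans(rec$oxy[ic, , drop = FALSE]) -
           colMeans(rec$oxy[ir, , drop = FALSE]),
         deoxy = colMeans(rec$deoxy[ic, , drop = FALSE]) -
           colMeans(rec$deoxy[ir, , drop = FALSE]))
  })
  species_table <- function(sp) {
    d <- do.call(rbind, lapply(diffs, `[[`, sp))  # subjects x channels
    p_raw <- apply(d, 2, function(x) {
      if (stats::sd(x) == 0) return(NA_real_)
      stats::t.test(x)$p.value
    })
    data.frame(channel = 1:22,
               change_mean = colMeans(d),
               change_sd = apply(d, 2, stats::sd),
               p_raw = p_raw,
               p_adj = p_raw * 22,
               region = channel_regions(),
               row.names = NULL)
  }
  list(oxy = species_table("oxy"), deoxy = species_table("deoxy"))
}
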