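# Preprocessing: zero-phase low-pass filtering, block-design windowing,
# baseline-referenced deltas and the 2-SD artifact mask.

#' Zero-phase low-pass filter
#'
#' Butterworth low-pass applied forward-backward (`signal::filtfilt`) per
#' channel, so window boundaries are not phase-shifted and length is
#' preserved. Matches the 0.2 Hz on-line filtering of the acquisition device.
#'
#' @param x numeric matrix, time x channels (a vector is treated as one
#'   channel).
#' @param cutoff cutoff frequency, Hz; must be below Nyquist (`fs/2`).
#' @param fs sampling rate, Hz.
#' @param order filter order (default 4).
#' @return filtered matrix of the same shape.
#' @export
lowpass_filter <- function(x, cutoff = 0.2, fs = 10, order = 4) {
  if (cutoff >= fs / 2) {
    nc_stop("cutoff must be below the Nyquist frequency", "nc_parameter_error")
  }
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  n <- nrow(x)
  # odd-reflection padding suppresses the start/end transients that plain
  # forward-backward filtering leaves on signals with a nonzero offset
  np <- min(n - 1L, as.integer(ceiling(3 * fs / cutoff)))
  out <- apply(x, 2, function(col) {
    pre <- 2 * col[1] - col[(np + 1):2]
    post <- 2 * col[n] - col[(n - 1):(n - np)]
    y <- signal::filtfilt(bf, c(pre, col, post))
    y[(np + 1):(np + n)]
  })
  out <- matrix(out, nrow = n, dimnames = dimnames(x))
  if (vec) out[, 1] else out
}

#' Block-design analysis windows
#'
#' From the clench onset (seconds from recording start): baseline = 10 s
#' immediately before the rest window, rest = 60 s immediately before clench
#' onset, exclusion = first `exclude_s` seconds of the task (hemodynamics lag
#' the task onset), clench = remaining task seconds. Windows are half-open
#' `[start, end)` so sample counts are exact.
#'
#' @param clench_onset task onset, s.
#' @param baseline_s,rest_s,exclude_s,clench_s window durations, s.
#' @return an object of class `time_course` with named `c(start, end)` pairs.
#' @export
time_course <- function(clench_onset, baseline_s = 10, rest_s = 60,
                        exclude_s = 5, clench_s = 60) {
  structure(list(
    baseline = c(clench_onset - rest_s - baseline_s, clench_onset - rest_s),
    rest = c(clench_onset - rest_s, clench_onset),
    exclusion = c(clench_onset, clench_onset + exclude_s),
    clench = c(clench_onset + exclude_s, clench_onset + clench_s),
    clench_full = c(clench_onset, clench_onset + clench_s)
  ), class = "time_course")
}

# sample indices of half-open window [a, b) at rate fs (times on grid k/fs)
window_idx <- function(win, fs, n) {
  i0 <- as.integer(round(win[1] * fs)) + 1L
  i1 <- as.integer(round(win[2] * fs))
  if (i0 < 1 || i1 > n) nc_stop("recording too short for window",
                                "nc_window_error")
  i0:i1
}

#' Cut the analysis windows out of a recording
#'
#' @param rec an `hb_recording`.
#' @param tc a [time_course()]; defaults to the one implied by the recording's
#'   clench onset.
#' @return list with elements `oxy` and `deoxy`, each a list of matrices
#'   `baseline` (100 samples at 10 Hz), `rest` (600) and `clench` (550); the
#'   exclusion window is dropped.
#' @export
extract_windows <- function(rec, tc = NULL) {
  stopifnot(inherits(rec, "hb_recording"))
  tc <- tc %||% time_course(rec$events$clench_onset)
  n <- nrow(rec$oxy)
  idx <- list(baseline = window_idx(tc$baseline, rec$fs, n),
              rest = window_idx(tc$rest, rec$fs, n),
              clench = window_idx(tc$clench, rec$fs, n))
  out <- lapply(list(oxy = rec$oxy, deoxy = rec$deoxy), function(m) {
    lapply(idx, function(i) m[i, , drop = FALSE])
  })
  out
}

#' Per-channel baseline means
#'
#' @param segment time x channel matrix (the baseline window).
#' @return numeric vector of per-channel means.
#' @export
baseline_means <- function(segment) {
  if (nrow(segment) == 0) nc_stop("empty baseline segment", "nc_window_error")
  colMeans(segment)
}

#' Baseline-referenced deltas for the rest and clench windows
#'
#' `delta(t, ch) = value(t, ch) - baseline_mean(ch)`, per Hb species.
#'
#' @param windows output of [extract_windows()].
#' @param subject_id subject identifier carried through to downstream stages.
#' @return an object of class `epoch_deltas`: per species, matrices `rest`
#'   (600 x 22) and `clench` (550 x 22) of deltas, an all-`FALSE` missing-value
#'   mask of the same shapes, and `stats = NULL` (filled by
#'   [mask_artifacts()]).
#' @export
compute_deltas <- function(windows, subject_id = NA_character_) {
  sp <- lapply(windows, function(w) {
    bm <- baseline_means(w$baseline)
    list(rest = sweep(w$rest, 2, bm),
         clench = sweep(w$clench, 2, bm),
         baseline_mean = bm)
  })
  mask <- lapply(sp, function(s) {
    list(rest = matrix(FALSE, nrow(s$rest), ncol(s$rest)),
         clench = matrix(FALSE, nrow(s$clench), ncol(s$clench)))
  })
  structure(list(subject_id = subject_id,
                 oxy = sp$oxy, deoxy = sp$deoxy,
                 mask = mask, stats = NULL),
            class = "epoch_deltas")
}

#' Mask artifacts by the 2-SD rule
#'
#' For each window (rest, clench), Hb species and channel independently, the
#' mean and SD of the deltas are computed once on the unmasked data (single
#' pass); samples with `|delta - mean| > 2 * SD` (strict) become missing. A
#' zero-variance channel masks nothing.
#'
#' @param ed an `epoch_deltas`.
#' @param k threshold in SD units (default 2).
#' @return the `epoch_deltas` with its `mask` filled in and `stats` holding
#'   the per-window per-channel means/SDs used.
#' @export
mask_artifacts <- function(ed, k = 2) {
  stopifnot(inherits(ed, "epoch_deltas"))
  stats <- list()
  for (sp in c("oxy", "deoxy")) {
    for (win in c("rest", "clench")) {
      d <- ed[[sp]][[win]]
      if (nrow(d) < 2) nc_stop("need >= 2 samples to estimate the SD",
                               "nc_window_error")
      m <- colMeans(d)
      s <- apply(d, 2, stats::sd)
      dev <- abs(sweep(d, 2, m))
      ed$mask[[sp]][[win]] <- sweep(dev, 2, k * s, `>`)
      stats[[sp]][[win]] <- list(mean = m, sd = s)
    }
  }
  ed$stats <- stats
  ed
}

#' Delta values with masked samples set to NA
#'
#' @param ed an `epoch_deltas` (after [mask_artifacts()]; an unmasked object
#'   returns the raw deltas).
#' @param species `"oxy"` or `"deoxy"`.
#' @param window `"rest"` or `"clench"`.
#' @return matrix of deltas with `NA` at masked positions.
#' @export
delta_values <- function(ed, species = c("oxy", "deoxy"),
                         window = c("rest", "clench")) {
  species <- match.arg(species)
  window <- match.arg(window)
  d <- ed[[species]][[window]]
  d[ed$mask[[species]][[window]]] <- NA_real_
  d
}

#' Full preprocessing of one recording
#'
#' Low-pass filter, window extraction, baseline deltas and 2-SD masking, in
#' that order.
#'
#' @param rec an `hb_recording`.
#' @param cutoff low-pass cutoff, Hz (`NULL` disables filtering).
#' @param order filter order.
#' @param mask logical; apply the 2-SD artifact mask.
#' @return an `epoch_deltas`.
#' @export
preprocess_recording <- function(rec, cutoff = 0.2, order = 4, mask = TRUE) {
  stopifnot(inherits(rec, "hb_recording"))
  if (!is.null(cutoff)) {
    rec$oxy <- lowpass_filter(rec$oxy, cutoff, rec$fs, order)
    rec$deoxy <- lowpass_filter(rec$deoxy, cutoff, rec$fs, order)
  }
  ed <- compute_deltas(extract_windows(rec), subject_id = rec$subject_id)
  if (mask) ed <- mask_artifacts(ed)
  ed
}

#' Preprocess every recording of a cohort
#'
#' @param cohort an `hb_cohort`.
#' @inheritParams preprocess_recording
#' @return list of `epoch_deltas`, one per subject.
#' @export
preprocess_cohort <- function(cohort, cutoff = 0.2, order = 4, mask = TRUE) {
  stopifnot(inherits(cohort, "hb_cohort"))
  lapply(cohort$recordings, preprocess_recording,
         cutoff = cutoff, order = order, mask = mask)
}
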