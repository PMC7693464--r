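# Synthetic fNIRS cohort generator.
#
# Emulates the block design of the motivating experiment: 300 s rest, 60 s
# tooth clench, 60 s rest, sampled at 10 Hz over 22 prefrontal channels, for
# oxy- and deoxy-hemoglobin concentration changes in m(mol/L)*mm. The task
# response is a boxcar convolved with a canonical double-gamma hemodynamic
# response; physiological noise (cardiac, respiratory, Mayer wave), slow
# drift, white noise and movement-like spike artifacts are superimposed.

#' Per-channel task-effect profile
#'
#' Defines the mean task-evoked change per channel and Hb species and the
#' between-subject SD of those effects. Defaults are the reference per-channel
#' changes of [hb_effect_table()], with between-subject SDs set to the
#' across-subject SDs divided by sqrt(15) (a modest subject-level perturbation;
#' the published SDs describe across-subject spread of realized changes, not a
#' generative model).
#'
#' @param oxy,deoxy numeric(22): mean task effect per channel, m(mol/L)*mm.
#' @param subject_sd_oxy,subject_sd_deoxy numeric(22): SD of the zero-mean
#'   Gaussian subject-level perturbation of each channel effect.
#' @return an object of class `effect_profile`.
#' @export
effect_profile <- function(oxy = hb_effect_table("oxy")$change_mean,
                           deoxy = hb_effect_table("deoxy")$change_mean,
                           subject_sd_oxy =
                             hb_effect_table("oxy")$change_sd / sqrt(15),
                           subject_sd_deoxy =
                             hb_effect_table("deoxy")$change_sd / sqrt(15)) {
  for (v in list(oxy, deoxy, subject_sd_oxy, subject_sd_deoxy)) {
    if (length(v) != 22L || !is.numeric(v) || anyNA(v)) {
      nc_stop("effect profiles need exactly 22 finite values per Hb species",
              "nc_config_error")
    }
  }
  structure(list(oxy = as.numeric(oxy), deoxy = as.numeric(deoxy),
                 subject_sd_oxy = as.numeric(subject_sd_oxy),
                 subject_sd_deoxy = as.numeric(subject_sd_deoxy)),
            class = "effect_profile")
}

#' Null (no-activation) effect profile
#'
#' All task effects and subject-level perturbations zero; used for
#' chance-level controls.
#'
#' @return an `effect_profile`.
#' @export
null_effect_profile <- function() {
  z <- rep(0, 22)
  effect_profile(oxy = z, deoxy = z, subject_sd_oxy = z, subject_sd_deoxy = z)
}

#' Physiological / instrumental noise profile
#'
#' Amplitudes are in m(mol/L)*mm, frequencies in Hz. The spike model is
#' additive pulses of 1-3 samples whose amplitude is uniform in
#' `spike_amp_range` multiples of `white_sd` with random sign (so no spikes are
#' produced when `white_sd = 0`).
#'
#' @param white_sd SD of per-sample white noise.
#' @param drift_amplitude amplitude ceiling of the slow baseline wander, a
#'   random-phase sinusoid at period `drift_timescale` (amplitude drawn
#'   uniformly in `[0, drift_amplitude]` per channel). The wander is
#'   stationary: with no task effect, rest and clench windows are
#'   statistically exchangeable.
#' @param drift_timescale drift sinusoid period, seconds.
#' @param cardiac_freq,cardiac_amp cardiac oscillation (~1.2 Hz).
#' @param resp_freq,resp_amp respiratory oscillation (~0.3 Hz).
#' @param mayer_freq,mayer_amp Mayer-wave oscillation (~0.1 Hz).
#' @param spike_rate spike-artifact rate, events per minute per channel.
#' @param spike_amp_range length-2 numeric, spike amplitude bounds as
#'   multiples of `white_sd`.
#' @return an object of class `noise_profile`.
#' @export
noise_profile <- function(white_sd = 0.03,
                          drift_amplitude = 0.05, drift_timescale = 120,
                          cardiac_freq = 1.2, cardiac_amp = 0.02,
                          resp_freq = 0.3, resp_amp = 0.015,
                          mayer_freq = 0.1, mayer_amp = 0.02,
                          spike_rate = 2, spike_amp_range = c(4, 8)) {
  amps <- c(white_sd, drift_amplitude, cardiac_amp, resp_amp, mayer_amp,
            spike_rate, spike_amp_range)
  if (any(!is.finite(amps)) || any(amps < 0)) {
    nc_stop("noise amplitudes and rates must be finite and >= 0",
            "nc_config_error")
  }
  if (any(c(cardiac_freq, resp_freq, mayer_freq, drift_timescale) <= 0)) {
    nc_stop("noise frequencies and timescales must be > 0", "nc_config_error")
  }
  structure(list(white_sd = white_sd, drift_amplitude = drift_amplitude,
                 drift_timescale = drift_timescale,
                 cardiac_freq = cardiac_freq, cardiac_amp = cardiac_amp,
                 resp_freq = resp_freq, resp_amp = resp_amp,
                 mayer_freq = mayer_freq, mayer_amp = mayer_amp,
                 spike_rate = spike_rate,
                 spike_amp_range = as.numeric(spike_amp_range)),
            class = "noise_profile")
}

#' Noise profile with everything switched off
#'
#' @return a `noise_profile` whose every amplitude and rate is zero.
#' @export
no_noise_profile <- function() {
  noise_profile(white_sd = 0, drift_amplitude = 0, cardiac_amp = 0,
                resp_amp = 0, mayer_amp = 0, spike_rate = 0,
                spike_amp_range = c(0, 0))
}

#' Synthetic cohort configuration
#'
#' Defaults reproduce the study conditions: 15 subjects, 22 channels, 10 Hz,
#' 300 s rest + 60 s clench + 60 s rest.
#'
#' @param n_subjects number of subjects.
#' @param n_channels number of fNIRS channels (22).
#' @param fs sampling rate, Hz.
#' @param rest_s,clench_s,post_s durations of the initial rest, clench task
#'   and final rest blocks, seconds.
#' @param effects an [effect_profile()].
#' @param noise a [noise_profile()].
#' @param seed master seed; fully determines the cohort.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 15L, n_channels = 22L, fs = 10,
                          rest_s = 300, clench_s = 60, post_s = 60,
                          effects = effect_profile(),
                          noise = noise_profile(), seed = 1L) {
  if (fs <= 0 || rest_s <= 0 || clench_s <= 0 || post_s <= 0) {
    nc_stop("durations and sampling rate must be positive", "nc_config_error")
  }
  if (n_subjects < 1) nc_stop("need at least one subject", "nc_config_error")
  if (n_channels != 22L) {
    nc_stop("the probe layout defines exactly 22 channels", "nc_config_error")
  }
  stopifnot(inherits(effects, "effect_profile"),
            inherits(noise, "noise_profile"))
  structure(list(n_subjects = as.integer(n_subjects),
                 n_channels = 22L, fs = fs, rest_s = rest_s,
                 clench_s = clench_s, post_s = post_s,
                 effects = effects, noise = noise,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Canonical double-gamma hemodynamic response
#'
#' Difference of two gamma densities with response peak at `peak` seconds and
#' undershoot peak at `undershoot` seconds, normalized to unit peak amplitude.
#'
#' @param t time grid, seconds (t >= 0).
#' @param peak response peak time, s.
#' @param undershoot undershoot peak time, s.
#' @param ratio undershoot-to-peak amplitude ratio before normalization.
#' @return numeric vector, max value 1.
#' @export
hrf_double_gamma <- function(t, peak = 6, undershoot = 16, ratio = 1 / 6) {
  h <- stats::dgamma(t, shape = peak + 1, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot + 1, rate = 1)
  h / max(h)
}

# task regressor: boxcar over the clench window convolved with the HRF,
# normalized to unit plateau so a channel effect of e yields a sustained
# response of e during the task.
task_regressor <- function(n, fs, onset, offset, hrf_fun = hrf_double_gamma) {
  t <- (seq_len(n) - 1) / fs
  box <- as.numeric(t >= onset & t < offset)
  tk <- seq(0, 32, by = 1 / fs)
  k <- hrf_fun(tk)
  reg <- stats::convolve(box, rev(k), type = "open")[seq_len(n)]
  reg / max(reg)
}

# spike train: Poisson number of pulses, each 1-3 samples wide, amplitude
# uniform in amp_range * white_sd, random sign.
draw_spike_train <- function(n, fs, rate_per_min, amp_range, white_sd) {
  out <- numeric(n)
  lambda <- rate_per_min * n / fs / 60
  k <- stats::rpois(1, lambda)
  if (k == 0 || white_sd <= 0) return(list(train = out, count = k))
  pos <- sample.int(n, k, replace = TRUE)
  width <- sample.int(3, k, replace = TRUE)
  amp <- stats::runif(k, amp_range[1], amp_range[2]) * white_sd *
    sample(c(-1, 1), k, replace = TRUE)
  for (i in seq_len(k)) {
    idx <- pos[i]:min(n, pos[i] + width[i] - 1)
    out[idx] <- out[idx] + amp[i]
  }
  list(train = out, count = k)
}

# one channel's noise realization on time grid t
channel_noise <- function(t, fs, np) {
  n <- length(t)
  x <- numeric(n)
  if (np$white_sd > 0) x <- x + stats::rnorm(n, 0, np$white_sd)
  # slow baseline wander: random-amplitude, random-phase sinusoid at the
  # drift timescale. Kept stationary (no monotone trend) so that, under a
  # null task effect, rest and clench windows are statistically exchangeable
  # despite their different lags from the baseline window.
  samp <- stats::runif(1, 0, np$drift_amplitude)
  sphase <- stats::runif(1, 0, 2 * pi)
  x <- x + samp * sin(2 * pi * t / np$drift_timescale + sphase)
  for (comp in list(c(np$cardiac_freq, np$cardiac_amp),
                    c(np$resp_freq, np$resp_amp),
                    c(np$mayer_freq, np$mayer_amp))) {
    ph <- stats::runif(1, 0, 2 * pi)
    if (comp[2] > 0) x <- x + comp[2] * sin(2 * pi * comp[1] * t + ph)
  }
  x + draw_spike_train(n, fs, np$spike_rate, np$spike_amp_range,
                       np$white_sd)$train
}

#' Generate one subject's synthetic recording
#'
#' The task effect is a boxcar over the clench window convolved with the
#' canonical double-gamma HRF (unit plateau), scaled per channel by the effect
#' profile plus a subject-level Gaussian perturbation; noise per
#' [noise_profile()] is added independently per channel and Hb species. Output
#' is bit-reproducible given `(config, subject_index)`.
#'
#' @param config a [cohort_config()].
#' @param subject_index integer in `1:config$n_subjects`.
#' @param hrf_fun HRF kernel function of time (seconds), unit peak.
#' @return an object of class `hb_recording`: fields `subject_id`, `fs`,
#'   `oxy` and `deoxy` (time x 22 matrices), and `events` (clench
#'   onset/offset, seconds).
#' @export
generate_recording <- function(config, subject_index,
                               hrf_fun = hrf_double_gamma) {
  stopifnot(inherits(config, "cohort_config"))
  if (subject_index < 1 || subject_index > config$n_subjects) {
    nc_stop("subject_index outside cohort", "nc_config_error")
  }
  fs <- config$fs
  n <- as.integer(round((config$rest_s + config$clench_s + config$post_s) * fs))
  t <- (seq_len(n) - 1) / fs
  onset <- config$rest_s
  offset <- config$rest_s + config$clench_s
  reg <- task_regressor(n, fs, onset, offset, hrf_fun)
  ef <- config$effects
  np <- config$noise

  set.seed(derive_seed(config$seed, 101L, subject_index))
  make_species <- function(means, sds) {
    eff <- means + stats::rnorm(22, 0, sds)
    sig <- outer(reg, eff)
    noise <- vapply(seq_len(22), function(ch) channel_noise(t, fs, np),
                    numeric(n))
    sig + noise
  }
  oxy <- make_species(ef$oxy, ef$subject_sd_oxy)
  deoxy <- make_species(ef$deoxy, ef$subject_sd_deoxy)
  colnames(oxy) <- sprintf("ch%02d_oxy", 1:22)
  colnames(deoxy) <- sprintf("ch%02d_deoxy", 1:22)
  structure(list(subject_id = sprintf("sub-%02d", subject_index),
                 fs = fs, oxy = oxy, deoxy = deoxy,
                 events = list(clench_onset = onset, clench_offset = offset)),
            class = "hb_recording")
}

#' Generate a synthetic cohort
#'
#' One [generate_recording()] per subject, each from its own deterministic
#' RNG substream of the master seed.
#'
#' @param config a [cohort_config()].
#' @return an object of class `hb_cohort`: list with `recordings` (list of
#'   `hb_recording`) and the `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  recs <- lapply(seq_len(config$n_subjects),
                 function(i) generate_recording(config, i))
  structure(list(recordings = recs, config = config), class = "hb_cohort")
}

#' Write a cohort to disk as per-subject CSV plus JSON sidecars
#'
#' CSV dialect: header `time_s,ch01_oxy,...,ch22_oxy,ch01_deoxy,...,
#' ch22_deoxy`; sidecar `<subject>.json` holds subject id, sampling rate and
#' clench onset/offset.
#'
#' @param cohort an `hb_cohort`.
#' @param dir output directory (created if missing).
#' @return invisibly, the written CSV paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "hb_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(cohort$recordings, function(rec) {
    n <- nrow(rec$oxy)
    df <- data.frame(time_s = (seq_len(n) - 1) / rec$fs)
    df <- cbind(df, as.data.frame(rec$oxy), as.data.frame(rec$deoxy))
    csv <- file.path(dir, paste0(rec$subject_id, ".csv"))
    utils::write.csv(df, csv, row.names = FALSE)
    side <- list(subject_id = rec$subject_id, fs = rec$fs,
                 clench_onset = rec$events$clench_onset,
                 clench_offset = rec$events$clench_offset)
    jsonlite::write_json(side, file.path(dir, paste0(rec$subject_id, ".json")),
                         auto_unbox = TRUE, digits = NA)
    csv
  }, character(1))
  invisible(paths)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory holding `<subject>.csv` / `<subject>.json` pairs.
#' @return an `hb_cohort` (its `config` field is `NULL`).
#' @export
read_cohort <- function(dir) {
  csvs <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(csvs) == 0) nc_stop("no cohort CSV files found", "nc_config_error")
  recs <- lapply(csvs, function(csv) {
    df <- utils::read.csv(csv)
    side <- jsonlite::read_json(sub("\\.csv$", ".json", csv),
                                simplifyVector = TRUE)
    oxy <- as.matrix(df[, sprintf("ch%02d_oxy", 1:22)])
    deoxy <- as.matrix(df[, sprintf("ch%02d_deoxy", 1:22)])
    structure(list(subject_id = side$subject_id, fs = side$fs,
                   oxy = oxy, deoxy = deoxy,
                   events = list(clench_onset = side$clench_onset,
                                 clench_offset = side$clench_offset)),
              class = "hb_recording")
  })
  structure(list(recordings = recs, config = NULL), class = "hb_cohort")
}
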