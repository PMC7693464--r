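# Small fixtures shared across test files. Everything is generated in code.

# a fast, quiet cohort: few subjects, mild noise, reference effect sizes
tiny_cohort_config <- function(n_subjects = 5L, seed = 42L,
                               effects = effect_profile(),
                               noise = noise_profile()) {
  cohort_config(n_subjects = n_subjects, effects = effects, noise = noise,
                seed = seed)
}

# deterministic epoch_deltas with known values: rest/clench filled from a
# (scalar) function of (sample, channel)
synthetic_deltas <- function(rest_fun, clench_fun, subject = "sub-01") {
  rest <- outer(seq_len(600), seq_len(22), Vectorize(rest_fun))
  clench <- outer(seq_len(550), seq_len(22), Vectorize(clench_fun))
  sp <- list(rest = rest, clench = clench, baseline_mean = rep(0, 22))
  mask <- list(rest = matrix(FALSE, 600, 22), clench = matrix(FALSE, 550, 22))
  structure(list(subject_id = subject, oxy = sp, deoxy = sp,
                 mask = list(oxy = mask, deoxy = mask), stats = NULL),
            class = "epoch_deltas")
}

# separable toy image stack for classifier tests: class means 0.2 vs 0.8
toy_images <- function(n = 40, side = 64, noise_sd = 0.05, seed = 1) {
  set.seed(seed)
  labs <- rep(c("rest", "clench"), each = n / 2)
  imgs <- array(0, c(side, side, n))
  for (i in seq_len(n)) {
    imgs[, , i] <- ifelse(labs[i] == "clench", 0.8, 0.2) +
      matrix(stats::rnorm(side^2, 0, noise_sd), side, side)
  }
  list(images = imgs, labels = labs)
}
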