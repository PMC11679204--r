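# Shared fixture builders: everything is generated in code at test time.

# A small trial set with planted, strongly separable class structure:
# class c carries a large-amplitude sinusoid at a class-specific frequency
# on a class-specific channel, on top of weak white noise.
separable_trials <- function(n = 48, n_channels = 9, n_samples = 100,
                             fs = 100, snr = 6, seed = 1) {
  withr::with_seed(seed, {
    labels <- sample(rep_len(1:4, n))
    freqs <- c(6, 10, 14, 18)
    dat <- array(rnorm(n * n_channels * n_samples), c(n, n_channels, n_samples))
    t <- seq_len(n_samples) / fs
    for (i in seq_len(n)) {
      ch <- labels[i] * 2           # channels 2, 4, 6, 8
      dat[i, ch, ] <- dat[i, ch, ] +
        snr * sin(2 * pi * freqs[labels[i]] * t + runif(1, 0, 2 * pi))
    }
    trial_set(dat, labels, fs)
  })
}

# Uniform random trials with balanced labels (no class signal at all).
random_trials <- function(n = 64, n_channels = 9, n_samples = 64, fs = 64,
                          seed = 1) {
  withr::with_seed(seed, {
    dat <- array(rnorm(n * n_channels * n_samples), c(n, n_channels, n_samples))
    trial_set(dat, sample(rep_len(1:4, n)), fs)
  })
}

# Tiny preprocessed two-cohort world for transfer tests: short windows,
# decimated, LFCNN-compatible.
tiny_world <- function(n_source = 2, n_target = 2, n_trials = 12, seed = 3,
                       mixing = 0.3) {
  prof <- synthetic_profile(mixing_strength = mixing)
  cohorts <- make_cohort(n_source, n_target, prof, seed = seed,
                         n_trials = n_trials)
  shrink <- function(cohort) {
    for (i in seq_along(cohort$subjects)) {
      cohort$subjects[[i]]$sessions <-
        lapply(cohort$subjects[[i]]$sessions, function(s)
          decimate_trials(extract_window(s, 2, 2), 5))
    }
    cohort
  }
  list(source = shrink(cohorts$source), target = shrink(cohorts$target))
}
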