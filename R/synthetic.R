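# Synthetic motor-imagery EEG with ERD structure, 1/f background noise and
# per-subject spatial mixing. The generator emulates the statistical
# structure the classifier relies on: class-dependent attenuation of
# narrow-band rhythm power (event-related desynchronization, ERD) on
# class-specific channel subsets during the imagery interval.

#' Synthetic subject profile
#'
#' Describes the generative model for one subject's EEG. Each class `c`
#' owns a set of informative channels and a frequency band; on a class-`c`
#' trial the rhythm power in that band on those channels is attenuated by
#' the ERD depth during the imagery interval (2-6 s of a 7 s trial),
#' relative to baseline (0-2 s) and rest (6-7 s). All channels named by any
#' class carry the corresponding rhythm at all times; only its imagery-time
#' attenuation is class-dependent. Background activity is 1/f ("pink")
#' noise on every channel.
#'
#' @param class_channel_map List of 4 integer vectors: informative montage
#'   channels per class (1-based, defaults follow sensorimotor topography:
#'   left hand -> right hemisphere, right hand -> left hemisphere, feet ->
#'   midline, tongue -> lateral central).
#' @param band_specs List of 4 lists `(center, bw, erd)`: band center and
#'   width in Hz, ERD depth in `[0, 1]` (fraction of band power removed
#'   during imagery).
#' @param snr_db Rhythm-to-background power ratio in dB on an informative
#'   channel (default 10).
#' @param subject_seed Seed for the subject-specific spatial mixing.
#' @param mixing_strength In `[0, 1]`: magnitude of the subject's random
#'   orthonormal channel rotation (0 = identity; simulates inter-subject
#'   distribution shift).
#' @param drift_per_session In `[0, 1]`: magnitude of an additional rotation
#'   applied to session 2 (within-subject, between-session drift).
#' @param layout `"sensorimotor"` (default, 18 informative channels) or
#'   `"focal6"` (a compact layout whose classes share 6 informative
#'   channels in total, useful for channel-selection studies).
#' @return Object of class `synthetic_profile`.
#' @export
synthetic_profile <- function(class_channel_map = NULL,
                              band_specs = NULL,
                              snr_db = 10,
                              subject_seed = 1L,
                              mixing_strength = 0.3,
                              drift_per_session = 0.1,
                              layout = c("sensorimotor", "focal6")) {
  layout <- match.arg(layout)
  if (is.null(class_channel_map)) {
    class_channel_map <- if (layout == "sensorimotor") {
      list(
        c(6L, 11L, 12L, 13L, 18L),  # left hand  -> right hemisphere (FC4,C2,C4,C6,CP4)
        c(2L, 7L, 8L, 9L, 14L),     # right hand -> left hemisphere  (FC3,C5,C3,C1,CP3)
        c(4L, 10L, 16L, 20L),       # feet       -> midline          (FCz,Cz,CPz,Pz)
        c(9L, 11L, 15L, 17L)        # tongue     -> lateral central  (C1,C2,CP1,CP2)
      )
    } else {
      # 6 informative channels in total; classes 1-3 own disjoint mu-band
      # pairs, class 4 desynchronises the beta band over all six, so no
      # small channel subset can stand in for the full informative set.
      list(
        c(6L, 12L),                      # left hand,  mu band
        c(2L, 8L),                       # right hand, mu band
        c(10L, 16L),                     # feet,       mu band
        c(2L, 6L, 8L, 10L, 12L, 16L)    # tongue,     beta band
      )
    }
  }
  if (is.null(band_specs)) {
    band_specs <- list(
      list(center = 10, bw = 4, erd = 0.6),
      list(center = 10, bw = 4, erd = 0.6),
      list(center = if (layout == "focal6") 10 else 21,
           bw = if (layout == "focal6") 4 else 6, erd = 0.6),
      list(center = 21, bw = 6, erd = 0.6)
    )
  }
  assert_that(is.list(class_channel_map) && length(class_channel_map) == 4,
              "class_channel_map must list channels for the 4 classes")
  assert_that(all(vapply(class_channel_map, length, 1L) >= 1),
              "each class needs at least one informative channel")
  assert_that(is.list(band_specs) && length(band_specs) == 4,
              "band_specs must describe the 4 classes")
  for (b in band_specs) {
    assert_that(all(c("center", "bw", "erd") %in% names(b)),
                "each band spec needs center, bw, erd")
    assert_that(b$erd >= 0 && b$erd <= 1, "ERD depth must lie in [0, 1]")
    assert_that(b$center > 0 && b$bw > 0, "band center and width must be positive")
  }
  assert_that(is.finite(snr_db), "snr_db must be finite")
  assert_that(mixing_strength >= 0 && mixing_strength <= 1,
              "mixing_strength must lie in [0, 1]")
  assert_that(drift_per_session >= 0 && drift_per_session <= 1,
              "drift_per_session must lie in [0, 1]")
  structure(
    list(class_channel_map = lapply(class_channel_map, as.integer),
         band_specs = band_specs, snr_db = snr_db,
         subject_seed = as.integer(subject_seed),
         mixing_strength = mixing_strength,
         drift_per_session = drift_per_session),
    class = "synthetic_profile"
  )
}

#' Channels carrying class information under a profile
#' @param profile A `synthetic_profile`.
#' @return Sorted integer vector of informative channel indices.
#' @export
informative_channels <- function(profile) {
  sort(unique(unlist(profile$class_channel_map)))
}

# 1/f-shaped unit-variance noise, one column per signal.
pink_noise <- function(n_samples, n_cols, fs) {
  w <- matrix(stats::rnorm(n_samples * n_cols), n_samples, n_cols)
  f <- seq_len(n_samples) - 1
  f <- pmin(f, n_samples - f) * fs / n_samples
  amp <- ifelse(f > 0, 1 / sqrt(f), 0)
  x <- Re(stats::mvfft(stats::mvfft(w) * amp, inverse = TRUE)) / n_samples
  scale_cols_unit_sd(x)
}

# Narrow-band Gaussian noise centred on `center` Hz.
narrowband_noise <- function(n_samples, n_cols, fs, center, bw) {
  w <- matrix(stats::rnorm(n_samples * n_cols), n_samples, n_cols)
  f <- seq_len(n_samples) - 1
  f <- pmin(f, n_samples - f) * fs / n_samples
  amp <- exp(-0.5 * ((f - center) / (bw / 2))^2)
  x <- Re(stats::mvfft(stats::mvfft(w) * amp, inverse = TRUE)) / n_samples
  scale_cols_unit_sd(x)
}

scale_cols_unit_sd <- function(x) {
  s <- sqrt(colMeans(x^2) - colMeans(x)^2)
  s[s == 0] <- 1
  sweep(x, 2, s, "/")
}

# Random orthonormal rotation of the channel space: exp(angle * A) with A
# skew-symmetric, angle = strength * pi/2.
random_rotation <- function(n_channels, strength, seed) {
  if (strength == 0) return(diag(n_channels))
  with_local_seed(seed, {
    r <- matrix(stats::rnorm(n_channels^2), n_channels)
    a <- (r - t(r)) / 2
    a <- a / max(Mod(eigen(a, only.values = TRUE)$values))
    as.matrix(Matrix::expm(Matrix::Matrix(strength * (pi / 2) * a)))
  })
}

# Imagery-interval amplitude envelope with short cosine ramps.
erd_envelope <- function(n_samples, fs, trial_s, depth) {
  t <- (seq_len(n_samples) - 0.5) / fs
  g <- rep(1, n_samples)
  on <- 2; off <- min(6, trial_s); ramp <- 0.1
  w <- rep(0, n_samples)
  w[t >= on + ramp & t < off - ramp] <- 1
  ri <- t >= on & t < on + ramp
  w[ri] <- (1 - cos(pi * (t[ri] - on) / ramp)) / 2
  ro <- t >= off - ramp & t < off
  w[ro] <- (1 + cos(pi * (t[ro] - (off - ramp)) / ramp)) / 2
  sqrt(1 - depth * w)
}

#' Generate one subject's synthetic trials
#'
#' Deterministic for a fixed `(profile, seed)`. Trials are 7 s by default
#' (baseline 0-2 s, imagery 2-6 s, rest 6-7 s) over the 22-channel montage.
#' Classes are balanced up to remainder and shuffled.
#'
#' @param profile A [synthetic_profile()].
#' @param n_trials Number of trials (> 0).
#' @param fs Sampling rate in Hz (default 250).
#' @param trial_s Trial length in seconds (default 7).
#' @param seed Integer seed for the trial-level randomness.
#' @param session_id Session identifier stored on the result; session 2 (or
#'   higher) additionally receives the profile's per-session drift
#'   rotation.
#' @param subject_id Subject identifier stored on the result.
#' @return A [trial_set()] of dimension `n_trials x 22 x round(trial_s*fs)`.
#' @export
generate_subject <- function(profile, n_trials, fs = 250, trial_s = 7,
                             seed = 1L, session_id = 1L, subject_id = NA) {
  assert_that(inherits(profile, "synthetic_profile"),
              "profile must be a synthetic_profile")
  assert_that(is_count(n_trials), "n_trials must be a positive integer")
  assert_that(fs > 0 && trial_s > 0, "fs and trial_s must be positive")
  n_ch <- 22L
  n_samp <- as.integer(round(trial_s * fs))
  gen_seed <- derive_seed(seed, profile$subject_seed, session_id, "gen")

  labels <- with_local_seed(derive_seed(gen_seed, "labels"),
                            sample(rep_len(1:4, n_trials)))
  noise_sd <- 10^(-profile$snr_db / 20)

  dat <- with_local_seed(gen_seed, {
    # background 1/f noise: columns are (channel within trial) signals
    x <- pink_noise(n_samp, n_ch * n_trials, fs) * noise_sd
    dim(x) <- c(n_samp, n_ch, n_trials)
    # class rhythms
    for (cls in 1:4) {
      spec <- profile$band_specs[[cls]]
      chans <- profile$class_channel_map[[cls]]
      r <- narrowband_noise(n_samp, length(chans) * n_trials, fs,
                            spec$center, spec$bw)
      dim(r) <- c(n_samp, length(chans), n_trials)
      env <- erd_envelope(n_samp, fs, trial_s, spec$erd)
      hit <- labels == cls
      if (any(hit)) r[, , hit] <- r[, , hit] * env
      x[, chans, ] <- x[, chans, ] + r
    }
    x
  })

  mix <- random_rotation(n_ch, profile$mixing_strength,
                         derive_seed(profile$subject_seed, "mix"))
  if (session_id >= 2 && profile$drift_per_session > 0) {
    drift <- random_rotation(n_ch, profile$drift_per_session,
                             derive_seed(profile$subject_seed, "drift", session_id))
    mix <- drift %*% mix
  }
  dim(dat) <- c(n_samp, n_ch * n_trials)
  dat <- aperm(array(dat, c(n_samp, n_ch, n_trials)), c(2, 1, 3))
  dim(dat) <- c(n_ch, n_samp * n_trials)
  dat <- mix %*% dat
  dim(dat) <- c(n_ch, n_samp, n_trials)
  dat <- aperm(dat, c(3, 1, 2)) * 10 # arbitrary microvolt scale

  trial_set(dat, labels, fs, subject_id = subject_id,
            session_id = session_id, window = c(0, n_samp / fs))
}

#' Generate source and target cohorts
#'
#' Subjects differ by their spatial-mixing seeds (inter-subject shift);
#' each subject has two sessions, the second receiving the profile's
#' per-session drift. Roles mirror the common source/target split of
#' multi-subject transfer studies.
#'
#' @param n_source,n_target Numbers of source / target subjects (>= 1).
#' @param profile_family A [synthetic_profile()] used as template; each
#'   subject gets its own `subject_seed` derived from `seed`.
#' @param seed Integer base seed.
#' @param n_trials Trials per session (default 288, the benchmark session
#'   size).
#' @param fs,trial_s Sampling rate and trial length.
#' @return List with elements `source` and `target`, each a `cohort`:
#'   a list of subjects, each with `subject_id` and a list `sessions` of
#'   [trial_set()]s.
#' @export
make_cohort <- function(n_source, n_target, profile_family = synthetic_profile(),
                        seed = 1L, n_trials = 288, fs = 250, trial_s = 7) {
  assert_that(is_count(n_source) && is_count(n_target),
              "n_source and n_target must be positive integers")
  build <- function(ids, role) {
    subjects <- lapply(ids, function(sid) {
      prof <- profile_family
      prof$subject_seed <- derive_seed(seed, "subject", sid)
      sessions <- lapply(1:2, function(sess) {
        generate_subject(prof, n_trials, fs = fs, trial_s = trial_s,
                         seed = derive_seed(seed, sid, sess),
                         session_id = sess, subject_id = sid)
      })
      list(subject_id = sid, sessions = sessions)
    })
    structure(list(subjects = subjects, role = role), class = "cohort")
  }
  list(source = build(seq_len(n_source), "source"),
       target = build(n_source + seq_len(n_target), "target"))
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> role=%s, %d subjects x %d sessions\n",
              x$role, length(x$subjects),
              length(x$subjects[[1]]$sessions)))
  invisible(x)
}

#' Ids of the subjects in a cohort
#' @param cohort A `cohort`.
#' @export
cohort_subject_ids <- function(cohort) {
  vapply(cohort$subjects, function(s) s$subject_id, numeric(1))
}

#' All trials of one subject (sessions concatenated)
#' @param cohort A `cohort`.
#' @param subject_id Subject identifier.
#' @return A [trial_set()].
#' @export
cohort_subject_trials <- function(cohort, subject_id) {
  ids <- cohort_subject_ids(cohort)
  i <- match(subject_id, ids)
  assert_that(!is.na(i), sprintf("subject %s not in cohort", subject_id))
  bind_trials(cohort$subjects[[i]]$sessions)
}

#' Band power per trial and channel
#'
#' Mean periodogram power inside `band` (Hz), computed over the time range
#' `t_range` (seconds, relative to the trial-set window origin). Used by
#' the generator's validation oracles and available for feature inspection.
#'
#' @param trials A [trial_set()].
#' @param band Length-2 numeric `(lo, hi)` in Hz.
#' @param t_range Length-2 numeric in seconds, defaults to the full window.
#' @return Matrix `n_trials x n_channels` of band powers.
#' @export
trial_bandpower <- function(trials, band, t_range = NULL) {
  fs <- trials$fs
  d <- trials$data
  if (!is.null(t_range)) {
    i0 <- round((t_range[1]) * fs) + 1L
    i1 <- round((t_range[2]) * fs)
    d <- d[, , i0:i1, drop = FALSE]
  }
  nt <- dim(d)[1]; nc <- dim(d)[2]; ns <- dim(d)[3]
  m <- matrix(aperm(d, c(3, 2, 1)), ns, nc * nt)
  sp <- Mod(stats::mvfft(m))^2 / ns
  f <- (seq_len(ns) - 1) * fs / ns
  sel <- f >= band[1] & f <= band[2]
  bp <- colMeans(sp[sel, , drop = FALSE])
  t(matrix(bp, nc, nt))
}
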