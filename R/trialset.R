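# TrialSet: a cube of EEG trials with labels and acquisition metadata.

#' Construct a trial set
#'
#' A trial set holds a cube of EEG trials (trials x channels x samples, in
#' microvolts), one label per trial in 1..4 (left hand, right hand, feet,
#' tongue), the sampling rate, subject/session identity and the time window
#' the samples cover relative to trial onset.
#'
#' @param data Numeric array `[n_trials, n_channels, n_samples]`.
#' @param labels Integer vector of class labels in 1..4.
#' @param fs Sampling rate (Hz).
#' @param subject_id Subject identifier (integer or character).
#' @param session_id Session identifier.
#' @param window Numeric length-2 `(start_s, end_s)` relative to onset.
#' @param channel_ids 1-based montage indices of the retained channels.
#' @return Object of class `trial_set`.
#' @export
trial_set <- function(data, labels, fs, subject_id = NA, session_id = NA,
                      window = c(0, dim(data)[3] / fs),
                      channel_ids = seq_len(dim(data)[2])) {
  assert_that(is.array(data) && length(dim(data)) == 3,
              "data must be a 3-d array [trials x channels x samples]")
  n <- dim(data)[1]
  assert_that(length(labels) == n, "one label per trial required")
  labels <- as.integer(labels)
  assert_that(all(labels %in% 1:4), "labels must lie in 1..4")
  assert_that(is.numeric(fs) && fs > 0, "fs must be positive")
  assert_that(length(window) == 2 && window[2] > window[1],
              "window must be (start_s, end_s) with end > start")
  n_samp <- dim(data)[3]
  expect_samp <- round((window[2] - window[1]) * fs)
  assert_that(n_samp == expect_samp,
              sprintf("n_samples (%d) must equal round((end-start)*fs) = %d",
                      n_samp, expect_samp))
  assert_that(length(channel_ids) == dim(data)[2],
              "channel_ids must match channel dimension")
  storage.mode(data) <- "double"
  structure(
    list(data = data, labels = labels, fs = fs,
         subject_id = subject_id, session_id = session_id,
         window = as.numeric(window),
         channel_ids = as.integer(channel_ids)),
    class = "trial_set"
  )
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<trial_set> subject %s session %s: %d trials x %d channels x %d samples @ %g Hz, window [%g, %g] s\n",
    x$subject_id, x$session_id, d[1], d[2], d[3], x$fs,
    x$window[1], x$window[2]
  ))
  tab <- table(factor(x$labels, levels = 1:4))
  cat("  labels:", paste(sprintf("%d:%d", 1:4, tab), collapse = " "), "\n")
  invisible(x)
}

#' Number of trials in a trial set
#' @param trials A `trial_set`.
#' @export
n_trials <- function(trials) dim(trials$data)[1]

#' Extract a time window from every trial
#'
#' Cuts `[start_s, start_s + dur_s)` (relative to the trial-set's own time
#' origin) out of each trial. The output has `round(dur_s * fs)` samples;
#' labels and metadata are preserved.
#'
#' @param trials A `trial_set`.
#' @param start_s Window start in seconds, relative to the current window
#'   origin (trial onset for full trials).
#' @param dur_s Window duration in seconds.
#' @return A `trial_set` covering the requested window.
#' @export
extract_window <- function(trials, start_s, dur_s) {
  assert_that(inherits(trials, "trial_set"), "trials must be a trial_set")
  assert_that(dur_s > 0, "dur_s must be positive")
  fs <- trials$fs
  n_samp <- dim(trials$data)[3]
  i0 <- round(start_s * fs)
  len <- round(dur_s * fs)
  assert_that(i0 >= 0, "start_s must be non-negative")
  assert_that(i0 + len <= n_samp,
              sprintf("window [%g, %g] s exceeds trial length %g s",
                      start_s, start_s + dur_s, n_samp / fs))
  idx <- (i0 + 1L):(i0 + len)
  out <- trials$data[, , idx, drop = FALSE]
  trial_set(out, trials$labels, fs,
            subject_id = trials$subject_id, session_id = trials$session_id,
            window = trials$window[1] + c(start_s, start_s + dur_s),
            channel_ids = trials$channel_ids)
}

#' Decimate trials to a lower sampling rate
#'
#' Applies an ideal (FFT) low-pass at the new Nyquist frequency and keeps
#' every `factor`-th sample. Standard preprocessing when the rhythms of
#' interest (mu/beta, < 30 Hz) live far below the recording rate; reduces
#' classifier cost proportionally.
#'
#' @param trials A `trial_set`.
#' @param factor Integer decimation factor (>= 1); the sample count must
#'   be divisible by it.
#' @return A `trial_set` sampled at `fs / factor`.
#' @export
decimate_trials <- function(trials, factor) {
  assert_that(inherits(trials, "trial_set"), "trials must be a trial_set")
  assert_that(is_count(factor), "factor must be a positive integer")
  if (factor == 1L) return(trials)
  d <- dim(trials$data)
  ns <- d[3]
  assert_that(ns %% factor == 0,
              sprintf("sample count %d is not divisible by %d", ns, factor))
  m <- matrix(aperm(trials$data, c(3, 2, 1)), ns, d[2] * d[1])
  sp <- stats::mvfft(m)
  f <- pmin(seq_len(ns) - 1, ns - (seq_len(ns) - 1)) * trials$fs / ns
  sp[f >= trials$fs / (2 * factor), ] <- 0
  m <- Re(stats::mvfft(sp, inverse = TRUE)) / ns
  keep <- seq(1, ns, by = factor)
  out <- aperm(array(m[keep, ], c(length(keep), d[2], d[1])), c(3, 2, 1))
  trial_set(out, trials$labels, trials$fs / factor,
            subject_id = trials$subject_id, session_id = trials$session_id,
            window = trials$window, channel_ids = trials$channel_ids)
}

#' Drop channels outside a mask
#'
#' Retains only the channels selected by `mask`, in ascending printed-index
#' order. The mask is defined over the montage the trial set was recorded
#' with (its `channel_ids`).
#'
#' @param trials A `trial_set`.
#' @param mask A [channel_mask()] over the trial set's montage.
#' @return A `trial_set` with `mask_popcount(mask)` channels.
#' @export
drop_channels <- function(trials, mask) {
  assert_that(inherits(trials, "trial_set"), "trials must be a trial_set")
  assert_that(inherits(mask, "channel_mask"), "mask must be a channel_mask")
  bits <- unclass(mask)
  assert_that(length(bits) == dim(trials$data)[2],
              "mask length must equal the trial set's channel count")
  assert_that(any(bits), "mask must retain at least one channel")
  keep <- which(bits)
  trial_set(trials$data[, keep, , drop = FALSE], trials$labels, trials$fs,
            subject_id = trials$subject_id, session_id = trials$session_id,
            window = trials$window,
            channel_ids = trials$channel_ids[keep])
}

#' Concatenate trial sets along the trial axis
#'
#' All inputs must share channel count, sample count and sampling rate.
#' Metadata is taken from the first set; subject/session identifiers are
#' collapsed to `NA` when they differ.
#'
#' @param ... `trial_set` objects (or a single list of them).
#' @return A combined `trial_set`.
#' @export
bind_trials <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && !inherits(sets[[1]], "trial_set")) sets <- sets[[1]]
  assert_that(length(sets) >= 1, "no trial sets given")
  d0 <- dim(sets[[1]]$data)[-1]
  for (s in sets) {
    assert_that(inherits(s, "trial_set"), "all inputs must be trial_set")
    assert_that(identical(dim(s$data)[-1], d0) && s$fs == sets[[1]]$fs,
                "trial sets are not compatible")
  }
  dat <- array(0, c(sum(vapply(sets, n_trials, 1L)), d0))
  lab <- integer(0)
  at <- 0L
  for (s in sets) {
    k <- n_trials(s)
    dat[at + seq_len(k), , ] <- s$data
    lab <- c(lab, s$labels)
    at <- at + k
  }
  subj <- unique(vapply(sets, function(s) paste(s$subject_id), ""))
  sess <- unique(vapply(sets, function(s) paste(s$session_id), ""))
  trial_set(dat, lab, sets[[1]]$fs,
            subject_id = if (length(subj) == 1) sets[[1]]$subject_id else NA,
            session_id = if (length(sess) == 1) sets[[1]]$session_id else NA,
            window = sets[[1]]$window,
            channel_ids = sets[[1]]$channel_ids)
}

#' Subset trials by index
#' @param trials A `trial_set`.
#' @param idx Integer trial indices.
#' @return A `trial_set` with the selected trials.
#' @export
subset_trials <- function(trials, idx) {
  assert_that(all(idx >= 1 & idx <= n_trials(trials)), "trial index out of range")
  trial_set(trials$data[idx, , , drop = FALSE], trials$labels[idx], trials$fs,
            subject_id = trials$subject_id, session_id = trials$session_id,
            window = trials$window, channel_ids = trials$channel_ids)
}
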