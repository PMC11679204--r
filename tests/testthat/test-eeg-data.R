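# Montage, channel masks, trial-set operations and preprocessing.

test_that("montage describes the 22-channel 10-20 layout", {
  m <- montage_info()
  expect_length(m$channel_ids, 22)
  expect_length(m$channel_names, 22)
  expect_equal(m$fs, 250)
  expect_true(all(c("Cz", "C3", "C4", "Fz", "Pz") %in% m$channel_names))
  expect_error(montage_info(fs = -1), "positive")
})

test_that("printed channel lists parse and format round-trip", {
  # published selection for one subject: 12 channels retained
  mask <- parse_channel_list("[3,8,10,11,13,15,16,18-22]")
  expect_equal(mask_popcount(mask), 12)
  expect_equal(which(unclass(mask)),
               c(3, 8, 10, 11, 13, 15, 16, 18, 19, 20, 21, 22))
  expect_equal(format_channel_mask(mask), "3,8,10-11,13,15-16,18-22")
  # en-dash as printed in tables
  expect_equal(which(unclass(parse_channel_list("3,10,13,14,17,19–22"))),
               c(3, 10, 13, 14, 17, 19, 20, 21, 22))
  # arbitrary masks round-trip through the printed notation
  withr::with_seed(5, {
    for (i in 1:20) {
      ids <- sort(sample(22, sample(1:22, 1)))
      txt <- format_channel_mask(channel_mask(ids))
      expect_equal(which(unclass(parse_channel_list(txt))), ids)
    }
  })
  expect_error(channel_mask(integer(0)), "non-empty")
  expect_error(channel_mask(23), "1..22")
  expect_error(parse_channel_list(""), "empty")
})

test_that("mask files round-trip", {
  path <- tempfile()
  mask <- channel_mask(c(1, 5, 9, 10, 11, 22))
  write_channel_mask(mask, path)
  expect_equal(read_channel_mask(path), mask)
})

test_that("trial_set validates its invariants", {
  dat <- array(0, c(3, 22, 100))
  expect_error(trial_set(dat, c(1, 2, 5), fs = 100), "1..4")
  expect_error(trial_set(dat, c(1, 2), fs = 100), "one label per trial")
  expect_error(trial_set(dat, c(1, 2, 3), fs = 250, window = c(0, 1)),
               "round")
  ts <- trial_set(dat, c(1, 2, 3), fs = 100)
  expect_s3_class(ts, "trial_set")
  expect_equal(n_trials(ts), 3)
})

test_that("windowing yields round(dur * fs) samples for arbitrary rates", {
  withr::with_seed(2, {
    for (i in 1:15) {
      fs <- sample(c(50, 100, 128, 250), 1)
      trial_s <- sample(2:7, 1)
      dat <- array(rnorm(2 * 4 * trial_s * fs), c(2, 4, trial_s * fs))
      ts <- trial_set(dat, c(1, 3), fs)
      start <- runif(1, 0, trial_s / 2)
      dur <- runif(1, 0.2, trial_s - start)
      w <- extract_window(ts, start, dur)
      expect_equal(dim(w$data)[3], round(dur * fs))
      expect_equal(w$labels, ts$labels)
    }
  })
})

test_that("a full-length window is the identity and bad windows error", {
  ts <- random_trials(n = 4, n_samples = 80, fs = 40)
  w <- extract_window(ts, 0, 2)
  expect_equal(w$data, ts$data)
  expect_error(extract_window(ts, 3, 1), "exceeds")
  expect_error(extract_window(ts, 0, 3), "exceeds")
})

test_that("drop_channels keeps masked channels in printed order", {
  ts <- random_trials(n = 3, n_channels = 22, n_samples = 50, fs = 50)
  mask <- parse_channel_list("3,8,10,11,13,15,16,18-22")
  out <- drop_channels(ts, mask)
  expect_equal(dim(out$data)[2], 12)
  expect_equal(out$channel_ids, which(unclass(mask)))
  # identity and single-channel cases
  expect_equal(drop_channels(ts, channel_mask(rep(TRUE, 22)))$data, ts$data)
  one <- drop_channels(ts, channel_mask(1))
  expect_equal(one$data[, 1, ], ts$data[, 1, ])
  expect_error(drop_channels(ts, channel_mask(rep(FALSE, 22))), "at least one")
})

test_that("composed channel drops equal the conjunction mask", {
  ts <- random_trials(n = 2, n_channels = 22, n_samples = 40, fs = 40)
  withr::with_seed(7, {
    for (i in 1:10) {
      a <- sort(sample(22, sample(5:20, 1)))
      b_rel <- sort(sample(length(a), sample(1:length(a), 1)))
      step1 <- drop_channels(ts, channel_mask(a))
      step2 <- drop_channels(step1, channel_mask(b_rel, n_channels = length(a)))
      direct <- drop_channels(ts, channel_mask(a[b_rel]))
      expect_equal(step2$data, direct$data)
      expect_equal(step2$channel_ids, direct$channel_ids)
    }
  })
})

test_that("decimation lowers the rate and preserves slow content", {
  fs <- 200
  t <- seq_len(400) / fs
  sig <- sin(2 * pi * 5 * t)
  dat <- array(rep(sig, each = 2), c(1, 2, 400))
  ts <- trial_set(dat, 1, fs)
  dec <- decimate_trials(ts, 4)
  expect_equal(dec$fs, 50)
  expect_equal(dim(dec$data)[3], 100)
  # a 5 Hz tone is far below the new 25 Hz Nyquist: almost unchanged
  expect_gt(cor(dec$data[1, 1, ], sig[seq(1, 400, by = 4)]), 0.99)
})

test_that("bind and subset preserve structure", {
  a <- random_trials(n = 3, seed = 1)
  b <- random_trials(n = 5, seed = 2)
  ab <- bind_trials(a, b)
  expect_equal(n_trials(ab), 8)
  expect_equal(ab$labels, c(a$labels, b$labels))
  expect_equal(subset_trials(ab, 4:8)$data, b$data)
  expect_error(subset_trials(ab, 9), "out of range")
})
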