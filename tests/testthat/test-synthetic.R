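# Statistical structure of the synthetic ERD generator, checked against
# independent spectral oracles (periodogram band power, Welch tests).

test_that("generation is deterministic for a fixed seed", {
  prof <- synthetic_profile()
  a <- generate_subject(prof, 6, seed = 9)
  b <- generate_subject(prof, 6, seed = 9)
  expect_identical(a$data, b$data)
  expect_identical(a$labels, b$labels)
  c <- generate_subject(prof, 6, seed = 10)
  expect_false(identical(a$data, c$data))
})

test_that("classes are balanced up to remainder", {
  prof <- synthetic_profile()
  ts <- generate_subject(prof, 10, seed = 1)
  expect_true(all(abs(table(factor(ts$labels, levels = 1:4)) - 2.5) <= 0.5))
})

test_that("zero ERD depth removes all class information in band power", {
  specs <- lapply(1:4, function(i)
    list(center = c(10, 10, 21, 21)[i], bw = c(4, 4, 6, 6)[i], erd = 0))
  prof <- synthetic_profile(band_specs = specs, mixing_strength = 0)
  ts <- generate_subject(prof, 200, seed = 4)
  ch <- prof$class_channel_map[[1]]
  bp <- rowMeans(trial_bandpower(ts, c(8, 12), c(2, 6))[, ch, drop = FALSE])
  # Welch test: class-1 trials vs the rest, alpha = 0.01
  p <- t.test(log(bp[ts$labels == 1]), log(bp[ts$labels != 1]))$p.value
  expect_gt(p, 0.01)
})

test_that("ERD attenuates imagery-interval band power on informative channels", {
  prof <- synthetic_profile(mixing_strength = 0)  # depth 0.6, snr 10 dB
  ts <- generate_subject(prof, 60, seed = 8)
  ch <- prof$class_channel_map[[2]]
  hit <- ts$labels == 2
  bp_im <- rowMeans(trial_bandpower(ts, c(8, 12), c(2, 6))[, ch, drop = FALSE])
  bp_bl <- rowMeans(trial_bandpower(ts, c(8, 12), c(0, 2))[, ch, drop = FALSE])
  ratio <- bp_im[hit] / bp_bl[hit]
  expect_gte(mean(ratio < 1), 0.95)
  # the attenuation is class-specific: other-class trials stay near 1
  expect_lt(mean(ratio), mean(bp_im[!hit] / bp_bl[!hit]))
})

test_that("without mixing, class information lives only on declared channels", {
  prof <- synthetic_profile(layout = "focal6", mixing_strength = 0)
  ts <- generate_subject(prof, 160, seed = 5)
  info <- informative_channels(prof)
  bp <- trial_bandpower(ts, c(8, 12), c(2, 6))
  pvals <- vapply(seq_len(22), function(ch) {
    stats::anova(stats::lm(log(bp[, ch]) ~ factor(ts$labels)))[["Pr(>F)"]][1]
  }, numeric(1))
  # strong effects on the mu-band informative channels ...
  mu_info <- sort(unique(unlist(prof$class_channel_map[1:3])))
  expect_true(all(pvals[mu_info] < 1e-4))
  # ... and none detectable on uninformative channels at alpha 0.001
  expect_true(all(pvals[setdiff(1:22, info)] > 0.001))
})

test_that("cohorts have the requested structure and reproducible content", {
  prof <- synthetic_profile()
  co <- make_cohort(3, 2, prof, seed = 6, n_trials = 4, trial_s = 2)
  expect_equal(co$source$role, "source")
  expect_equal(co$target$role, "target")
  expect_equal(cohort_subject_ids(co$source), 1:3)
  expect_equal(cohort_subject_ids(co$target), 4:5)
  expect_length(co$source$subjects[[1]]$sessions, 2)
  co2 <- make_cohort(3, 2, prof, seed = 6, n_trials = 4, trial_s = 2)
  expect_identical(co$target$subjects[[1]]$sessions[[2]]$data,
                   co2$target$subjects[[1]]$sessions[[2]]$data)
  # subjects differ (different mixing), sessions differ (drift + new draws)
  expect_false(identical(co$source$subjects[[1]]$sessions[[1]]$data,
                         co$source$subjects[[2]]$sessions[[1]]$data))
})

test_that("zero mixing strength leaves source and target channels unmixed", {
  prof0 <- synthetic_profile(mixing_strength = 0, drift_per_session = 0)
  co <- make_cohort(1, 1, prof0, seed = 2, n_trials = 30, trial_s = 2)
  # informative channels carry rhythm power in both cohorts; an
  # uninformative channel has comparable (pure-noise) power in both
  bp_s <- trial_bandpower(cohort_subject_trials(co$source, 1), c(8, 12))
  bp_t <- trial_bandpower(cohort_subject_trials(co$target, 2), c(8, 12))
  info <- informative_channels(prof0)
  expect_gt(mean(bp_s[, info]) / mean(bp_s[, -info]), 3)
  expect_gt(mean(bp_t[, info]) / mean(bp_t[, -info]), 3)
})
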