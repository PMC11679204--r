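# Leave-one-subject-out pre-training and classifier selection criteria.

test_that("LOSO yields one classifier per tested source subject", {
  w <- tiny_world(n_source = 3, n_trials = 8, seed = 2)
  cfg <- train_config(epochs = 0, batch_size = 8, seed = 1)
  cls <- loso_pretrain(w$source, model_variant("LFCNN"), cfg)
  expect_length(cls, 3)
  expect_equal(vapply(cls, function(x) x$tested_source_subject, numeric(1)),
               1:3)
  expect_true(all(vapply(cls, function(x) mask_popcount(x$mask), numeric(1)) == 22))
  # two subjects, one variant -> two classifiers
  w2 <- tiny_world(n_source = 2, n_trials = 8, seed = 3)
  expect_length(loso_pretrain(w2$source, model_variant("LFCNN"), cfg), 2)
})

test_that("single-subject cohorts are rejected", {
  w <- tiny_world(n_source = 2, n_trials = 8, seed = 4)
  w$source$subjects <- w$source$subjects[1]
  expect_error(loso_pretrain(w$source, model_variant("LFCNN"),
                             train_config(epochs = 0)),
               "at least 2")
})

test_that("masks from the provider are applied per tested subject", {
  w <- tiny_world(n_source = 2, n_trials = 8, seed = 5)
  masks <- list(`1` = channel_mask(1:12), `2` = channel_mask(5:16))
  cls <- loso_pretrain(w$source, model_variant("LFCNN", TRUE),
                       train_config(epochs = 0, seed = 1),
                       mask_provider = function(sid) masks[[as.character(sid)]])
  expect_equal(cls[[1]]$mask, masks[["1"]])
  expect_equal(cls[[1]]$model$arch$C, 12)
  expect_equal(cls[[2]]$model$arch$C, 12)
})

test_that("trained LOSO classifiers perform at least near chance", {
  w <- tiny_world(n_source = 2, n_trials = 12, seed = 6)
  cfg <- train_config(learning_rate = 5e-3, epochs = 4, batch_size = 16,
                      seed = 2)
  cls <- loso_pretrain(w$source, model_variant("LFCNN"), cfg)
  n_test <- 48   # 2 sessions x 12 trials... per held-out subject
  for (cl in cls) {
    # chance 0.25; allow 3 sigma below for the binomial draw
    expect_gte(cl$accuracy_on_tested_subject,
               0.25 - 3 * sqrt(0.25 * 0.75 / n_test))
  }
})

test_that("the two published selection criteria pick the right subjects", {
  # published cross-subject accuracies (%), subjects 1..6, one model family
  no_cs <- c(`1` = 72.92, `2` = 53.71, `3` = 84.16, `4` = 57.76,
             `5` = 57.43, `6` = 61.06)
  cs <- c(`1` = 77.98, `2` = 53.53, `3` = 85.45, `4` = 55.10,
          `5` = 58.74, `6` = 61.52)
  pick <- pick_classifiers(no_cs, cs)
  expect_equal(pick$best, 3)                       # 85.45 with selection
  expect_equal(pick$best_accuracy, 85.45)
  expect_equal(pick$most_improved, 1)              # +5.06 from selection
  expect_equal(pick$improvement, 5.06, tolerance = 1e-9)
  # invariant to input ordering
  ord <- c(4, 2, 6, 1, 5, 3)
  pick2 <- pick_classifiers(no_cs[ord], cs[ord])
  expect_equal(pick2[c("best", "most_improved")],
               pick[c("best", "most_improved")])
})

test_that("ties break toward the lower subject id and mismatches error", {
  eq <- c(`1` = 0.5, `2` = 0.5, `3` = 0.5)
  pick <- pick_classifiers(eq, eq)
  expect_equal(pick$best, 1)
  expect_equal(pick$most_improved, 1)
  # all-negative improvement still returns the least negative
  no_cs <- c(`1` = 0.6, `2` = 0.7)
  cs <- c(`1` = 0.55, `2` = 0.6)
  expect_equal(pick_classifiers(no_cs, cs)$most_improved, 1)
  expect_error(pick_classifiers(no_cs, c(`1` = 0.5, `3` = 0.5)), "different")
})

test_that("classifier bundles round-trip through disk", {
  w <- tiny_world(n_source = 2, n_trials = 8, seed = 7)
  cls <- loso_pretrain(w$source, model_variant("LFCNN", TRUE),
                       train_config(epochs = 0, seed = 1),
                       mask_provider = function(sid) channel_mask(2:14))[[1]]
  dir <- tempfile()
  save_classifier(cls, dir)
  back <- load_classifier(dir)
  expect_identical(back$model$params, cls$model$params)
  expect_equal(back$mask, cls$mask)
  expect_equal(back$tested_source_subject, cls$tested_source_subject)
  expect_equal(back$variant$uses_channel_selection, TRUE)
})
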