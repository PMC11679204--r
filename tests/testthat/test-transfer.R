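# Session divisions, schedules, the online prequential loop and reporting.

test_that("the nominal 600-trial divisions match the published boundaries", {
  six <- make_divisions(600, "six")
  expect_equal(six$boundaries,
               list(c(0, 90), c(90, 180), c(180, 270), c(270, 360),
                    c(360, 450), c(450, 600)))
  four <- make_divisions(600, "four")
  expect_equal(four$boundaries,
               list(c(0, 140), c(140, 280), c(280, 420), c(420, 600)))
})

test_that("other trial counts split equally with the remainder last", {
  d <- make_divisions(4, "four")
  expect_equal(d$boundaries, list(c(0, 1), c(1, 2), c(2, 3), c(3, 4)))
  d2 <- make_divisions(23, "four")
  expect_equal(d2$boundaries, list(c(0, 5), c(5, 10), c(10, 15), c(15, 23)))
  expect_error(make_divisions(3, "four"), "at least 4")
  expect_error(make_divisions(10, "custom", list(c(0, 4), c(5, 10))), "cover")
})

test_that("schedules alternate subjects within each division", {
  sch <- build_schedule(c(7, 8, 9), make_divisions(600, "four"))
  expect_equal(nrow(sch), 12)
  expect_equal(sch$subject_id[1:3], c(7, 8, 9))
  expect_equal(sch$division[1:3], c(1, 1, 1))
  expect_equal(sch$subject_id, rep(c(7, 8, 9), 4))
  expect_equal(sch$start[1:3], c(0, 0, 0))
  # two targets, six divisions -> 12 alternating entries
  sch2 <- build_schedule(c(7, 8), make_divisions(600, "six"))
  expect_equal(nrow(sch2), 12)
  expect_equal(sch2$subject_id, rep(c(7, 8), 6))
  # single target: sequential sessions
  sch1 <- build_schedule(5, make_divisions(20, "four"))
  expect_equal(sch1$subject_id, rep(5, 4))
  expect_error(build_schedule(numeric(0), make_divisions(20, "four")),
               "at least one")
})

test_that("session duration arithmetic reproduces the published minutes", {
  expect_equal(session_minutes(140, 7), 17)
  expect_equal(session_minutes(90, 7), 11)
  expect_equal(session_minutes(60, 1), 1)
})

test_that("group averages are exact arithmetic means", {
  acc <- c(`7` = 0.8, `8` = 0.9, `9` = 0.7)
  av <- group_averages(acc)
  expect_equal(av$all, 0.8)
  expect_equal(av$pair_7_8, 0.85)
  expect_equal(av$pair_8_9, 0.8)
  expect_equal(av$pair_7_9, 0.75)
  expect_equal(group_averages(c(`7` = 0.63))$all, 0.63)
  expect_error(group_averages(acc, target_ids = c(7, 11)), "unknown")
  # published per-subject row: 72.63 / 81.68 / 73.05 averages to 75.79
  pub <- c(`7` = 72.63, `8` = 81.68, `9` = 73.05)
  expect_equal(round(group_averages(pub)$all, 2), 75.79)
  expect_equal(round(group_averages(pub)$pair_7_8, 3), 77.155)
})

test_that("with zero epochs every entry scores the pretrained accuracy", {
  w <- tiny_world(n_source = 2, n_target = 2, n_trials = 8, seed = 9)
  cls <- loso_pretrain(w$source, model_variant("LFCNN"),
                       train_config(epochs = 0, seed = 1))[[1]]
  ids <- cohort_subject_ids(w$target)
  nt <- n_trials(cohort_subject_trials(w$target, ids[1]))
  sch <- build_schedule(ids, make_divisions(nt, "four"))
  rep0 <- online_tl_run(cls, w$target, sch,
                        tl_config(epochs = 0, warmup_epochs = 0, n_runs = 1))
  expect_equal(nrow(rep0$per_entry), 8)    # 2 targets x 4 divisions
  for (sid in ids) {
    tr <- cohort_subject_trials(w$target, sid)
    direct <- model_accuracy(cls$model, tr)
    expect_equal(unname(rep0$per_subject[as.character(sid)]), direct)
  }
})

test_that("the prequential loop records per-entry accuracies and saves on improvement", {
  w <- tiny_world(n_source = 2, n_target = 2, n_trials = 8, seed = 10)
  cls <- loso_pretrain(w$source, model_variant("LFCNN"),
                       train_config(epochs = 0, seed = 2))[[1]]
  ids <- cohort_subject_ids(w$target)
  nt <- n_trials(cohort_subject_trials(w$target, ids[1]))
  sch <- build_schedule(ids, make_divisions(nt, "four"))
  rep1 <- suppressWarnings(
    online_tl_run(cls, w$target, sch,
                  tl_config(freeze_level = 44, learning_rate = "LR1",
                            epochs = 2, warmup_epochs = 1, n_runs = 2,
                            batch_size = 8, seed = 5)))
  expect_equal(nrow(rep1$per_entry), 2 * 8)       # runs x entries
  expect_true(all(rep1$per_entry$prequential_accuracy >= 0 &
                    rep1$per_entry$prequential_accuracy <= 1))
  # save-if-improved: persisted monitored accuracies are strictly increasing
  for (r in unique(rep1$saved_log$run)) {
    seqs <- rep1$saved_log$monitor_accuracy[rep1$saved_log$run == r]
    expect_true(all(diff(seqs) > 0))
  }
  # per-subject aggregates are trial-weighted means of per-entry records
  e <- rep1$per_entry[rep1$per_entry$subject_id == ids[1], ]
  manual <- sum(e$prequential_accuracy * e$n_trials) / sum(e$n_trials)
  expect_equal(unname(rep1$per_subject[as.character(ids[1])]), manual)
})

test_that("frozen entries are bit-identical through the online loop", {
  w <- tiny_world(n_source = 2, n_target = 1, n_trials = 8, seed = 11)
  cls <- loso_pretrain(w$source, model_variant("LFCNN"),
                       train_config(epochs = 0, seed = 3))[[1]]
  ids <- cohort_subject_ids(w$target)
  nt <- n_trials(cohort_subject_trials(w$target, ids[1]))
  sch <- build_schedule(ids, make_divisions(nt, "four"))
  snapshots <- list()
  hook <- function(model, i) {
    snapshots[[i]] <<- model$params
    model
  }
  reg <- cls$model$registry
  frozen_keys <- as.character(reg$index[reg$index <= 26 & reg$param_count > 0])
  suppressWarnings(
    online_tl_run(cls, w$target, sch,
                  tl_config(freeze_level = 26, epochs = 1, warmup_epochs = 1,
                            n_runs = 1, batch_size = 8, seed = 6),
                  entry_hook = hook))
  for (snap in snapshots) {
    for (key in frozen_keys) {
      expect_identical(snap[[key]], cls$model$params[[key]])
    }
  }
})

test_that("pseudo-label mode trains on the model's own predictions", {
  w <- tiny_world(n_source = 2, n_target = 1, n_trials = 8, seed = 12)
  cls <- loso_pretrain(w$source, model_variant("LFCNN"),
                       train_config(epochs = 0, seed = 4))[[1]]
  ids <- cohort_subject_ids(w$target)
  nt <- n_trials(cohort_subject_trials(w$target, ids[1]))
  sch <- build_schedule(ids, make_divisions(nt, "four"))
  rep_p <- suppressWarnings(
    online_tl_run(cls, w$target, sch,
                  tl_config(epochs = 1, warmup_epochs = 1, n_runs = 1,
                            label_mode = "pseudo", batch_size = 8, seed = 7)))
  expect_equal(nrow(rep_p$per_entry), 4)
})

test_that("schedules beyond a subject's trial count are rejected", {
  w <- tiny_world(n_source = 2, n_target = 1, n_trials = 8, seed = 13)
  cls <- loso_pretrain(w$source, model_variant("LFCNN"),
                       train_config(epochs = 0, seed = 5))[[1]]
  sch <- build_schedule(cohort_subject_ids(w$target),
                        make_divisions(999, "four"))
  expect_error(online_tl_run(cls, w$target, sch, tl_config(epochs = 0)),
               "exceeds")
})
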