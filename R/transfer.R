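# Edge-side online transfer learning: session divisions, the
# subject-alternating schedule, and the prequential predict-then-update
# loop with warm-up, freezing, and save-if-improved semantics.

#' Session-based division of a subject's trials
#'
#' For the nominal 600-trial protocol the published boundaries are
#' reproduced exactly: six divisions (0-90, 90-180, 180-270, 270-360,
#' 360-450, 450-600) or four (0-140, 140-280, 280-420, 420-600). For other
#' trial counts, equal-size ranges are used with the remainder absorbed by
#' the last range (consistent with the published pattern, where the last
#' range is the largest).
#'
#' @param n_trials Total trials available (at least one per division).
#' @param scheme_name `"six"`, `"four"`, or `"custom"`.
#' @param boundaries For `"custom"`: a list of `c(start, end)` half-open
#'   0-based ranges covering `[0, n_trials)`.
#' @return Object of class `division_scheme`: list with `name` and
#'   `boundaries` (list of half-open 0-based `c(start, end)` pairs).
#' @export
make_divisions <- function(n_trials, scheme_name = c("six", "four", "custom"),
                           boundaries = NULL) {
  scheme_name <- match.arg(scheme_name)
  assert_that(is_count(n_trials), "n_trials must be a positive integer")
  if (scheme_name == "custom") {
    assert_that(!is.null(boundaries), "custom scheme needs boundaries")
  } else {
    k <- if (scheme_name == "six") 6L else 4L
    assert_that(n_trials >= k,
                sprintf("need at least %d trials for %s divisions", k, scheme_name))
    boundaries <- if (n_trials == 600L) {
      if (k == 6L) {
        list(c(0, 90), c(90, 180), c(180, 270), c(270, 360), c(360, 450),
             c(450, 600))
      } else {
        list(c(0, 140), c(140, 280), c(280, 420), c(420, 600))
      }
    } else {
      size <- n_trials %/% k
      lapply(seq_len(k), function(i) {
        c((i - 1L) * size, if (i == k) n_trials else i * size)
      })
    }
  }
  # validate: disjoint, ordered, covering [0, n)
  b <- do.call(rbind, lapply(boundaries, as.numeric))
  assert_that(ncol(b) == 2 && all(b[, 2] > b[, 1]),
              "each range must be a half-open (start, end) pair")
  assert_that(b[1, 1] == 0 && b[nrow(b), 2] == n_trials &&
                all(b[-1, 1] == b[-nrow(b), 2]),
              "ranges must be ordered, disjoint and cover [0, n)")
  structure(list(name = scheme_name, boundaries = boundaries,
                 n_trials = as.integer(n_trials)),
            class = "division_scheme")
}

#' @export
print.division_scheme <- function(x, ...) {
  cat(sprintf("<division_scheme> %s over %d trials: %s\n", x$name, x$n_trials,
              paste(vapply(x$boundaries, function(b)
                sprintf("%d-%d", b[1], b[2]), ""), collapse = ", ")))
  invisible(x)
}

#' Subject-alternating retraining schedule
#'
#' Orders the (subject, division) pairs so that subjects alternate within
#' each division: for targets `(7, 8, 9)` and four divisions the schedule
#' is `(7,d1), (8,d1), (9,d1), (7,d2), ...` — each rehabilitation session
#' of each subject is trained in turn with the same shared model.
#'
#' @param target_ids Vector of target subject ids (non-empty).
#' @param divisions A [make_divisions()] scheme.
#' @return Object of class `tl_schedule`: data frame with columns
#'   `entry`, `subject_id`, `division`, `start`, `end` (half-open, 0-based).
#' @export
build_schedule <- function(target_ids, divisions) {
  assert_that(length(target_ids) >= 1, "at least one target required")
  assert_that(inherits(divisions, "division_scheme"), "divisions required")
  k <- length(target_ids)
  m <- length(divisions$boundaries)
  entries <- lapply(seq_len(k * m), function(i) {
    d <- (i - 1L) %/% k + 1L
    s <- (i - 1L) %% k + 1L
    b <- divisions$boundaries[[d]]
    data.frame(entry = i, subject_id = target_ids[s], division = d,
               start = b[1], end = b[2])
  })
  structure(do.call(rbind, entries), class = c("tl_schedule", "data.frame"))
}

#' Transfer-learning configuration
#'
#' The published strategy grid: freeze level in `{0, 6, 16, 26, 44}`,
#' learning rate in `{LR0 = 0.0009, LR1 = 0.0001, LR2 = 0.00009,
#' LR3 = 0.00001}`, epochs in `{30, 50, 100, 200}`, a 5-epoch warm-up for
#' each subject's first session, and 3 runs per experiment.
#'
#' @param freeze_level Registry prefix to freeze.
#' @param learning_rate Either a number or one of `"LR0".."LR3"`.
#' @param epochs Retraining epochs per session (after warm-up).
#' @param warmup_epochs Epochs for each subject's first session (default 5).
#' @param label_mode `"instructed"` (true cue labels, default) or
#'   `"pseudo"` (the model's own predictions).
#' @param n_runs Number of seeded repetitions (default 3).
#' @param batch_size Mini-batch size for retraining.
#' @param seed Base seed; run `r` uses `seed + r - 1`.
#' @return Object of class `tl_config`.
#' @export
tl_config <- function(freeze_level = 44, learning_rate = "LR1", epochs = 30,
                      warmup_epochs = 5, label_mode = c("instructed", "pseudo"),
                      n_runs = 3, batch_size = 64, seed = 1L) {
  if (is.character(learning_rate)) {
    learning_rate <- switch(match.arg(learning_rate,
                                      c("LR0", "LR1", "LR2", "LR3")),
                            LR0 = 9e-4, LR1 = 1e-4, LR2 = 9e-5, LR3 = 1e-5)
  }
  assert_that(learning_rate > 0, "learning_rate must be positive")
  assert_that(is.numeric(epochs) && epochs >= 0, "epochs must be >= 0")
  assert_that(is_count(n_runs), "n_runs must be >= 1")
  structure(list(freeze_level = as.integer(freeze_level),
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 warmup_epochs = as.integer(warmup_epochs),
                 label_mode = match.arg(label_mode),
                 n_runs = as.integer(n_runs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "tl_config")
}

#' Online multi-subject transfer learning
#'
#' Runs the prequential predict-then-update loop over the schedule: for
#' each entry, (1) the entry's trials are predicted with the currently
#' saved classifier and the prequential accuracy recorded, (2) the working
#' model is retrained on the subject's accumulated trials (5 warm-up
#' epochs for the subject's first entry, `tl_cfg$epochs` thereafter) at the
#' configured learning rate and freeze level, and (3) the retrained
#' weights are persisted as the new saved classifier only if the monitored
#' session-end accuracy improved on the best so far. The whole loop is
#' repeated `n_runs` times with consecutive seeds.
#'
#' @param pretrained A `pretrained_classifier` (from [loso_pretrain()]),
#'   or a bare `model_handle`.
#' @param targets A target `cohort`; each scheduled subject's sessions are
#'   concatenated and preprocessed with the classifier's mask and window.
#' @param schedule A [build_schedule()] result.
#' @param tl_cfg A [tl_config()].
#' @param entry_hook Optional diagnostic function
#'   `(model_handle, entry_index) -> model_handle` applied to the working
#'   model after each entry's update (used e.g. for lookahead audits).
#' @return Object of class `tl_report` — see [group_averages()]; fields:
#'   `per_entry` (data frame over runs x entries with prequential
#'   accuracies and wall times), `per_subject` (pooled prequential accuracy
#'   per subject, averaged over runs), `runs`, `saved_log`.
#' @export
online_tl_run <- function(pretrained, targets, schedule, tl_cfg,
                          entry_hook = NULL) {
  model0 <- if (inherits(pretrained, "pretrained_classifier")) {
    pretrained$model
  } else {
    pretrained
  }
  assert_that(inherits(model0, "model_handle"), "no model to transfer")
  mask <- if (inherits(pretrained, "pretrained_classifier")) pretrained$mask else NULL
  window <- if (inherits(pretrained, "pretrained_classifier")) pretrained$window else NULL

  subj_ids <- unique(schedule$subject_id)
  subj_data <- lapply(subj_ids, function(sid) {
    tr <- cohort_subject_trials(targets, sid)
    if (!is.null(window)) tr <- extract_window(tr, window[1], window[2])
    if (!is.null(mask)) tr <- drop_channels(tr, mask)
    d <- dim(tr$data)
    assert_that(d[2] == model0$arch$C && d[3] == model0$arch$T,
                sprintf("subject %s data (%d ch x %d samples) does not match the classifier (%d x %d); was it preprocessed with the classifier's mask?",
                        sid, d[2], d[3], model0$arch$C, model0$arch$T))
    assert_that(max(schedule$end[schedule$subject_id == sid]) <= n_trials(tr),
                sprintf("schedule exceeds subject %s trial count", sid))
    tr
  })
  names(subj_data) <- as.character(subj_ids)

  runs <- vector("list", tl_cfg$n_runs)
  for (run_i in seq_len(tl_cfg$n_runs)) {
    run_seed <- tl_cfg$seed + run_i - 1L
    model <- set_freeze_level(model0, tl_cfg$freeze_level)
    saved <- model                 # the classifier used for predictions
    best_monitor <- -Inf
    seen <- character(0)           # subjects already warm-started
    pool_idx <- stats::setNames(vector("list", length(subj_ids)),
                                as.character(subj_ids))
    pseudo_lab <- pool_idx
    per_entry <- NULL
    saved_log <- NULL
    for (i in seq_len(nrow(schedule))) {
      e <- schedule[i, ]
      sid <- as.character(e$subject_id)
      tr_all <- subj_data[[sid]]
      idx <- (e$start + 1L):e$end
      t0 <- proc.time()[3]
      entry_tr <- subset_trials(tr_all, idx)
      pred <- predict(saved, entry_tr)
      preq_acc <- mean(pred$labels == entry_tr$labels)
      # accumulate the subject's predicted trials
      pool_idx[[sid]] <- c(pool_idx[[sid]], idx)
      pool_tr <- subset_trials(tr_all, pool_idx[[sid]])
      if (tl_cfg$label_mode == "pseudo") {
        # labels the saved classifier assigned when each block was first seen
        pseudo_lab[[sid]] <- c(pseudo_lab[[sid]], pred$labels)
        pool_tr$labels <- pseudo_lab[[sid]]
      }
      first_time <- !(sid %in% seen)
      seen <- union(seen, sid)
      ep <- if (first_time) tl_cfg$warmup_epochs else tl_cfg$epochs
      monitor_acc <- NA_real_
      if (ep > 0) {
        cfg <- train_config(learning_rate = tl_cfg$learning_rate, epochs = ep,
                            batch_size = tl_cfg$batch_size,
                            seed = derive_seed(run_seed, "entry", i),
                            checkpoint = "best")
        fit <- train_model(model, pool_tr, cfg)
        model <- fit$model
        # monitored performance at session end: accuracy on this entry's trials
        monitor_acc <- mean(predict(model, entry_tr)$labels == entry_tr$labels)
        if (monitor_acc > best_monitor) {
          best_monitor <- monitor_acc
          saved <- model
          saved_log <- rbind(saved_log,
                             data.frame(run = run_i, entry = i,
                                        monitor_accuracy = monitor_acc))
        }
      }
      if (!is.null(entry_hook)) model <- entry_hook(model, i)
      per_entry <- rbind(per_entry, data.frame(
        run = run_i, entry = i, subject_id = e$subject_id,
        division = e$division, n_trials = length(idx),
        prequential_accuracy = preq_acc,
        monitor_accuracy = monitor_acc,
        wall_s = proc.time()[3] - t0))
    }
    runs[[run_i]] <- list(per_entry = per_entry, saved_log = saved_log)
  }

  all_entries <- do.call(rbind, lapply(runs, `[[`, "per_entry"))
  # pooled (trial-weighted) prequential accuracy per subject and run
  agg <- stats::aggregate(
    cbind(correct = prequential_accuracy * n_trials, n = n_trials) ~
      run + subject_id, data = all_entries, FUN = sum)
  agg$accuracy <- agg$correct / agg$n
  per_subject <- stats::aggregate(accuracy ~ subject_id, data = agg, FUN = mean)
  structure(
    list(per_entry = all_entries,
         per_subject = stats::setNames(per_subject$accuracy,
                                       per_subject$subject_id),
         per_run_subject = agg[, c("run", "subject_id", "accuracy")],
         saved_log = do.call(rbind, lapply(runs, `[[`, "saved_log")),
         config = tl_cfg, n_runs = tl_cfg$n_runs),
    class = "tl_report"
  )
}

#' @export
print.tl_report <- function(x, ...) {
  cat(sprintf("<tl_report> %d runs x %d entries; freeze %d, lr %g, epochs %d\n",
              x$n_runs, max(x$per_entry$entry), x$config$freeze_level,
              x$config$learning_rate, x$config$epochs))
  cat("  per-subject prequential accuracy:\n")
  print(round(x$per_subject, 4))
  cat(sprintf("  mean over subjects: %.4f\n", mean(x$per_subject)))
  invisible(x)
}

#' Group averages of per-subject accuracies
#'
#' Arithmetic means over the full target set and every subject pair,
#' mirroring the grouping used in multi-subject evaluation tables
#' ("AVG All", "AVG 78", ...).
#'
#' @param report A `tl_report`, or a named numeric vector of per-subject
#'   accuracies.
#' @param target_ids Subject ids to average over (default: all present).
#' @return Named list: `all`, then one entry per pair (`pair_7_8`, ...).
#' @export
group_averages <- function(report, target_ids = NULL) {
  acc <- if (inherits(report, "tl_report")) report$per_subject else report
  assert_that(!is.null(names(acc)), "per-subject accuracies must be named")
  if (is.null(target_ids)) target_ids <- names(acc)
  target_ids <- as.character(target_ids)
  assert_that(all(target_ids %in% names(acc)),
              sprintf("unknown subject(s): %s",
                      paste(setdiff(target_ids, names(acc)), collapse = ", ")))
  acc <- acc[target_ids]
  out <- list(all = mean(acc))
  if (length(acc) >= 2) {
    cmb <- utils::combn(target_ids, 2)
    for (j in seq_len(ncol(cmb))) {
      out[[paste0("pair_", cmb[1, j], "_", cmb[2, j])]] <-
        mean(acc[cmb[, j]])
    }
  }
  out
}

#' Transfer-learning direction study on synthetic shifted targets
#'
#' Evaluates whether the online transfer-learning protocol improves over
#' the frozen pre-trained classifier when target subjects are drawn from a
#' shifted distribution (per-subject spatial mixing). One classifier is
#' pre-trained on a synthetic source cohort; each replicate then draws a
#' fresh set of shifted target subjects and runs (a) the online loop with
#' the published best strategy (freeze level 44, four divisions, LR1,
#' 30 epochs, 5 warm-up epochs) and (b) a no-update baseline (0 epochs),
#' recording the mean prequential accuracy of both.
#'
#' @param seed Integer base seed.
#' @param n_replicates Number of paired replicates (default 5).
#' @param n_source,n_target Numbers of source training subjects and of
#'   target subjects per replicate (defaults 2 and 2).
#' @param n_trials Trials per session and subject (default 24; two
#'   sessions are concatenated per subject).
#' @param window,decimate Preprocessing applied to every session.
#' @param pretrain_epochs Source-side training length.
#' @param tl Optional [tl_config()] override for the TL arm.
#' @param mixing_strength Inter-subject shift magnitude (default 0.3).
#' @return Data frame with one row per replicate: `tl` and `baseline`
#'   mean prequential accuracies over target subjects, plus the
#'   source-validation accuracy of the shared pre-trained classifier as
#'   attribute `source_accuracy`.
#' @export
tl_direction_study <- function(seed, n_replicates = 5, n_source = 2,
                               n_target = 2, n_trials = 32,
                               window = c(2, 2), decimate = 5,
                               pretrain_epochs = 80, tl = NULL,
                               mixing_strength = 0.3) {
  prof <- synthetic_profile(mixing_strength = mixing_strength)
  preproc <- function(cohort) {
    for (i in seq_along(cohort$subjects)) {
      cohort$subjects[[i]]$sessions <-
        lapply(cohort$subjects[[i]]$sessions, function(s) {
          decimate_trials(extract_window(s, window[1], window[2]), decimate)
        })
    }
    cohort
  }
  # one shared pre-trained classifier: trained on the source subjects,
  # validated on one extra held-out source subject
  src <- preproc(make_cohort(n_source + 1, 1, prof,
                             seed = derive_seed(seed, "src"),
                             n_trials = n_trials)$source)
  ids <- cohort_subject_ids(src)
  held_out <- ids[length(ids)]
  train_tr <- bind_trials(lapply(setdiff(ids, held_out), function(sid)
    cohort_subject_trials(src, sid)))
  d <- dim(train_tr$data)
  model <- build_model(model_variant("LFCNN"), d[2], d[3],
                       seed = derive_seed(seed, "init"))
  fit <- train_model(model, train_tr,
                     train_config(learning_rate = 1e-2,
                                  epochs = pretrain_epochs,
                                  batch_size = 32,
                                  seed = derive_seed(seed, "pre")))
  pre <- fit$model
  src_acc <- model_accuracy(pre, cohort_subject_trials(src, held_out))

  out <- NULL
  for (r in seq_len(n_replicates)) {
    rs <- derive_seed(seed, "rep", r)
    tgt <- preproc(make_cohort(1, n_target, prof, seed = rs,
                               n_trials = n_trials)$target)
    tids <- cohort_subject_ids(tgt)
    nt <- n_trials(cohort_subject_trials(tgt, tids[1]))
    schedule <- build_schedule(tids, make_divisions(nt, "four"))
    tl_cfg <- tl %||% tl_config(freeze_level = 44, learning_rate = "LR1",
                                epochs = 30, warmup_epochs = 5,
                                n_runs = 1, batch_size = 32, seed = rs)
    rep_tl <- online_tl_run(pre, tgt, schedule, tl_cfg)
    base_cfg <- tl_config(freeze_level = tl_cfg$freeze_level,
                          learning_rate = tl_cfg$learning_rate,
                          epochs = 0, warmup_epochs = 0,
                          n_runs = 1, batch_size = 32, seed = rs)
    rep_base <- online_tl_run(pre, tgt, schedule, base_cfg)
    out <- rbind(out, data.frame(
      replicate = r,
      tl = mean(rep_tl$per_subject),
      baseline = mean(rep_base$per_subject)))
  }
  attr(out, "source_accuracy") <- src_acc
  out
}

#' Duration of a rehabilitation session in whole minutes
#'
#' `ceiling(n_trials * trial_s / 60)`: 140 seven-second trials make a
#' 17-minute session, 90 make an 11-minute session.
#'
#' @param n_trials Trials in the session.
#' @param trial_s Trial duration in seconds.
#' @return Integer minutes.
#' @export
session_minutes <- function(n_trials, trial_s) {
  assert_that(n_trials > 0 && trial_s > 0, "inputs must be positive")
  as.integer(ceiling(n_trials * trial_s / 60))
}
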