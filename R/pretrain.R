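# Cloud-side preparation of pre-trained classifiers: leave-one-subject-out
# training over the source cohort and the two published selection criteria.

#' Leave-one-subject-out pre-training
#'
#' For each source subject, trains `variant` on all remaining source
#' subjects (both sessions concatenated) and evaluates on the held-out
#' subject, yielding one pre-trained classifier per tested subject. With a
#' `mask_provider`, each classifier is trained on that tested subject's
#' selected channels; otherwise all channels are used.
#'
#' @param source_cohort A source `cohort` with at least 2 subjects.
#' @param variant A [model_variant()].
#' @param train_cfg A [train_config()] (pre-training default learning rate
#'   is 0.0009; the full-scale protocol trains up to 1000 epochs under the
#'   best-accuracy checkpoint, desk-scale profiles use far fewer).
#' @param mask_provider Optional function `subject_id -> channel_mask`.
#' @param window Optional `c(start_s, dur_s)` window applied to all trials.
#' @param evaluate Whether to score each classifier on its held-out
#'   subject (default: only when training actually ran, i.e. `epochs > 0`).
#' @return List of `pretrained_classifier` objects, one per source
#'   subject, each with fields `model`, `variant`, `tested_source_subject`,
#'   `mask`, `accuracy_on_tested_subject`, `window`.
#' @export
loso_pretrain <- function(source_cohort, variant, train_cfg,
                          mask_provider = NULL, window = NULL,
                          evaluate = train_cfg$epochs > 0) {
  ids <- cohort_subject_ids(source_cohort)
  assert_that(length(ids) >= 2,
              "leave-one-subject-out needs at least 2 source subjects")
  lapply(ids, function(test_id) {
    mask <- if (is.null(mask_provider)) {
      channel_mask(rep(TRUE, 22))
    } else {
      mask_provider(test_id)
    }
    assert_that(inherits(mask, "channel_mask"), "mask_provider must return a channel_mask")
    prep <- function(sid) {
      tr <- cohort_subject_trials(source_cohort, sid)
      if (!is.null(window)) tr <- extract_window(tr, window[1], window[2])
      drop_channels(tr, mask)
    }
    train_tr <- bind_trials(lapply(setdiff(ids, test_id), prep))
    d <- dim(train_tr$data)
    model <- build_model(variant, d[2], d[3],
                         seed = derive_seed(train_cfg$seed, "loso", test_id))
    fit <- train_model(model, train_tr, train_cfg)
    acc <- if (evaluate) model_accuracy(fit$model, prep(test_id)) else NA_real_
    structure(
      list(model = fit$model, variant = variant,
           tested_source_subject = test_id, mask = mask,
           accuracy_on_tested_subject = acc,
           window = window, train_report = fit$report),
      class = "pretrained_classifier"
    )
  })
}

#' @export
print.pretrained_classifier <- function(x, ...) {
  cat(sprintf(
    "<pretrained_classifier> %s%s, tested on subject %s: accuracy %.4f (%d channels)\n",
    x$variant$name, if (x$variant$uses_channel_selection) " +CS" else "",
    x$tested_source_subject, x$accuracy_on_tested_subject,
    mask_popcount(x$mask)
  ))
  invisible(x)
}

#' Save / load a pre-trained classifier bundle
#'
#' A bundle directory holds the model checkpoint, the channel-mask file in
#' printed notation, and a JSON metadata manifest; the triple round-trips
#' a `pretrained_classifier`.
#'
#' @param classifier A `pretrained_classifier`.
#' @param dir Directory to create or read.
#' @return `load_classifier` returns the restored object.
#' @export
save_classifier <- function(classifier, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  save_model(classifier$model, file.path(dir, "model"))
  write_channel_mask(classifier$mask, file.path(dir, "mask.txt"))
  jsonlite::write_json(
    list(variant = classifier$variant$name,
         uses_channel_selection = classifier$variant$uses_channel_selection,
         tested_source_subject = classifier$tested_source_subject,
         accuracy_on_tested_subject = classifier$accuracy_on_tested_subject,
         window = classifier$window),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  structure(
    list(model = load_model(file.path(dir, "model")),
         variant = model_variant(meta$variant,
                                 uses_channel_selection = isTRUE(meta$uses_channel_selection)),
         tested_source_subject = meta$tested_source_subject,
         mask = read_channel_mask(file.path(dir, "mask.txt")),
         accuracy_on_tested_subject = meta$accuracy_on_tested_subject,
         window = if (length(meta$window)) as.numeric(meta$window)),
    class = "pretrained_classifier"
  )
}

#' Select classifiers by the two published criteria
#'
#' Given leave-one-subject-out accuracies without and with channel
#' selection (indexed by tested subject), returns (1) the tested subject
#' with the highest accuracy overall, and (2) the tested subject with the
#' greatest improvement from channel selection. Ties break toward the
#' lower subject id.
#'
#' @param results_no_cs,results_cs Named numeric vectors of accuracies
#'   keyed by tested-subject id (or lists of `pretrained_classifier`s).
#' @return List with `best` (highest-accuracy subject id), `best_accuracy`,
#'   `most_improved` (largest-gain subject id), `improvement`.
#' @export
pick_classifiers <- function(results_no_cs, results_cs) {
  to_vec <- function(x) {
    if (is.list(x) && length(x) && inherits(x[[1]], "pretrained_classifier")) {
      stats::setNames(
        vapply(x, function(cl) cl$accuracy_on_tested_subject, numeric(1)),
        vapply(x, function(cl) as.character(cl$tested_source_subject), "")
      )
    } else {
      assert_that(!is.null(names(x)), "results must be named by tested subject")
      x
    }
  }
  a0 <- to_vec(results_no_cs)
  a1 <- to_vec(results_cs)
  assert_that(setequal(names(a0), names(a1)),
              "the two result sets cover different tested subjects")
  a1 <- a1[names(a0)]
  # order by subject id so which.max's first-hit rule breaks ties low
  ord <- order(as.numeric(names(a0)))
  a0 <- a0[ord]; a1 <- a1[ord]
  overall <- pmax(a0, a1)
  best <- names(a0)[which.max(overall)]
  imp <- a1 - a0
  most_improved <- names(a0)[which.max(imp)]
  list(best = as.numeric(best), best_accuracy = max(overall),
       most_improved = as.numeric(most_improved),
       improvement = max(imp))
}
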