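# Experiment manifests: a flat, validated configuration covering the
# whole pipeline (simulate -> pretrain -> select-channels -> transfer ->
# report), with explicit seeds so that a manifest re-run reproduces all
# deterministic outputs.

manifest_schema <- function() {
  list(
    simulate = c("n_source", "n_target", "n_trials", "fs", "trial_s",
                 "layout", "snr_db", "erd_depth", "mixing_strength",
                 "drift_per_session", "seed"),
    window = c("start_s", "dur_s"),
    pretrain = c("variant", "channel_selection", "epochs", "learning_rate",
                 "batch_size", "seed"),
    select_channels = c("enabled", "population_size", "generations",
                        "n_repeats", "fitness_epochs", "max_train_trials",
                        "seed"),
    transfer = c("divisions", "freeze_level", "learning_rate", "epochs",
                 "warmup_epochs", "label_mode", "n_runs", "batch_size",
                 "seed"),
    output = c("dir")
  )
}

#' Default experiment manifest
#'
#' Returns a complete manifest at desk scale (small synthetic cohort, few
#' epochs) which [run_experiment()] accepts as-is; individual fields can
#' be overridden before running. The transfer section defaults to the
#' best-performing published strategy: four divisions, freeze level 44,
#' LR1 (0.0001), 30 epochs.
#'
#' @param seed Base seed copied into every section.
#' @return Nested named list (class `experiment_manifest`).
#' @export
default_manifest <- function(seed = 1L) {
  structure(list(
    simulate = list(n_source = 2, n_target = 2, n_trials = 24, fs = 250,
                    trial_s = 7, layout = "sensorimotor", snr_db = 10,
                    erd_depth = 0.6, mixing_strength = 0.3,
                    drift_per_session = 0.1, seed = seed),
    window = list(start_s = 2, dur_s = 0.4),
    pretrain = list(variant = "LFCNN", channel_selection = FALSE,
                    epochs = 3, learning_rate = 9e-4, batch_size = 32,
                    seed = seed),
    select_channels = list(enabled = FALSE, population_size = 8,
                           generations = 3, n_repeats = 1,
                           fitness_epochs = 1, max_train_trials = 48,
                           seed = seed),
    transfer = list(divisions = "four", freeze_level = 44,
                    learning_rate = "LR1", epochs = 30, warmup_epochs = 5,
                    label_mode = "instructed", n_runs = 1, batch_size = 64,
                    seed = seed),
    output = list(dir = tempfile("mitl_experiment_"))
  ), class = "experiment_manifest")
}

#' Validate an experiment manifest
#'
#' Checks the section/key structure against the schema and errors with the
#' full list of offending keys.
#'
#' @param manifest A nested list (e.g. from [default_manifest()] or
#'   [read_manifest()]).
#' @return The manifest, invisibly, on success.
#' @export
validate_manifest <- function(manifest) {
  schema <- manifest_schema()
  bad <- character(0)
  for (sec in names(manifest)) {
    if (!sec %in% names(schema)) {
      bad <- c(bad, sec)
      next
    }
    extra <- setdiff(names(manifest[[sec]]), schema[[sec]])
    if (length(extra)) bad <- c(bad, paste0(sec, ".", extra))
  }
  for (sec in c("simulate", "transfer")) {
    if (!sec %in% names(manifest)) bad <- c(bad, paste0("<missing> ", sec))
  }
  assert_that(length(bad) == 0,
              paste("manifest violates the schema at:",
                    paste(bad, collapse = ", ")))
  invisible(manifest)
}

#' Read / write a manifest file (YAML)
#' @param path File path.
#' @return `read_manifest` returns the validated manifest.
#' @export
read_manifest <- function(path) {
  m <- yaml::read_yaml(path)
  class(m) <- "experiment_manifest"
  validate_manifest(m)
  m
}

#' @rdname read_manifest
#' @param manifest A manifest list.
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(unclass(manifest), path)
  invisible(path)
}

manifest_profile <- function(sim) {
  prof <- synthetic_profile(layout = sim$layout %||% "sensorimotor",
                            snr_db = sim$snr_db %||% 10,
                            mixing_strength = sim$mixing_strength %||% 0.3,
                            drift_per_session = sim$drift_per_session %||% 0.1)
  if (!is.null(sim$erd_depth)) {
    for (i in 1:4) prof$band_specs[[i]]$erd <- sim$erd_depth
  }
  prof
}

log_line <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%dT%H:%M:%S] "), sprintf(...))
}

#' Run a full experiment from a manifest
#'
#' Executes simulate -> pretrain -> (optional) channel selection ->
#' transfer -> report, writes the report JSON and a copy of the manifest
#' beside the outputs, and returns the artifacts invisibly. Deterministic:
#' re-running the same manifest reproduces the same report.
#'
#' @param manifest An `experiment_manifest`.
#' @param quiet Suppress progress logging.
#' @return List with `cohorts`, `classifiers`, `picked`, `mask`, `report`,
#'   `averages`, `paths`.
#' @export
run_experiment <- function(manifest, quiet = FALSE) {
  validate_manifest(manifest)
  say <- if (quiet) function(...) invisible(NULL) else log_line
  sim <- manifest$simulate
  win <- manifest$window
  pre <- manifest$pretrain
  sel <- manifest$select_channels %||% list(enabled = FALSE)
  tl <- manifest$transfer
  out_dir <- manifest$output$dir %||% tempfile("mitl_experiment_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  say("simulate: %d source + %d target subjects, %d trials/session",
      sim$n_source, sim$n_target, sim$n_trials)
  cohorts <- make_cohort(sim$n_source, sim$n_target,
                         manifest_profile(sim), seed = sim$seed %||% 1L,
                         n_trials = sim$n_trials, fs = sim$fs %||% 250,
                         trial_s = sim$trial_s %||% 7)
  window <- if (!is.null(win)) c(win$start_s, win$dur_s)

  variant <- model_variant(pre$variant %||% "LFCNN",
                           uses_channel_selection = isTRUE(sel$enabled))
  mask_provider <- NULL
  mask <- NULL
  if (isTRUE(sel$enabled)) {
    say("select-channels: GA over %d-bit masks", 22)
    fit_cfg <- train_config(learning_rate = pre$learning_rate %||% 9e-4,
                            epochs = sel$fitness_epochs %||% 1,
                            batch_size = pre$batch_size %||% 32,
                            seed = sel$seed %||% 1L)
    ids <- cohort_subject_ids(cohorts$source)
    fitness <- function(m) {
      fitness_cross_subject(m, cohorts$source, ids[1], variant, fit_cfg,
                            window = window,
                            max_train_trials = sel$max_train_trials)
    }
    ga <- ga_select(fitness,
                    ga_config(population_size = sel$population_size %||% 8,
                              generations = sel$generations %||% 3,
                              n_repeats = sel$n_repeats %||% 1,
                              seed = sel$seed %||% 1L))
    mask <- ga$best_mask
    write_channel_mask(mask, file.path(out_dir, "selected_channels.txt"))
    mask_provider <- function(sid) mask
  }

  say("pretrain: leave-one-subject-out, variant %s", variant$name)
  pre_cfg <- train_config(learning_rate = pre$learning_rate %||% 9e-4,
                          epochs = pre$epochs %||% 3,
                          batch_size = pre$batch_size %||% 32,
                          seed = pre$seed %||% 1L)
  classifiers <- loso_pretrain(cohorts$source, variant, pre_cfg,
                               mask_provider = mask_provider, window = window)
  accs <- stats::setNames(
    vapply(classifiers, function(x) x$accuracy_on_tested_subject, numeric(1)),
    vapply(classifiers, function(x) as.character(x$tested_source_subject), ""))
  picked_id <- as.numeric(names(accs)[which.max(accs)])
  picked <- classifiers[[match(picked_id, cohort_subject_ids(cohorts$source))]]
  say("pretrain: picked classifier tested on subject %s (accuracy %.3f)",
      picked_id, max(accs))

  target_ids <- cohort_subject_ids(cohorts$target)
  n_target_trials <- n_trials(cohort_subject_trials(cohorts$target, target_ids[1]))
  divisions <- make_divisions(n_target_trials, tl$divisions %||% "four")
  schedule <- build_schedule(target_ids, divisions)
  tlc <- tl_config(freeze_level = tl$freeze_level %||% 44,
                   learning_rate = tl$learning_rate %||% "LR1",
                   epochs = tl$epochs %||% 30,
                   warmup_epochs = tl$warmup_epochs %||% 5,
                   label_mode = tl$label_mode %||% "instructed",
                   n_runs = tl$n_runs %||% 1,
                   batch_size = tl$batch_size %||% 64,
                   seed = tl$seed %||% 1L)
  say("transfer: %d targets x %d divisions, freeze %d, lr %g, epochs %d",
      length(target_ids), length(divisions$boundaries), tlc$freeze_level,
      tlc$learning_rate, tlc$epochs)
  report <- online_tl_run(picked, cohorts$target, schedule, tlc)
  averages <- group_averages(report)

  paths <- list(
    report = file.path(out_dir, "report.json"),
    manifest = file.path(out_dir, "manifest.yaml")
  )
  jsonlite::write_json(
    list(config = unclass(manifest),
         pretrain_accuracies = as.list(accs),
         picked_subject = picked_id,
         selected_channels = if (!is.null(mask)) format_channel_mask(mask),
         per_entry = report$per_entry,
         per_subject = as.list(report$per_subject),
         group_averages = averages),
    paths$report, auto_unbox = TRUE, digits = NA)
  write_manifest(manifest, paths$manifest)
  say("report written to %s", paths$report)
  invisible(list(cohorts = cohorts, classifiers = classifiers,
                 picked = picked, mask = mask, report = report,
                 averages = averages, paths = paths))
}

#' Save / load a cohort container
#'
#' Persists the cohorts with their full trial cubes, labels and metadata
#' in a single container file.
#'
#' @param cohorts List with `source` and `target` cohorts (or one cohort).
#' @param path File path (`.rds`).
#' @export
save_cohort <- function(cohorts, path) {
  saveRDS(cohorts, path)
  invisible(path)
}

#' @rdname save_cohort
#' @export
load_cohort <- function(path) readRDS(path)
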