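# Genetic-algorithm channel selection: binary masks over the montage,
# fitness = cross-subject validation accuracy, best-of over repeated runs.

#' Genetic-algorithm configuration
#'
#' Defaults are desk-scale: population 24, 30 generations, uniform
#' crossover 0.8, bit-flip mutation 0.02, tournament-2 selection with
#' 2 elites, and the published practice of repeating the search 2-3 times
#' and keeping the best mask.
#'
#' @param population_size Even positive integer.
#' @param generations Number of generations.
#' @param crossover_prob,mutation_prob Probabilities in `[0, 1]`.
#' @param elitism_count Elites copied unchanged each generation.
#' @param tournament_size Tournament size for selection.
#' @param n_repeats Independent GA runs (best-of); the published rule is
#'   2-3.
#' @param seed Integer seed.
#' @return Object of class `ga_config`.
#' @export
ga_config <- function(population_size = 24, generations = 30,
                      crossover_prob = 0.8, mutation_prob = 0.02,
                      elitism_count = 2, tournament_size = 2,
                      n_repeats = 2, seed = 1L) {
  assert_that(is_count(population_size) && population_size %% 2 == 0,
              "population_size must be a positive even integer")
  assert_that(is_count(generations), "generations must be positive")
  assert_that(crossover_prob >= 0 && crossover_prob <= 1 &&
                mutation_prob >= 0 && mutation_prob <= 1,
              "probabilities must lie in [0, 1]")
  assert_that(is_count(n_repeats), "n_repeats must be >= 1")
  assert_that(elitism_count >= 0 && elitism_count < population_size,
              "elitism_count must be smaller than the population")
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 elitism_count = as.integer(elitism_count),
                 tournament_size = as.integer(tournament_size),
                 n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed)),
            class = "ga_config")
}

# all-zero candidates are repaired by switching one random bit on
repair_mask <- function(bits) {
  if (!any(bits)) bits[sample.int(length(bits), 1L)] <- TRUE
  bits
}

#' Genetic-algorithm search over channel masks
#'
#' Maximises `fitness` over binary masks of length `n_channels` with at
#' least one selected channel. Runs `config$n_repeats` independent
#' searches with derived seeds and returns the best mask observed across
#' all evaluated individuals of all repeats. Fitness values are cached by
#' mask, so duplicated individuals cost nothing.
#'
#' @param fitness Function `channel_mask -> numeric score` (higher is
#'   better).
#' @param config A [ga_config()].
#' @param n_channels Mask length (default 22).
#' @return List with `best_mask` (a [channel_mask()]), `best_fitness`, and
#'   `history`: a data frame with columns `repeat_id`, `generation`,
#'   `best`, `mean` (per-generation fitness of the population).
#' @export
ga_select <- function(fitness, config = ga_config(), n_channels = 22) {
  assert_that(is.function(fitness), "fitness must be a function")
  cache <- new.env(parent = emptyenv())
  evals <- 0L
  eval_mask <- function(bits) {
    key <- paste(as.integer(bits), collapse = "")
    v <- cache[[key]]
    if (is.null(v)) {
      v <- fitness(channel_mask(bits, n_channels = n_channels))
      assert_that(is.numeric(v) && length(v) == 1 && is.finite(v),
                  "fitness must return a single finite number")
      cache[[key]] <- v
      evals <<- evals + 1L
    }
    v
  }

  best_bits <- NULL
  best_fit <- -Inf
  hist <- list()
  for (rep_i in seq_len(config$n_repeats)) {
    with_local_seed(derive_seed(config$seed, "ga", rep_i), {
      np <- config$population_size
      pop <- lapply(seq_len(np), function(i) {
        repair_mask(stats::runif(n_channels) < 0.5)
      })
      fit <- vapply(pop, eval_mask, numeric(1))
      for (gen in seq_len(config$generations)) {
        ord <- order(fit, decreasing = TRUE)
        elite <- pop[ord[seq_len(config$elitism_count)]]
        children <- list()
        while (length(children) < np - config$elitism_count) {
          pick <- function() {
            cand <- sample.int(np, config$tournament_size)
            pop[[cand[which.max(fit[cand])]]]
          }
          pa <- pick(); pb <- pick()
          if (stats::runif(1) < config$crossover_prob) {
            swap <- stats::runif(n_channels) < 0.5
            c1 <- ifelse(swap, pb, pa)
            c2 <- ifelse(swap, pa, pb)
          } else {
            c1 <- pa; c2 <- pb
          }
          mut <- function(b) {
            flip <- stats::runif(n_channels) < config$mutation_prob
            repair_mask(xor(b, flip))
          }
          children <- c(children, list(mut(c1)), list(mut(c2)))
        }
        pop <- c(elite, children[seq_len(np - config$elitism_count)])
        fit <- vapply(pop, eval_mask, numeric(1))
        hist[[length(hist) + 1L]] <- data.frame(
          repeat_id = rep_i, generation = gen,
          best = max(fit), mean = mean(fit))
        if (max(fit) > best_fit) {
          best_fit <- max(fit)
          best_bits <- pop[[which.max(fit)]]
        }
      }
    })
  }
  # account for initial populations as evaluated individuals
  all_keys <- ls(cache)
  for (key in all_keys) {
    v <- cache[[key]]
    if (v > best_fit) {
      best_fit <- v
      best_bits <- as.integer(strsplit(key, "")[[1]]) == 1L
    }
  }
  list(best_mask = channel_mask(best_bits, n_channels = n_channels),
       best_fitness = best_fit,
       history = do.call(rbind, hist),
       n_evaluations = evals)
}

#' Cross-subject fitness of a channel mask
#'
#' Trains `variant` on every source subject except `test_subject`
#' (sessions concatenated), restricted to the channels in `mask`, and
#' returns the classification accuracy on `test_subject`'s trials — the
#' quantity the channel-selection search maximises.
#'
#' @param mask A [channel_mask()].
#' @param source_cohort A source `cohort`.
#' @param test_subject Subject id inside the source cohort.
#' @param variant A [model_variant()].
#' @param train_cfg A [train_config()]; desk-scale searches use few epochs.
#' @param window Optional `c(start_s, dur_s)` applied to all trials before
#'   training (defaults to the full stored window).
#' @param decimate Integer decimation factor applied after windowing
#'   (default 1 = none); see [decimate_trials()].
#' @param max_train_trials Optional cap on the number of training trials
#'   (a seeded subsample; reduces search cost).
#' @param warm_start Optional `model_handle` trained on the full montage
#'   (same window/decimation, same training subjects): every
#'   channel-count-independent parameter is copied into the per-mask model
#'   before training, so each evaluation only has to relearn the spatial
#'   filters. This amortises the temporal-feature learning across the
#'   whole search; see [fitness_warm_start()].
#' @return Accuracy in `[0, 1]`.
#' @export
fitness_cross_subject <- function(mask, source_cohort, test_subject, variant,
                                  train_cfg, window = NULL, decimate = 1L,
                                  max_train_trials = NULL, warm_start = NULL) {
  assert_that(mask_popcount(mask) >= 1, "mask must select channels")
  ids <- cohort_subject_ids(source_cohort)
  assert_that(test_subject %in% ids, "test_subject must be in the cohort")
  prep <- function(sid) {
    tr <- cohort_subject_trials(source_cohort, sid)
    if (!is.null(window)) tr <- extract_window(tr, window[1], window[2])
    if (decimate > 1L) tr <- decimate_trials(tr, decimate)
    drop_channels(tr, mask)
  }
  train_tr <- bind_trials(lapply(setdiff(ids, test_subject), prep))
  if (!is.null(max_train_trials) && n_trials(train_tr) > max_train_trials) {
    keep <- with_local_seed(derive_seed(train_cfg$seed, "sub"),
                            sample.int(n_trials(train_tr), max_train_trials))
    train_tr <- subset_trials(train_tr, sort(keep))
  }
  test_tr <- prep(test_subject)
  d <- dim(train_tr$data)
  model <- build_model(variant, d[2], d[3], seed = train_cfg$seed)
  if (!is.null(warm_start)) {
    assert_that(warm_start$arch$T == d[3],
                "warm_start model was built for a different window length")
    for (key in names(model$params)) {
      if (key == "7") {
        # spatial depthwise filters: restrict the base's 22-channel
        # filters to the masked channels, so the mask's fitness reflects
        # how much of the learned spatial-filter mass it retains
        keep <- which(unclass(mask))
        assert_that(dim(warm_start$params[["7"]]$W)[1] >= max(keep),
                    "warm_start model covers fewer channels than the mask")
        model$params[[key]]$W <-
          warm_start$params[[key]]$W[keep, , , drop = FALSE]
      } else {
        model$params[[key]] <- warm_start$params[[key]]
      }
    }
  }
  fit <- train_model(model, train_tr, train_cfg)
  model_accuracy(fit$model, test_tr)
}

#' Planted-signal channel-selection study (one replicate)
#'
#' End-to-end evaluation of the channel-selection search on synthetic data
#' whose class information is planted on a known 6-channel subset
#' (compact layout, no spatial mixing): generates a 2-source-subject
#' cohort (200 trials per subject), pre-trains a full-montage base model,
#' runs the GA with the warm-started cross-subject fitness, and reports
#' the selected mask's overlap with the planted channels against the
#' expected overlap of a random mask of the same size
#' (`popcount * 6 / 22`).
#'
#' @param seed Integer seed for the replicate (cohort, base training, GA).
#' @param ga A [ga_config()]; the default is desk-scale
#'   (population 8, 3 generations, 1 repeat).
#' @param n_trials Trials per session and subject (default 100; two
#'   sessions give the 200 trials per subject the study design uses).
#' @param window,decimate Preprocessing: imagery-interval window
#'   (default 2 s from cue at 2 s) and decimation factor (default 4,
#'   i.e. 62.5 Hz).
#' @param base_epochs,fit_epochs Training lengths for the base model and
#'   the per-mask fitness.
#' @return List with `mask`, `overlap` (channels shared with the planted
#'   set), `expected_overlap` (random mask of the same size), `popcount`,
#'   `fitness`, `informative`.
#' @export
ga_planted_signal_run <- function(seed, ga = NULL, n_trials = 100,
                                  window = c(2, 2), decimate = 4,
                                  base_epochs = 30, fit_epochs = 3) {
  prof <- synthetic_profile(layout = "focal6", mixing_strength = 0,
                            drift_per_session = 0)
  info <- informative_channels(prof)
  # two source subjects, two sessions each, preprocessed once
  # (window + decimate, full montage)
  subjects <- lapply(1:2, function(sid) {
    p <- prof
    p$subject_seed <- derive_seed(seed, "subject", sid)
    sessions <- lapply(1:2, function(sess) {
      tr <- generate_subject(p, n_trials, seed = derive_seed(seed, sid, sess),
                             session_id = sess, subject_id = sid)
      decimate_trials(extract_window(tr, window[1], window[2]), decimate)
    })
    list(subject_id = sid, sessions = sessions)
  })
  src <- structure(list(subjects = subjects, role = "source"),
                   class = "cohort")
  variant <- model_variant("LFCNN", uses_channel_selection = TRUE)
  base <- fitness_warm_start(
    src, 1, variant,
    train_config(learning_rate = 1e-2, epochs = base_epochs, batch_size = 32,
                 seed = derive_seed(seed, "base")),
    max_train_trials = 128)
  fit_cfg <- train_config(learning_rate = 2e-3, epochs = fit_epochs,
                          batch_size = 32, seed = derive_seed(seed, "fit"))
  fitness <- function(mask) {
    fitness_cross_subject(mask, src, 1, variant, fit_cfg,
                          max_train_trials = 128, warm_start = base)
  }
  if (is.null(ga)) {
    ga <- ga_config(population_size = 8, generations = 3, n_repeats = 1,
                    seed = derive_seed(seed, "ga"))
  }
  res <- ga_select(fitness, ga)
  pc <- mask_popcount(res$best_mask)
  list(mask = res$best_mask,
       overlap = length(intersect(which(unclass(res$best_mask)), info)),
       expected_overlap = pc * length(info) / 22,
       popcount = pc,
       fitness = res$best_fitness,
       informative = info,
       history = res$history)
}

#' Train a full-montage base model for warm-started channel-selection
#'
#' Trains `variant` on the channel-selection training subjects (all source
#' subjects except `test_subject`) with all 22 channels, for use as the
#' `warm_start` argument of [fitness_cross_subject()].
#'
#' @inheritParams fitness_cross_subject
#' @return A trained `model_handle`.
#' @export
fitness_warm_start <- function(source_cohort, test_subject, variant,
                               train_cfg, window = NULL, decimate = 1L,
                               max_train_trials = NULL) {
  fullmask <- channel_mask(rep(TRUE, 22))
  ids <- setdiff(cohort_subject_ids(source_cohort), test_subject)
  prep <- function(sid) {
    tr <- cohort_subject_trials(source_cohort, sid)
    if (!is.null(window)) tr <- extract_window(tr, window[1], window[2])
    if (decimate > 1L) tr <- decimate_trials(tr, decimate)
    tr
  }
  train_tr <- bind_trials(lapply(ids, prep))
  if (!is.null(max_train_trials) && n_trials(train_tr) > max_train_trials) {
    keep <- with_local_seed(derive_seed(train_cfg$seed, "sub"),
                            sample.int(n_trials(train_tr), max_train_trials))
    train_tr <- subset_trials(train_tr, sort(keep))
  }
  d <- dim(train_tr$data)
  model <- build_model(variant, d[2], d[3], seed = train_cfg$seed)
  train_model(model, train_tr, train_cfg)$model
}
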