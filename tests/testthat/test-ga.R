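# Genetic-algorithm channel search on cheap synthetic fitnesses.

test_that("the GA recovers a hidden target mask from bit-agreement fitness", {
  target <- rep(FALSE, 22)
  target[c(1, 3, 5, 8, 9, 12, 14, 17, 18, 20, 21, 22)] <- TRUE  # 12 bits
  fitness <- function(mask) sum(unclass(mask) == target)
  res <- ga_select(fitness, ga_config(population_size = 24, generations = 40,
                                      n_repeats = 1, seed = 42))
  expect_equal(unclass(res$best_mask), target, ignore_attr = TRUE)
  expect_equal(res$best_fitness, 22)
})

test_that("constant fitness returns that constant and some valid mask", {
  res <- ga_select(function(mask) 3.5,
                   ga_config(population_size = 8, generations = 2, seed = 1))
  expect_equal(res$best_fitness, 3.5)
  expect_gte(mask_popcount(res$best_mask), 1)
})

test_that("elitism makes the per-generation best non-decreasing", {
  noisy <- function(mask) mask_popcount(mask) + stats::runif(1, 0, 0.01)
  res <- ga_select(noisy, ga_config(population_size = 12, generations = 15,
                                    seed = 3, n_repeats = 1))
  per_gen <- res$history$best
  expect_true(all(diff(per_gen) >= -1e-12))
})

test_that("repeated runs are best-of and reproducible", {
  fitness <- function(mask) -abs(mask_popcount(mask) - 7)
  cfg3 <- ga_config(population_size = 8, generations = 4, n_repeats = 3, seed = 5)
  r3 <- ga_select(fitness, cfg3)
  r3b <- ga_select(fitness, cfg3)
  expect_identical(r3$history, r3b$history)
  expect_identical(r3$best_mask, r3b$best_mask)
  r1 <- ga_select(fitness, ga_config(population_size = 8, generations = 4,
                                     n_repeats = 1, seed = 5))
  expect_gte(r3$best_fitness, r1$best_fitness)
})

test_that("all-zero candidates are repaired before evaluation", {
  seen_zero <- FALSE
  fitness <- function(mask) {
    if (mask_popcount(mask) == 0) seen_zero <<- TRUE
    mask_popcount(mask)
  }
  # heavy mutation maximises the chance of producing all-zero children
  res <- ga_select(fitness, ga_config(population_size = 8, generations = 10,
                                      mutation_prob = 0.5, seed = 8))
  expect_false(seen_zero)
  expect_gte(mask_popcount(res$best_mask), 1)
})

test_that("cross-subject fitness honours masks and rejects outsiders", {
  w <- tiny_world(n_source = 2, n_trials = 8, seed = 4)
  cfg <- train_config(epochs = 0, batch_size = 8, seed = 1)
  acc <- fitness_cross_subject(channel_mask(1:22), w$source, 1,
                               model_variant("LFCNN"), cfg)
  expect_true(acc >= 0 && acc <= 1)
  expect_error(fitness_cross_subject(channel_mask(1:22), w$source, 99,
                                     model_variant("LFCNN"), cfg),
               "test_subject")
})

test_that("warm-started fitness reuses channel-independent weights", {
  w <- tiny_world(n_source = 2, n_trials = 8, seed = 6)
  cfg <- train_config(epochs = 0, batch_size = 8, seed = 2)
  base <- fitness_warm_start(w$source, 1, model_variant("LFCNN"), cfg)
  # with 0 fine-tuning epochs, the fitness equals the accuracy of the
  # warm-started model (base weights, spatial filters restricted to the
  # masked channels) on the held-out subject's masked trials
  mask <- channel_mask(1:9)
  test_tr <- drop_channels(cohort_subject_trials(w$source, 1), mask)
  m <- build_model(model_variant("LFCNN"), 9, dim(test_tr$data)[3],
                   seed = cfg$seed)
  for (key in names(m$params)) {
    if (key == "7") {
      m$params[[key]]$W <- base$params[[key]]$W[1:9, , , drop = FALSE]
    } else {
      m$params[[key]] <- base$params[[key]]
    }
  }
  a_direct <- model_accuracy(m, test_tr)
  a_fit <- fitness_cross_subject(mask, w$source, 1, model_variant("LFCNN"),
                                 cfg, warm_start = base)
  expect_equal(a_fit, a_direct)
})
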