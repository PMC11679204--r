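# Numerical core: analytic gradients against finite differences, training
# and prediction contracts.

test_that("backpropagated gradients match central finite differences", {
  ne <- asNamespace("mitransfer")
  mod <- build_model(model_variant("LFCNN"), 9, 70, seed = 42)
  mod$dropout_rate <- 0                      # deterministic objective
  withr::with_seed(7, {
    X <- array(rnorm(70 * 9 * 3), c(1, 70, 9, 3))
  })
  y <- c(1L, 3L, 4L)
  fw <- ne$net_forward(mod, X, mode = "train", keep = TRUE)
  ls <- ne$xent_loss(fw$probs, y)
  gr <- ne$net_backward(mod, fw, ls$dlogits)
  loss_at <- function(m) {
    ne$xent_loss(ne$net_forward(m, X, mode = "train")$probs, y)$loss
  }
  # every parameterised registry entry contributes gradients
  reg <- mod$registry
  expect_setequal(names(gr),
                  as.character(reg$index[reg$param_count > 0]))
  withr::with_seed(99, {
    for (key in names(gr)) {
      for (tn in names(gr[[key]])) {
        nel <- length(gr[[key]][[tn]])
        for (i in sample(nel, min(2, nel))) {
          m1 <- mod; m1$params[[key]][[tn]][i] <- m1$params[[key]][[tn]][i] + 1e-5
          m2 <- mod; m2$params[[key]][[tn]][i] <- m2$params[[key]][[tn]][i] - 1e-5
          num <- (loss_at(m1) - loss_at(m2)) / 2e-5
          ana <- gr[[key]][[tn]][i]
          expect_lt(abs(num - ana) / max(1e-4, abs(num) + abs(ana)), 1e-3)
        }
      }
    }
  })
})

test_that("predicted probability rows sum to one", {
  m <- build_model(model_variant("LFCNN"), 9, 64, seed = 1)
  p <- predict(m, random_trials(n = 7))$probabilities
  expect_equal(dim(p), c(7, 4))
  expect_equal(rowSums(p), rep(1, 7), tolerance = 1e-6)
  expect_true(all(p >= 0))
})

test_that("an untrained model scores at chance on balanced random data", {
  m <- build_model(model_variant("LFCNN"), 9, 64, seed = 2)
  ts <- random_trials(n = 1000, seed = 3)
  acc <- model_accuracy(m, ts)
  expect_gte(acc, 0.15)   # binomial band around chance 0.25 at n = 1000
  expect_lte(acc, 0.35)
})

test_that("zero epochs leave the model untouched with an empty report", {
  m <- build_model(model_variant("LFCNN"), 9, 64, seed = 4)
  fit <- train_model(m, random_trials(n = 8), train_config(epochs = 0))
  expect_identical(fit$model$params, m$params)
  expect_equal(nrow(fit$report), 0)
})

test_that("training on a strongly separable set reaches high accuracy", {
  ts <- separable_trials(n = 48, seed = 10)
  m <- build_model(model_variant("LFCNN"), 9, 100, seed = 5)
  fit <- train_model(m, ts, train_config(learning_rate = 5e-3, epochs = 30,
                                         batch_size = 16, seed = 5))
  expect_gt(max(fit$report$accuracy), 0.9)
  expect_gt(model_accuracy(fit$model, ts), 0.9)
  # held-out draws from the same process are classified well above chance
  held <- separable_trials(n = 32, seed = 77)
  expect_gt(model_accuracy(fit$model, held), 0.6)
})

test_that("label permutation destroys out-of-sample accuracy", {
  ts <- separable_trials(n = 48, seed = 12)
  perm <- ts
  perm$labels <- withr::with_seed(1, sample(ts$labels))
  m <- build_model(model_variant("LFCNN"), 9, 100, seed = 6)
  fit <- train_model(m, perm, train_config(learning_rate = 5e-3, epochs = 12,
                                           batch_size = 16, seed = 6))
  held <- separable_trials(n = 80, seed = 78)
  expect_lt(model_accuracy(fit$model, held), 0.45)  # chance 0.25 + slack
})

test_that("training is deterministic given data and seed", {
  ts <- separable_trials(n = 16, seed = 13)
  m <- build_model(model_variant("LFCNN"), 9, 100, seed = 7)
  cfg <- train_config(epochs = 3, batch_size = 8, seed = 11)
  f1 <- train_model(m, ts, cfg)
  f2 <- train_model(m, ts, cfg)
  expect_identical(f1$report, f2$report)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("a fully frozen model is bit-identical after training", {
  ts <- separable_trials(n = 16, seed = 14)
  m <- build_model(model_variant("LFCNN"), 9, 100, seed = 8)
  m <- set_freeze_level(m, nrow(m$registry))
  fit <- train_model(m, ts, train_config(epochs = 2, batch_size = 8, seed = 1))
  expect_identical(fit$model$params, m$params)
})

test_that("degenerate single-class input warns but still runs", {
  ts <- random_trials(n = 8, seed = 15)
  ts$labels <- rep(2L, 8)
  m <- build_model(model_variant("LFCNN"), 9, 64, seed = 9)
  expect_warning(train_model(m, ts, train_config(epochs = 1, batch_size = 8)),
                 "single class")
})
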