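# User-facing model handles: construction, freezing, training, prediction
# and checkpoint persistence.

#' Build a model
#'
#' Constructs a `model_handle` for a [model_variant()] applied to inputs of
#' `n_channels x n_samples`, with deterministically seeded Glorot-uniform
#' weights and the flat layer registry attached.
#'
#' @param variant A [model_variant()].
#' @param n_channels Input channels (9..22).
#' @param n_samples Samples per trial (at least the widest kernel).
#' @param seed Integer seed for weight initialisation.
#' @return Object of class `model_handle`.
#' @export
build_model <- function(variant, n_channels, n_samples, seed = 1L) {
  registry <- build_layer_registry(variant, n_channels, n_samples)
  arch <- derive_arch(variant, n_channels, n_samples)
  params <- init_params(arch, derive_seed(seed, "init", variant$name))
  structure(
    list(variant = variant, registry = registry, arch = arch,
         params = params, dropout_rate = 0.25, freeze_level = 0L),
    class = "model_handle"
  )
}

#' @export
print.model_handle <- function(x, ...) {
  cat(sprintf(
    "<model_handle> %s on %d ch x %d samples: %d layers, %s params (%s trainable, freeze level %d), %.1f M MAC\n",
    x$variant$name, x$arch$C, x$arch$T, nrow(x$registry),
    format(count_total_params(x), big.mark = ","),
    format(count_trainable_params(x), big.mark = ","),
    x$freeze_level, total_mac(x) / 1e6
  ))
  invisible(x)
}

#' Set the freeze level of a model
#'
#' Marks registry entries with `index <= level` as frozen: their parameters
#' are excluded from optimisation (and their normalisation statistics stop
#' updating), so they are bit-identical after any subsequent training.
#'
#' @param model A `model_handle`.
#' @param level Integer in `0..nrow(registry)`; the published levels are
#'   [freeze_levels()].
#' @return The modified `model_handle`.
#' @export
set_freeze_level <- function(model, level) {
  assert_that(inherits(model, "model_handle"), "model required")
  assert_that(is.numeric(level) && length(level) == 1 && level == round(level) &&
                level >= 0, "level must be a non-negative integer")
  assert_that(level <= nrow(model$registry),
              sprintf("level %d exceeds registry length %d",
                      level, nrow(model$registry)))
  model$registry$frozen <- model$registry$index <= level
  model$freeze_level <- as.integer(level)
  model
}

#' Training configuration
#'
#' @param learning_rate Adam step size (> 0); the pre-training default is
#'   0.0009.
#' @param epochs Number of passes over the data (>= 0; 0 leaves the model
#'   untouched).
#' @param batch_size Mini-batch size (clamped down to the trial count).
#' @param seed Integer seed controlling shuffling and dropout.
#' @param checkpoint `"best"` (default) restores the weights of the epoch
#'   with the highest monitored accuracy; `"last"` keeps the final epoch.
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 9e-4, epochs = 10, batch_size = 64,
                         seed = 1L, checkpoint = c("best", "last")) {
  assert_that(learning_rate > 0, "learning_rate must be positive")
  assert_that(is.numeric(epochs) && epochs >= 0 && epochs == round(epochs),
              "epochs must be a non-negative integer")
  assert_that(is_count(batch_size), "batch_size must be a positive integer")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 checkpoint = match.arg(checkpoint)),
            class = "train_config")
}

trials_to_input <- function(trials, arch) {
  d <- dim(trials$data)
  assert_that(d[2] == arch$C,
              sprintf("model expects %d channels, data has %d", arch$C, d[2]))
  assert_that(d[3] == arch$T,
              sprintf("model expects %d samples, data has %d", arch$T, d[3]))
  x <- aperm(trials$data, c(3, 2, 1))
  dim(x) <- c(1L, d[3], d[2], d[1])
  x
}

adam_step <- function(state, key, tname, grad, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  s <- state$slots[[key]][[tname]]
  if (is.null(s)) s <- list(m = grad * 0, v = grad * 0)
  s$m <- b1 * s$m + (1 - b1) * grad
  s$v <- b2 * s$v + (1 - b2) * grad^2
  state$slots[[key]][[tname]] <- s
  mhat <- s$m / (1 - b1^state$t)
  vhat <- s$v / (1 - b2^state$t)
  lr * mhat / (sqrt(vhat) + eps)
}

#' Train a model
#'
#' Adam optimisation of the categorical cross-entropy over mini-batches,
#' honouring the model's freeze level: frozen entries receive no updates
#' and their normalisation layers run in inference mode throughout, so
#' their state is bit-identical afterwards. Per-epoch accuracy on the
#' training stream is monitored; with the default checkpoint policy the
#' returned model carries the weights of the best epoch.
#'
#' @param model A `model_handle`.
#' @param trials A [trial_set()] matching the model's input shape.
#' @param config A [train_config()].
#' @return List with elements `model` (trained handle) and `report`
#'   (data frame of per-epoch `loss` and `accuracy`).
#' @export
train_model <- function(model, trials, config) {
  assert_that(inherits(model, "model_handle"), "model required")
  assert_that(inherits(trials, "trial_set"), "trials required")
  assert_that(inherits(config, "train_config"), "config required")
  n <- n_trials(trials)
  report <- data.frame(epoch = integer(0), loss = numeric(0),
                       accuracy = numeric(0))
  if (config$epochs == 0L) return(list(model = model, report = report))

  tab <- table(trials$labels)
  if (length(tab) < 2) {
    warning("training labels contain a single class; the fit is degenerate")
  } else if (max(tab) / min(tab) > 3) {
    warning("training labels are strongly imbalanced")
  }
  bs <- min(config$batch_size, n)
  x_all <- trials_to_input(trials, model$arch)
  y_all <- trials$labels

  state <- new.env(parent = emptyenv())
  state$slots <- list()
  state$t <- 0L
  fz <- model$registry$frozen
  best_acc <- -Inf
  best_params <- model$params

  with_local_seed(derive_seed(config$seed, "fit"), {
    for (ep in seq_len(config$epochs)) {
      perm <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0
      for (start in seq(1L, n, by = bs)) {
        idx <- perm[start:min(start + bs - 1L, n)]
        xb <- x_all[, , , idx, drop = FALSE]
        yb <- y_all[idx]
        fw <- net_forward(model, xb, mode = "train", keep = TRUE)
        model$params <- fw$params     # updated normalisation statistics
        ls <- xent_loss(fw$probs, yb)
        ep_loss <- ep_loss + ls$loss * length(idx)
        ep_correct <- ep_correct + sum(max.col(t(fw$probs)) == yb)
        grads <- net_backward(model, fw, ls$dlogits)
        state$t <- state$t + 1L
        for (key in names(grads)) {
          if (fz[as.integer(key)]) next
          for (tname in names(grads[[key]])) {
            upd <- adam_step(state, key, tname, grads[[key]][[tname]],
                             config$learning_rate)
            model$params[[key]][[tname]] <- model$params[[key]][[tname]] - upd
          }
        }
      }
      acc <- ep_correct / n
      report <- rbind(report, data.frame(epoch = ep, loss = ep_loss / n,
                                         accuracy = acc))
      if (acc > best_acc) {
        best_acc <- acc
        best_params <- model$params
      }
    }
  })
  if (config$checkpoint == "best") model$params <- best_params
  list(model = model, report = report)
}

#' Predict class labels and probabilities
#'
#' @param object A trained `model_handle`.
#' @param trials A [trial_set()] matching the model's input shape.
#' @param batch_size Prediction batch size.
#' @param ... Unused.
#' @return List with `labels` (integer vector) and `probabilities`
#'   (`n_trials x 4` matrix, rows summing to 1).
#' @export
predict.model_handle <- function(object, trials, batch_size = 128, ...) {
  assert_that(inherits(trials, "trial_set"), "trials required")
  n <- n_trials(trials)
  x_all <- trials_to_input(trials, object$arch)
  probs <- matrix(0, n, object$arch$n_classes)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    fw <- net_forward(object, x_all[, , , idx, drop = FALSE], mode = "eval")
    probs[idx, ] <- t(fw$probs)
  }
  list(labels = max.col(probs, ties.method = "first"),
       probabilities = probs)
}

#' Classification accuracy of a model on a trial set
#'
#' @param model A `model_handle`.
#' @param trials A [trial_set()].
#' @return Fraction of correctly classified trials.
#' @export
model_accuracy <- function(model, trials) {
  mean(predict(model, trials)$labels == trials$labels)
}

#' Save / load a model checkpoint
#'
#' A checkpoint directory holds a JSON manifest (variant, input shape,
#' freeze level, registry) and the weight arrays; the pair round-trips a
#' `model_handle` exactly.
#'
#' @param model A `model_handle`.
#' @param dir Directory to create or read.
#' @return `load_model` returns the restored `model_handle`.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    variant = model$variant$name,
    uses_channel_selection = model$variant$uses_channel_selection,
    n_channels = model$arch$C, n_samples = model$arch$T,
    freeze_level = model$freeze_level,
    dropout_rate = model$dropout_rate,
    registry = model$registry
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(model$params, file.path(dir, "weights.rds"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  variant <- model_variant(manifest$variant,
                           uses_channel_selection = isTRUE(manifest$uses_channel_selection))
  model <- build_model(variant, manifest$n_channels, manifest$n_samples)
  model$params <- readRDS(file.path(dir, "weights.rds"))
  model$dropout_rate <- manifest$dropout_rate
  set_freeze_level(model, manifest$freeze_level)
}
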