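# Model variants: named hyperparameter bundles for the dual-branch
# attention CNN family.

#' Stage hyperparameters
#'
#' One convolutional stage is described by the number of temporal filters
#' `F1`, the temporal kernel width `KE1` (samples), the depth multiplier `D`
#' of the spatial depthwise convolution, and the separable kernel width
#' `KE2` (samples).
#'
#' @param F1,KE1,D,KE2 Positive integers.
#' @return Object of class `stage_spec`.
#' @export
stage_spec <- function(F1, KE1, D, KE2 = 16) {
  for (v in list(F1, KE1, D, KE2)) {
    assert_that(is_count(v), "stage parameters must be positive integers")
  }
  structure(list(F1 = as.integer(F1), KE1 = as.integer(KE1),
                 D = as.integer(D), KE2 = as.integer(KE2)),
            class = "stage_spec")
}

#' Model variant
#'
#' The three published variants share one architecture and differ only in
#' the stage-1 filter count and kernel widths: FCNNA (96 filters, width
#' 60), XFCNN (16, 60) and LFCNN (8, 48). Stage 2 is common to all
#' (16 filters, width 64); the depth multiplier is 2 in stage 1 and 1 in
#' stage 2, and all separable kernels are 16 samples wide.
#'
#' @param name One of `"FCNNA"`, `"XFCNN"`, `"LFCNN"`.
#' @param uses_channel_selection Logical: whether this model is intended to
#'   be paired with a genetic-algorithm channel mask.
#' @return Object of class `model_variant` with `stage1`, `stage2`,
#'   `n_classes = 4`.
#' @export
model_variant <- function(name = c("FCNNA", "XFCNN", "LFCNN"),
                          uses_channel_selection = FALSE) {
  name <- match.arg(name)
  stage1 <- switch(name,
    FCNNA = stage_spec(96, 60, 2, 16),
    XFCNN = stage_spec(16, 60, 2, 16),
    LFCNN = stage_spec(8, 48, 2, 16)
  )
  structure(
    list(name = name, stage1 = stage1, stage2 = stage_spec(16, 64, 1, 16),
         n_classes = 4L,
         uses_channel_selection = isTRUE(uses_channel_selection)),
    class = "model_variant"
  )
}

#' @export
print.model_variant <- function(x, ...) {
  cat(sprintf(
    "<model_variant> %s%s: stage1 (F1=%d, KE1=%d, D=%d, KE2=%d), stage2 (F1=%d, KE1=%d, D=%d, KE2=%d)\n",
    x$name, if (x$uses_channel_selection) " +CS" else "",
    x$stage1$F1, x$stage1$KE1, x$stage1$D, x$stage1$KE2,
    x$stage2$F1, x$stage2$KE1, x$stage2$D, x$stage2$KE2
  ))
  invisible(x)
}
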