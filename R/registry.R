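# Flat layer registry: an ordered list of every layer of the network with
# its parameter count, convolution shape metadata and frozen flag. The
# registry is the freeze-by-index surface: "freeze level L" marks entries
# 1..L as excluded from optimisation. Entries are laid out in semantic
# groups so that the published freeze levels land on meaningful
# boundaries:
#   prefix 6  — the stage-1 temporal filters (+ their norm),
#   prefix 16 — adds both spatial depthwise blocks,
#   prefix 26 — adds both separable-convolution blocks,
#   prefix 44 — extends through the first attention block's spatial
#               attention, average-path MLP and max-path first dense.
# The stage-2 temporal convolution and everything from the first attention
# block's max-path output dense onward remain trainable at level 44.
# Registry order is a freeze ordering, not the execution order.

# Architecture dimensions derived from a variant and an input shape.
derive_arch <- function(variant, n_channels, n_samples) {
  s1 <- variant$stage1; s2 <- variant$stage2
  FD <- s1$F1 * s1$D          # stage-1 branch width
  M1 <- 2L * FD               # stage-1 concat width
  F2 <- s2$F1
  M2 <- 2L * F2               # stage-2 concat width
  pool <- 16L
  T2 <- n_samples %/% pool
  list(C = as.integer(n_channels), T = as.integer(n_samples),
       F1 = s1$F1, K1 = s1$KE1, D = s1$D, KE2 = s1$KE2,
       FD = FD, M1 = M1, H1 = M1 %/% 2L,
       F2 = F2, K2 = s2$KE1, D2 = s2$D, KE2b = s2$KE2,
       M2 = M2, H2 = M2 %/% 2L,
       pool = pool, T2 = T2, Ks = 7L,
       n_classes = variant$n_classes)
}

#' Build the flat layer registry of a model variant
#'
#' Returns the ordered layer list (one row per entry) for `variant` applied
#' to an input of `n_channels x n_samples`, with 1-based contiguous
#' indices, layer kinds, parameter counts and, for convolutional entries,
#' the shape metadata `(K1, K2, Cin, Cout, Hout, Wout)` used by the MAC
#' formulas.
#'
#' @param variant A [model_variant()].
#' @param n_channels Input channel count (9..22).
#' @param n_samples Input samples per trial.
#' @return A `data.frame` with columns `index`, `kind`, `name`,
#'   `param_count`, `K1`, `K2`, `Cin`, `Cout`, `D`, `Hout`, `Wout`,
#'   `frozen`.
#' @export
build_layer_registry <- function(variant, n_channels, n_samples) {
  assert_that(inherits(variant, "model_variant"), "variant required")
  assert_that(is_count(n_channels) && n_channels <= 22,
              "n_channels must lie in 1..22")
  a <- derive_arch(variant, n_channels, n_samples)
  assert_that(a$T >= max(a$K1, a$K2),
              sprintf("input of %d samples is narrower than the widest kernel (%d)",
                      a$T, max(a$K1, a$K2)))
  assert_that(a$T2 >= 1, "input too short for the stage-2 pooling")

  rows <- list()
  add <- function(kind, name, params = 0, shape = NULL) {
    s <- shape %||% rep(NA_real_, 6)
    rows[[length(rows) + 1L]] <<- data.frame(
      kind = kind, name = name, param_count = params,
      K1 = s[1], K2 = s[2], Cin = s[3], Cout = s[4], D = s[5],
      Hout = if (length(s) >= 7) s[6] else NA_real_,
      Wout = s[length(s)], stringsAsFactors = FALSE
    )
  }
  # conv shape metadata: c(K1, K2, Cin, Cout, D, Hout, Wout)
  add("marker", "input")
  add("temporal_conv", "conv_t1", a$F1 * (a$K1 + 1),
      c(1, a$K1, 1, a$F1, NA, a$C, a$T))
  add("batch_norm", "bn_t1", 2 * a$F1)
  add("marker", "branch_a_in")
  add("marker", "branch_b_in")
  add("marker", "temporal_block_end")                        # index 6
  add("spatial_depthwise_conv", "dw1", a$C * a$F1 * a$D,
      c(a$C, 1, a$F1, a$FD, a$D, 1, a$T))
  add("batch_norm", "bn_dw1", 2 * a$FD)
  add("activation", "elu_a1")
  add("dropout", "drop_a1")
  add("spatial_depthwise_conv", "dw2", a$F2 * a$D2,
      c(1, 1, a$F2, a$F2, a$D2, 1, a$T))
  add("batch_norm", "bn_dw2", 2 * a$F2)
  add("activation", "elu_a2")
  add("pooling", "pool_a2")
  add("dropout", "drop_a2")
  add("marker", "spatial_block_end")                         # index 16
  add("pooling", "chmean_b1")
  add("separable_conv", "sep1", a$F1 * a$KE2 + a$F1 * a$FD + a$FD,
      c(1, a$KE2, a$F1, a$FD, NA, 1, a$T))
  add("batch_norm", "bn_sep1", 2 * a$FD)
  add("activation", "elu_b1")
  add("dropout", "drop_b1")
  add("separable_conv", "sep2", a$F2 * a$KE2b + a$F2 * a$F2 + a$F2,
      c(1, a$KE2b, a$F2, a$F2, NA, 1, a$T))
  add("batch_norm", "bn_sep2", 2 * a$F2)
  add("activation", "elu_b2")
  add("pooling", "pool_b2")
  add("dropout", "drop_b2")                                  # index 26
  add("marker", "concat1")
  add("marker", "att1_in")
  add("attention_sub", "att1_sa_mean")
  add("attention_sub", "att1_sa_max")
  add("attention_sub", "att1_sa_stack")
  add("attention_sub", "att1_sa_conv", 2 * a$Ks + 1,
      c(1, a$Ks, 2, 1, NA, 1, a$T))
  add("attention_sub", "att1_sa_bn", 2)
  add("attention_sub", "att1_sa_sigmoid")
  add("attention_sub", "att1_sa_scale")
  add("marker", "att1_sa_out")
  add("marker", "att1_ca_in")
  add("attention_sub", "att1_ca_avgpool")
  add("attention_sub", "att1_ca_d1_avg", a$M1 * a$H1 + a$H1)
  add("attention_sub", "att1_ca_act_avg")
  add("attention_sub", "att1_ca_d2_avg", a$H1 * a$M1 + a$M1)
  add("attention_sub", "att1_ca_maxpool")
  add("attention_sub", "att1_ca_d1_max", a$M1 * a$H1 + a$H1)
  add("attention_sub", "att1_ca_act_max")                    # index 44
  add("attention_sub", "att1_ca_d2_max", a$H1 * a$M1 + a$M1)
  add("attention_sub", "att1_ca_add")
  add("attention_sub", "att1_ca_sigmoid")
  add("attention_sub", "att1_ca_scale")
  add("marker", "att1_out")
  add("temporal_conv", "proj", a$M1 * a$F2 + a$F2,
      c(1, 1, a$M1, a$F2, NA, 1, a$T))
  add("batch_norm", "bn_proj", 2 * a$F2)
  add("temporal_conv", "conv_t2", a$F2 * a$K2 * a$F2 + a$F2,
      c(1, a$K2, a$F2, a$F2, NA, 1, a$T))
  add("batch_norm", "bn_t2", 2 * a$F2)
  add("marker", "concat2")
  add("marker", "att2_in")
  add("attention_sub", "att2_sa_mean")
  add("attention_sub", "att2_sa_max")
  add("attention_sub", "att2_sa_stack")
  add("attention_sub", "att2_sa_conv", 2 * a$Ks + 1,
      c(1, a$Ks, 2, 1, NA, 1, a$T2))
  add("attention_sub", "att2_sa_bn", 2)
  add("attention_sub", "att2_sa_sigmoid")
  add("attention_sub", "att2_sa_scale")
  add("marker", "att2_sa_out")
  add("attention_sub", "att2_ca_avgpool")
  add("attention_sub", "att2_ca_d1_avg", a$M2 * a$H2 + a$H2)
  add("attention_sub", "att2_ca_act_avg")
  add("attention_sub", "att2_ca_d2_avg", a$H2 * a$M2 + a$M2)
  add("attention_sub", "att2_ca_maxpool")
  add("attention_sub", "att2_ca_d1_max", a$M2 * a$H2 + a$H2)
  add("attention_sub", "att2_ca_act_max")
  add("attention_sub", "att2_ca_d2_max", a$H2 * a$M2 + a$M2)
  add("attention_sub", "att2_ca_add")
  add("attention_sub", "att2_ca_sigmoid")
  add("attention_sub", "att2_ca_scale")
  add("marker", "att2_out")
  add("marker", "flatten")
  add("dense", "dense", a$M2 * a$T2 * a$n_classes + a$n_classes)
  add("softmax", "softmax")

  reg <- do.call(rbind, rows)
  reg$index <- seq_len(nrow(reg))
  reg$frozen <- FALSE
  reg[, c("index", "kind", "name", "param_count", "K1", "K2", "Cin",
          "Cout", "D", "Hout", "Wout", "frozen")]
}

#' Published freeze levels
#'
#' The four freeze depths studied for this architecture, plus 0 (nothing
#' frozen): 6 preserves the stage-1 temporal filters, 16 adds the spatial
#' filters, 26 the separable convolutions, 44 parts of the first attention
#' block.
#'
#' @return Integer vector `c(0, 6, 16, 26, 44)`.
#' @export
freeze_levels <- function() c(0L, 6L, 16L, 26L, 44L)

#' Total MAC count of a registry
#'
#' Sums the published MAC formulas over the convolutional entries
#' (temporal, depthwise, separable and attention convolutions); all other
#' entries contribute zero.
#'
#' @param registry A registry from [build_layer_registry()], or a
#'   `model_handle`.
#' @return Total multiply-accumulate count.
#' @export
total_mac <- function(registry) {
  if (inherits(registry, "model_handle")) registry <- registry$registry
  tot <- 0
  for (i in seq_len(nrow(registry))) {
    r <- registry[i, ]
    if (r$kind %in% c("temporal_conv", "spatial_depthwise_conv")) {
      assert_that(!anyNA(c(r$K1, r$K2, r$Cin, r$Hout, r$Wout)),
                  sprintf("entry %d (%s) lacks shape metadata", r$index, r$name))
      tot <- tot + if (r$kind == "spatial_depthwise_conv") {
        mac_depthwise_conv2d(r$K1, r$K2, r$Cin, r$D, r$Hout, r$Wout)
      } else {
        mac_conv2d(r$K1, r$K2, r$Cin, r$Cout, r$Hout, r$Wout)
      }
    } else if (r$kind == "separable_conv") {
      assert_that(!anyNA(c(r$K1, r$K2, r$Cin, r$Cout, r$Hout, r$Wout)),
                  sprintf("entry %d (%s) lacks shape metadata", r$index, r$name))
      tot <- tot + mac_separable_conv2d(r$K1, r$K2, r$Cin, r$Cout, r$Hout, r$Wout)
    } else if (r$kind == "attention_sub" && !is.na(r$K2)) {
      tot <- tot + mac_conv2d(r$K1, r$K2, r$Cin, r$Cout, r$Hout, r$Wout)
    }
  }
  tot
}

#' Count trainable parameters
#'
#' Sum of `param_count` over the non-frozen registry entries.
#'
#' @param model A `model_handle` or a registry data frame.
#' @return Integer-valued count.
#' @export
count_trainable_params <- function(model) {
  reg <- if (inherits(model, "model_handle")) model$registry else model
  sum(reg$param_count[!reg$frozen])
}

#' Total parameters of a model
#' @param model A `model_handle` or registry data frame.
#' @export
count_total_params <- function(model) {
  reg <- if (inherits(model, "model_handle")) model$registry else model
  sum(reg$param_count)
}
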