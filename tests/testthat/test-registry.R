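# Model variants, the flat layer registry, freeze-by-index semantics and
# parameter/MAC accounting.

test_that("the three published variants carry their stage hyperparameters", {
  f <- model_variant("FCNNA")
  expect_equal(unlist(f$stage1), c(F1 = 96, KE1 = 60, D = 2, KE2 = 16))
  expect_equal(unlist(f$stage2), c(F1 = 16, KE1 = 64, D = 1, KE2 = 16))
  x <- model_variant("XFCNN")
  expect_equal(x$stage1$F1, 16)
  expect_equal(x$stage1$KE1, 60)
  l <- model_variant("LFCNN")
  expect_equal(unlist(l$stage1), c(F1 = 8, KE1 = 48, D = 2, KE2 = 16))
  expect_equal(l$n_classes, 4)
  expect_error(model_variant("EEGNET"))
})

test_that("registry indices are contiguous and counts are consistent", {
  for (nm in c("FCNNA", "XFCNN", "LFCNN")) {
    reg <- build_layer_registry(model_variant(nm), 22, 1125)
    expect_equal(reg$index, seq_len(nrow(reg)))
    expect_true(all(reg$param_count >= 0))
    expect_equal(sum(reg$param_count), count_total_params(reg))
    expect_true(all(reg$param_count[reg$kind == "marker"] == 0))
  }
})

test_that("freeze levels land on the documented semantic boundaries", {
  reg <- build_layer_registry(model_variant("FCNNA"), 22, 1125)
  # prefix 6: stage-1 temporal filters and their norm only
  conv_rows <- which(reg$kind %in% c("temporal_conv", "spatial_depthwise_conv",
                                     "separable_conv"))
  expect_equal(reg$name[reg$index <= 6 & reg$kind == "temporal_conv"], "conv_t1")
  # prefix 16 adds both spatial depthwise blocks
  expect_setequal(reg$name[reg$index <= 16 & reg$kind == "spatial_depthwise_conv"],
                  c("dw1", "dw2"))
  # prefix 26 adds both separable blocks
  expect_setequal(reg$name[reg$index <= 26 & reg$kind == "separable_conv"],
                  c("sep1", "sep2"))
  # prefix 44 reaches into the first attention block but not past it
  att1 <- reg$index[grepl("^att1", reg$name)]
  expect_true(44 > min(att1) && 44 < max(att1) + 2)
  expect_true(all(c(0, 6, 16, 26, 44) <= nrow(reg)))
})

test_that("count_trainable_params matches a hand-enumerated toy registry", {
  toy <- data.frame(index = 1:4,
                    kind = c("temporal_conv", "batch_norm", "dense", "softmax"),
                    name = c("a", "b", "c", "d"),
                    param_count = c(12, 4, 9, 0),
                    frozen = c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(count_trainable_params(toy), 4 + 9)
  toy$frozen <- FALSE
  expect_equal(count_trainable_params(toy), 25)
})

test_that("freezing is monotone and spans 0 to the full registry", {
  m <- build_model(model_variant("LFCNN"), 12, 96, seed = 1)
  total <- count_total_params(m)
  counts <- vapply(freeze_levels(), function(lv)
    count_trainable_params(set_freeze_level(m, lv)), numeric(1))
  expect_equal(counts[1], total)                     # level 0: all trainable
  expect_true(all(diff(counts) <= 0))
  expect_equal(count_trainable_params(set_freeze_level(m, nrow(m$registry))), 0)
  expect_error(set_freeze_level(m, nrow(m$registry) + 1), "exceeds")
  expect_error(set_freeze_level(m, -1), "non-negative")
})

test_that("trainable counts beyond level 16 ignore the channel count", {
  for (nm in c("FCNNA", "LFCNN")) {
    m22 <- build_model(model_variant(nm), 22, 1125, seed = 1)
    m12 <- build_model(model_variant(nm), 12, 1125, seed = 1)
    for (lv in c(16, 26, 44)) {
      expect_equal(count_trainable_params(set_freeze_level(m22, lv)),
                   count_trainable_params(set_freeze_level(m12, lv)))
    }
    # below 16 the spatial depthwise filters make the counts differ
    expect_gt(count_trainable_params(set_freeze_level(m22, 6)),
              count_trainable_params(set_freeze_level(m12, 6)))
  }
})

test_that("total_mac sums the conv entries and needs shape metadata", {
  reg <- build_layer_registry(model_variant("LFCNN"), 22, 1125)
  one <- reg[reg$name == "conv_t1", ]
  expect_equal(total_mac(one),
               mac_conv2d(one$K1, one$K2, one$Cin, one$Cout, one$Hout, one$Wout))
  broken <- reg
  broken$Wout[broken$name == "conv_t1"] <- NA
  expect_error(total_mac(broken), "shape metadata")
})

test_that("two builds from one seed share identical initial weights", {
  a <- build_model(model_variant("LFCNN"), 12, 96, seed = 7)
  b <- build_model(model_variant("LFCNN"), 12, 96, seed = 7)
  expect_identical(a$params, b$params)
  c <- build_model(model_variant("LFCNN"), 12, 96, seed = 8)
  expect_false(identical(a$params, c$params))
})

test_that("inputs narrower than the widest kernel are rejected", {
  expect_error(build_model(model_variant("LFCNN"), 12, 40), "kernel")
})

test_that("model checkpoints round-trip through save/load", {
  m <- set_freeze_level(build_model(model_variant("LFCNN"), 12, 96, seed = 3), 26)
  dir <- tempfile()
  save_model(m, dir)
  back <- load_model(dir)
  expect_identical(back$params, m$params)
  expect_equal(back$freeze_level, 26)
  expect_equal(back$registry$frozen, m$registry$frozen)
  expect_equal(back$variant$name, "LFCNN")
})
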