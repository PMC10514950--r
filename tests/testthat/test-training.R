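test_that("label smoothing follows y(1-eps) + eps/2", {
  m <- matrix(c(0L, 1L), 1, 2)
  expect_equal(smooth_labels(m, 0), m * 1.0)
  expect_equal(smooth_labels(m, 0.1), matrix(c(0.05, 0.95), 1, 2))
  expect_error(smooth_labels(m, 1), "eps")
})

test_that("weighted BCE matches closed forms and reduces at w = 1", {
  one <- matrix(0.5, 1, 1)
  expect_equal(weighted_bce(one, matrix(1, 1, 1), 8), 8 * log(2))
  expect_equal(weighted_bce(one, matrix(0, 1, 1), 8), log(2))
  expect_equal(weighted_bce(one, matrix(0, 1, 1), 3), log(2))

  hard <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_lt(weighted_bce(hard, hard, 5), 1e-5)   # p = t at clamped extremes

  set.seed(4)
  p <- matrix(runif(64, 0.01, 0.99), 8, 8)
  t <- matrix(runif(64), 8, 8)
  plain <- -mean(t * log(p) + (1 - t) * log(1 - p))
  expect_equal(weighted_bce(p, t, 1), plain)
  expect_error(weighted_bce(p, t[1:4, 1:4], 1), "shape")
})

test_that("loss is monotone in p for pure targets", {
  grid <- seq(0.02, 0.98, by = 0.02)
  l1 <- vapply(grid, function(p) {
    weighted_bce(matrix(p, 1, 1), matrix(1, 1, 1), 2)
  }, numeric(1))
  l0 <- vapply(grid, function(p) {
    weighted_bce(matrix(p, 1, 1), matrix(0, 1, 1), 2)
  }, numeric(1))
  expect_true(all(diff(l1) < 0))
  expect_true(all(diff(l0) > 0))
})

test_that("learning-rate schedule decays at 30/60/90% of the epochs", {
  cfg <- train_config("cytoplasm", epochs = 20L)
  expect_equal(lr_at_epoch(0, cfg), 1e-3)
  expect_equal(lr_at_epoch(5, cfg), 1e-3)   # floor(0.3*20) = 6
  expect_equal(lr_at_epoch(6, cfg), 1e-4)
  expect_equal(lr_at_epoch(12, cfg), 1e-5)
  expect_equal(lr_at_epoch(18, cfg), 1e-6)
  expect_error(lr_at_epoch(20, cfg), "range")
  expect_error(lr_at_epoch(-1, cfg), "range")
})

test_that("lookahead updates only on synchronization steps", {
  up <- lookahead_update(2, 0, step = 5, k = 5, alpha = 0.5)
  expect_equal(up, list(fast = 1, slow = 1))
  same <- lookahead_update(2, 0, step = 3, k = 5, alpha = 0.5)
  expect_equal(same, list(fast = 2, slow = 0))
  full <- lookahead_update(c(2, 4), c(0, 0), step = 10, k = 5, alpha = 1)
  expect_equal(full$slow, c(2, 4))
  expect_equal(full$fast, c(2, 4))
  expect_error(lookahead_update(1, 0, 1, k = 0, alpha = 0.5), "k")
  expect_error(lookahead_update(1, 0, 1, k = 5, alpha = 2), "alpha")
})

test_that("geometric augmentation moves image and masks together", {
  s <- tiny_samples(1)[[1]]
  W <- ncol(s$cytoplasm_mask)
  flipped <- augment(s, force = list(hflip = TRUE))
  expect_equal(flipped$image[, W:1, ], s$image)
  expect_equal(flipped$cytoplasm_mask[, W:1], s$cytoplasm_mask)
  expect_equal(flipped$nucleus_mask[, W:1], s$nucleus_mask)
  # a marked coordinate follows the flip in both image and mask
  expect_equal(flipped$cytoplasm_mask[5, W - 7], s$cytoplasm_mask[5, 8])

  bright <- augment(s, force = list(brightness = TRUE,
                                    brightness_delta = 0.1))
  expect_identical(bright$cytoplasm_mask, s$cytoplasm_mask)
  expect_identical(bright$nucleus_mask, s$nucleus_mask)
  expect_false(identical(bright$image, s$image))

  a1 <- augment(s, rng_state = 99L)
  a2 <- augment(s, rng_state = 99L)
  expect_identical(a1, a2)
  expect_true(all(a1$cytoplasm_mask %in% c(0, 1)))
  expect_true(all(a1$nucleus_mask %in% c(0, 1)))
})

test_that("select_best picks minimum validation loss with early tie-break", {
  mk <- function(vals) list(model = sum(vals),
                            history = data.frame(val_loss = vals))
  runs <- list(mk(c(0.4, 0.31)), mk(c(0.5, 0.28)), mk(c(0.30, 0.35)))
  expect_identical(select_best(runs), runs[[2]])
  expect_identical(select_best(runs[1]), runs[[1]])
  tie <- list(mk(0.3), mk(0.3), mk(0.4))
  expect_identical(select_best(tie), tie[[1]])
  expect_error(select_best(list()), "no runs")
})

test_that("train_model honours epochs = 0 and the determinism contract", {
  samples <- tiny_samples(10)
  spec <- model_spec("unet", "resnet34", tiny = TRUE)
  cfg0 <- tiny_train_config("cytoplasm", epochs = 0L)
  init <- train_model(spec, cfg0, samples[1:8], samples[9:10])
  expect_equal(nrow(init$history), 0)
  expect_false(init$model$trained)
  expect_length(init$model$params, count_parameters(init$model))

  cfg1 <- tiny_train_config("cytoplasm", seed = 5L, epochs = 1L)
  r1 <- train_model(spec, cfg1, samples[1:8], samples[9:10])
  r2 <- train_model(spec, cfg1, samples[1:8], samples[9:10])
  expect_equal(r1$history$val_loss, r2$history$val_loss)
  expect_identical(r1$model$params, r2$model$params)
  expect_error(train_model(spec, cfg1, list(), samples[9:10]), "non-empty")
})

test_that("a briefly trained tiny model beats the trivial predictors", {
  samples <- tiny_samples(72, seed = 19)
  spec <- model_spec("unet", "resnet34", tiny = TRUE)
  cfg <- tiny_train_config("cytoplasm", seed = 2L, epochs = 3L)
  run <- train_model(spec, cfg, samples[1:64], samples[65:68])
  test <- samples[69:72]
  maps <- predict(run$model, lapply(test, `[[`, "image"), task = "cytoplasm")
  preds <- lapply(maps, threshold_map)
  truths <- lapply(test, `[[`, "cytoplasm_mask")
  dice <- evaluate_micro(preds, truths)$metrics$dice

  h <- nrow(truths[[1]]); w <- ncol(truths[[1]])
  all_pos <- lapply(truths, function(t) matrix(1L, h, w))
  dice_pos <- evaluate_micro(all_pos, truths)$metrics$dice
  expect_gt(dice, 0)          # all-negative predictor has Dice 0
  expect_gt(dice, dice_pos)
})
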