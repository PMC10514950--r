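pm <- function(x, task = "cytoplasm") probability_map(task, x)

test_that("averaging reduces correctly in identity cases", {
  p <- matrix(runif(16), 4, 4)
  maps <- lapply(1:4, function(i) pm(p))
  avg <- average_probabilities(maps)
  expect_equal(avg$probs, p)

  vals <- c(0.6, 0.4, 0.5, 0.7)
  maps2 <- lapply(vals, function(v) pm(matrix(v, 2, 2)))
  expect_equal(average_probabilities(maps2)$probs, matrix(0.55, 2, 2))

  cfg_w <- ensemble_config("weighted", M = 4, weights = rep(1, 4))
  expect_equal(average_probabilities(maps2, cfg_w)$probs,
               average_probabilities(maps2)$probs)
})

test_that("averaging is permutation invariant and bounded by inputs", {
  set.seed(5)
  maps <- lapply(1:4, function(i) pm(matrix(runif(64), 8, 8)))
  a <- average_probabilities(maps)
  b <- average_probabilities(maps[c(3, 1, 4, 2)])
  expect_equal(a$probs, b$probs)
  lo <- Reduce(pmin, lapply(maps, `[[`, "probs"))
  hi <- Reduce(pmax, lapply(maps, `[[`, "probs"))
  expect_true(all(a$probs >= lo - 1e-12) && all(a$probs <= hi + 1e-12))
})

test_that("mismatched inputs are rejected", {
  maps <- lapply(1:3, function(i) pm(matrix(0.5, 4, 4)))
  expect_error(average_probabilities(maps, ensemble_config(M = 4)), "4")
  mixed <- c(maps[1:2], list(pm(matrix(0.5, 4, 4), task = "nucleus")))
  expect_error(average_probabilities(mixed, ensemble_config(M = 3)),
               "mixed tasks")
  shapes <- c(maps[1:2], list(pm(matrix(0.5, 2, 2))))
  expect_error(average_probabilities(shapes, ensemble_config(M = 3)),
               "shape")
})

test_that("validation-loss weights are normalized inverse losses", {
  expect_equal(weights_from_val_losses(rep(0.3, 4)), rep(0.25, 4))
  expect_equal(weights_from_val_losses(c(0.1, 0.2)), c(2 / 3, 1 / 3))
  set.seed(6)
  for (i in 1:20) {
    l <- runif(sample(2:6, 1), 0.01, 2)
    w <- weights_from_val_losses(l)
    expect_equal(sum(w), 1)
    expect_equal(order(w), order(-l))   # lower loss -> higher weight
  }
  expect_error(weights_from_val_losses(c(0.1, 0)), "positive")
})

test_that("thresholding is strict so exact 0.5 goes negative", {
  m <- pm(matrix(c(0.55, 0.5, 0.49999, 0), 2, 2))
  out <- threshold_map(m, 0.5)
  expect_equal(out$mask, matrix(c(1L, 0L, 0L, 0L), 2, 2))
  expect_equal(threshold_map(pm(matrix(0, 3, 3)))$mask, matrix(0L, 3, 3))
  expect_error(threshold_map(m, 1.5), "threshold")
})

test_that("an ensemble of copies reproduces the single model decision", {
  set.seed(7)
  p <- matrix(runif(36), 6, 6)
  maps <- lapply(1:4, function(i) pm(p))
  ens <- threshold_map(average_probabilities(maps), 0.5)
  single <- threshold_map(pm(p), 0.5)
  expect_equal(ens$mask, single$mask)
})
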