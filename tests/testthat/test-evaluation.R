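test_that("confusion_counts matches enumeration and the pixel-loop oracle", {
  pred <- matrix(c(1, 1, 0, 1), 2, 2, byrow = TRUE)  # [[1,0],[1,1]]
  truth <- matrix(c(1, 1, 0, 1), 2, 2)
  cc <- confusion_counts(pred, truth)
  oracle <- loop_confusion(pred, truth)
  expect_equal(unclass(cc)[c("tp", "fp", "fn", "tn")], oracle)

  m <- random_mask(5, 5)
  same <- confusion_counts(m, m)
  expect_equal(same$fp, 0)
  expect_equal(same$fn, 0)

  set.seed(11)
  for (i in 1:5) {
    p <- random_mask(16, 16, 0.4); t <- random_mask(16, 16, 0.6)
    expect_equal(unclass(confusion_counts(p, t))[c("tp", "fp", "fn", "tn")],
                 loop_confusion(p, t))
  }
  expect_error(confusion_counts(random_mask(4, 4), random_mask(5, 5)),
               "shape")
  expect_error(confusion_counts(binary_mask("cytoplasm", random_mask(4, 4)),
                                binary_mask("nucleus", random_mask(4, 4))),
               "task")
})

test_that("compute_metrics matches closed forms and conventions", {
  m <- compute_metrics(new_counts_for_test(tp = 2, fp = 1, fn = 1, tn = 6))
  expect_equal(m$dice, 2 * 2 / (2 * 2 + 1 + 1))
  expect_equal(m$sensitivity, 2 / 3)
  expect_equal(m$specificity, 6 / 7)

  perfect <- compute_metrics(new_counts_for_test(5, 0, 0, 5))
  expect_equal(unlist(perfect), c(dice = 1, sensitivity = 1,
                                  specificity = 1))

  vac <- compute_metrics(new_counts_for_test(0, 0, 0, 9))
  expect_equal(vac$dice, 1)
  expect_equal(vac$sensitivity, 1)
  expect_equal(vac$specificity, 1)
  expect_error(compute_metrics(new_counts_for_test(0, 0, 0, 0)), "empty")
})

test_that("micro-averaging is invariant to image grouping", {
  set.seed(3)
  preds <- lapply(1:6, function(i) random_mask(8, 8))
  truths <- lapply(1:6, function(i) random_mask(8, 8))
  whole <- evaluate_micro(preds, truths)

  # duplicate every image: ratios unchanged
  dup <- evaluate_micro(c(preds, preds), c(truths, truths))
  expect_equal(dup$metrics, whole$metrics)

  # arbitrary regrouping into one big raster
  big_p <- do.call(cbind, preds); big_t <- do.call(cbind, truths)
  expect_equal(evaluate_micro(list(big_p), list(big_t))$metrics,
               whole$metrics)

  # single image reduces to compute_metrics(confusion_counts(.))
  one <- evaluate_micro(preds[1], truths[1])
  expect_equal(one$metrics,
               compute_metrics(confusion_counts(preds[[1]], truths[[1]])))
  expect_error(evaluate_micro(preds, truths[1:3]), "misaligned")
})

test_that("AUC equals the positive-negative ranking probability", {
  pm <- probability_map("nucleus", matrix(c(0.9, 0.4, 0.6, 0.2), 2, 2))
  tm <- binary_mask("nucleus", matrix(c(1, 1, 0, 0), 2, 2))
  r <- roc_auc(list(pm), list(tm))
  expect_equal(r$auc, 0.75)
  expect_equal(r$auc, pairwise_auc(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0)))

  sep <- probability_map("nucleus", matrix(c(0.9, 0.8, 0.2, 0.1), 2, 2))
  expect_equal(roc_auc(list(sep), list(tm))$auc, 1)

  flat <- probability_map("nucleus", matrix(0.5, 2, 2))
  expect_equal(roc_auc(list(flat), list(tm))$auc, 0.5)

  expect_error(roc_auc(list(flat),
                       list(binary_mask("nucleus", matrix(1, 2, 2)))),
               "degenerate")
})

test_that("ranking AUC equals trapezoidal integration of the ROC curve", {
  set.seed(8)
  for (i in 1:10) {
    n <- 60
    probs <- round(runif(n), 2)          # force ties
    y <- as.integer(runif(n) < 0.4)
    if (sum(y) == 0 || sum(y) == n) next
    pm <- probability_map("nucleus", matrix(probs, 6, 10))
    tm <- binary_mask("nucleus", matrix(y, 6, 10))
    r <- roc_auc(list(pm), list(tm))
    trap <- sum(diff(r$points$fpr) *
                (utils::head(r$points$tpr, -1) + utils::tail(r$points$tpr, -1)) / 2)
    expect_equal(r$auc, trap, tolerance = 1e-9)
    expect_equal(r$auc, pairwise_auc(probs, y))
  }
})

test_that("bootstrap CI is seeded, degenerate when perfect, and shrinks with N", {
  perfect <- new_counts_for_test(40, 0, 0, 60)
  ci <- bootstrap_ci(perfect, "dice", eval_config(B = 200, seed = 4))
  expect_equal(c(ci$lo, ci$hi), c(1, 1))

  cc <- new_counts_for_test(35, 6, 5, 54)
  ci1 <- bootstrap_ci(cc, "dice", eval_config(B = 300, seed = 9))
  ci2 <- bootstrap_ci(cc, "dice", eval_config(B = 300, seed = 9))
  expect_identical(ci1, ci2)
  expect_true(ci1$lo <= ci1$point && ci1$point <= ci1$hi)

  # same error rates, N = 1e3 vs 1e5
  small <- new_counts_for_test(350, 60, 50, 540)
  large <- new_counts_for_test(35000, 6000, 5000, 54000)
  w_small <- with(bootstrap_ci(small, "dice", eval_config(B = 400, seed = 2)),
                  hi - lo)
  w_large <- with(bootstrap_ci(large, "dice", eval_config(B = 400, seed = 2)),
                  hi - lo)
  expect_lt(w_large, w_small)
  expect_error(bootstrap_ci(cc, "f1", eval_config()), "unknown metric")
})

test_that("category counts are sufficient for per-pixel resampling", {
  # a pixel bootstrap replicate is fully described by how many resampled
  # pixels fall in each confusion category: resample indices naively,
  # tabulate, and check the metric agrees with the pixel-loop metric
  set.seed(13)
  pred <- random_mask(2, 5); truth <- random_mask(2, 5)
  cats <- 1 + pred + 2 * truth             # 1=tn 2=fp 3=fn 4=tp
  for (rep in 1:20) {
    idx <- sample(10, 10, replace = TRUE)
    drawn <- tabulate(cats[idx], nbins = 4)
    counts <- new_counts_for_test(tp = drawn[4], fp = drawn[2],
                                  fn = drawn[3], tn = drawn[1])
    # oracle: score the resampled pixel list directly
    rp <- pred[idx]; rt <- truth[idx]
    dice_oracle <- if (sum(rp) + sum(rt) == 0) 1 else
      2 * sum(rp & rt) / (sum(rp) + sum(rt))
    expect_equal(compute_metrics(counts)$dice, dice_oracle)
  }
})

test_that("percentile interval covers the point estimate in Monte Carlo", {
  set.seed(17)
  hits <- 0; trials <- 40
  for (i in 1:trials) {
    n <- 400
    counts <- as.vector(stats::rmultinom(1, n, c(0.3, 0.1, 0.08, 0.52)))
    cc <- new_counts_for_test(counts[1], counts[2], counts[3], counts[4])
    ci <- bootstrap_ci(cc, sample(c("dice", "sensitivity", "specificity"), 1),
                       eval_config(B = 200, seed = i))
    if (ci$lo <= ci$point && ci$point <= ci$hi) hits <- hits + 1
  }
  expect_gte(hits / trials, 0.95)
})

test_that("paired bootstrap test behaves at the extremes", {
  truths <- lapply(1:4, function(i) random_mask(6, 6))
  cfgB <- eval_config(B = 500, seed = 3)

  pA <- truths                                     # A = truth exactly
  same <- paired_bootstrap_test(pA, pA, truths, "dice", cfgB)
  expect_equal(same$p_value, 1)
  expect_equal(same$observed_diff, 0)

  pB <- lapply(truths, function(t) 1L - t)         # B always wrong
  win <- paired_bootstrap_test(pA, pB, truths, "dice", cfgB)
  expect_equal(win$p_value, 1 / 500)
  expect_gt(win$observed_diff, 0)
  expect_error(paired_bootstrap_test(pA, pB[1:2], truths, "dice", cfgB),
               "misaligned")
})

test_that("report table recomputes published average rows", {
  nuc_dice <- list(u_r34 = list(dice = 0.7411, sensitivity = 0.9431,
                                specificity = 0.9951),
                   u_d121 = list(dice = 0.7506, sensitivity = 0.9566,
                                 specificity = 0.9952),
                   upp_r34 = list(dice = 0.8055, sensitivity = 0.9481,
                                  specificity = 0.9967),
                   upp_d121 = list(dice = 0.7731, sensitivity = 0.9653,
                                   specificity = 0.9957))
  rep <- summarize_report(nuc_dice)
  expect_equal(rep$table["Average value", "dice"], 0.7676)
  expect_equal(rep$table["Average value", "specificity"], 0.9957)

  one <- summarize_report(nuc_dice[1])
  expect_equal(one$table["Average value", ], one$table[1, ],
               ignore_attr = TRUE)
})
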