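# Micro-averaged segmentation metrics, ROC/AUC, pixel-level bootstrap
# confidence intervals and paired bootstrap comparisons.
#
# Note on the Dice definition: the standard overlap coefficient
# 2TP/(2TP+FP+FN) is used throughout.  (Published versions of this metric
# table occasionally misprint the denominator as 2TP+TN+FP; that reading
# is inconsistent with the reported values and with the baselines.)

#' Evaluation configuration
#'
#' @param B bootstrap replicates (default 500).
#' @param ci_level confidence level for percentile intervals.
#' @param alpha significance threshold for comparisons.
#' @param max_roc_pixels cap on pooled pixels for ROC computation; larger
#'   pools are uniformly subsampled (seeded).
#' @param seed RNG seed for resampling.
#' @return object of class `eval_config`.
#' @export
eval_config <- function(B = 500L, ci_level = 0.95, alpha = 0.05,
                        max_roc_pixels = 2e6, seed = 1L) {
  if (B < 1) stop("B must be >= 1")
  if (!(ci_level > 0 && ci_level < 1)) stop("ci_level must be in (0, 1)")
  structure(list(B = as.integer(B), ci_level = ci_level, alpha = alpha,
                 max_roc_pixels = max_roc_pixels, seed = as.integer(seed)),
            class = "eval_config")
}

new_counts <- function(tp, fp, fn, tn) {
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "confusion_counts")
}

confusion_counts_new <- function() new_counts(0, 0, 0, 0)

#' Pixel confusion counts
#'
#' @param pred,truth [binary_mask()]s (or 0/1 matrices) of equal shape and
#'   task.
#' @return object of class `confusion_counts` with fields tp, fp, fn, tn.
#'   Counts are additive: per-image counts can be accumulated with `+` in
#'   any order.
#' @export
confusion_counts <- function(pred, truth) {
  if (inherits(pred, "binary_mask") && inherits(truth, "binary_mask") &&
      pred$task != truth$task) {
    stop("prediction and truth belong to different tasks")
  }
  p <- mask_matrix(pred); t <- mask_matrix(truth)
  if (!all(dim(p) == dim(t))) stop("shape mismatch")
  tp <- sum(p == 1 & t == 1)
  fp <- sum(p == 1 & t == 0)
  fn <- sum(p == 0 & t == 1)
  tn <- sum(p == 0 & t == 0)
  new_counts(tp, fp, fn, tn)
}

#' @export
`+.confusion_counts` <- function(e1, e2) {
  new_counts(e1$tp + e2$tp, e1$fp + e2$fp, e1$fn + e2$fn, e1$tn + e2$tn)
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp=%g fp=%g fn=%g tn=%g (n=%g)\n",
              x$tp, x$fp, x$fn, x$tn, x$tp + x$fp + x$fn + x$tn))
  invisible(x)
}

#' Dice, sensitivity and specificity from confusion counts
#'
#' `sensitivity = TP/(TP+FN)`, `specificity = TN/(TN+FP)`,
#' `dice = 2TP/(2TP+FP+FN)`.  Vacuous denominators (no positive truth for
#' sensitivity/dice, no negative truth for specificity) return 1: no error
#' was possible.
#'
#' @param counts a `confusion_counts`.
#' @return list with `dice`, `sensitivity`, `specificity`.
#' @export
compute_metrics <- function(counts) {
  n <- counts$tp + counts$fp + counts$fn + counts$tn
  if (n <= 0) stop("empty counts")
  sens <- if (counts$tp + counts$fn == 0) 1 else counts$tp / (counts$tp + counts$fn)
  spec <- if (counts$tn + counts$fp == 0) 1 else counts$tn / (counts$tn + counts$fp)
  dice <- if (2 * counts$tp + counts$fp + counts$fn == 0) 1 else
    2 * counts$tp / (2 * counts$tp + counts$fp + counts$fn)
  list(dice = dice, sensitivity = sens, specificity = spec)
}

#' Micro-averaged metrics over a test set
#'
#' Accumulates confusion counts over every pixel of every image, then
#' computes the metrics once (micro-averaging).  Metrics are therefore
#' invariant to how the pixel population is grouped into images.
#'
#' @param preds,truths aligned lists of [binary_mask()]s / 0-1 matrices.
#' @return list with `counts` and `metrics`.
#' @export
evaluate_micro <- function(preds, truths) {
  if (length(preds) != length(truths)) stop("misaligned prediction/truth lists")
  counts <- confusion_counts_new()
  for (i in seq_along(preds)) {
    counts <- counts + confusion_counts(preds[[i]], truths[[i]])
  }
  list(counts = counts, metrics = compute_metrics(counts))
}

#' Pooled pixel-level ROC curve and AUC
#'
#' Pixels of all images are pooled (uniformly subsampled above
#' `max_roc_pixels`, seeded).  The AUC is the probability that a random
#' positive pixel outranks a random negative one, ties counted half --
#' identical to trapezoidal integration of the ROC curve.
#'
#' @param prob_maps list of [probability_map()]s.
#' @param truths aligned list of truth masks.
#' @param config an [eval_config()].
#' @return list with `points` (data frame: threshold, fpr, tpr) and `auc`.
#' @export
roc_auc <- function(prob_maps, truths, config = eval_config()) {
  if (length(prob_maps) != length(truths)) stop("misaligned lists")
  p <- unlist(lapply(prob_maps, function(m) as.numeric(prob_matrix(m))))
  y <- unlist(lapply(truths, function(m) as.numeric(mask_matrix(m))))
  if (length(p) > config$max_roc_pixels) {
    keep <- with_seed(config$seed,
                      sample(length(p), config$max_roc_pixels))
    p <- p[keep]; y <- y[keep]
  }
  npos <- sum(y == 1); nneg <- sum(y == 0)
  if (npos == 0 || nneg == 0) {
    stop("degenerate truth: both classes must be present")
  }
  r <- rank(p)  # average ranks handle ties as half-wins
  auc <- (sum(r[y == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  ord <- order(p, decreasing = TRUE)
  ps <- p[ord]; ys <- y[ord]
  last <- cumsum(rle(ps)$lengths)   # group ends among tied thresholds
  tpr <- cumsum(ys == 1)[last] / npos
  fpr <- cumsum(ys == 0)[last] / nneg
  points <- data.frame(threshold = c(Inf, ps[last]),
                       fpr = c(0, fpr), tpr = c(0, tpr))
  list(points = points, auc = auc)
}

metric_from_vectors <- function(tp, fp, fn, tn, metric) {
  switch(metric,
    dice = ifelse(2 * tp + fp + fn == 0, 1, 2 * tp / (2 * tp + fp + fn)),
    sensitivity = ifelse(tp + fn == 0, 1, tp / (tp + fn)),
    specificity = ifelse(tn + fp == 0, 1, tn / (tn + fp)),
    stop("unknown metric: ", metric))
}

#' Pixel-level bootstrap confidence interval
#'
#' Each of B replicates resamples the N evaluated pixels with replacement.
#' Because every pixel falls in one of four confusion categories, the
#' resample is drawn as a single multinomial over (tp, fp, fn, tn)/N --
#' distributionally identical to per-pixel index resampling but O(1) per
#' replicate.  The interval is the percentile interval at `ci_level`.
#'
#' @param counts a `confusion_counts` (micro-aggregated).
#' @param metric `"dice"`, `"sensitivity"` or `"specificity"`.
#' @param config an [eval_config()].
#' @return list with `point`, `lo`, `hi`.
#' @export
bootstrap_ci <- function(counts, metric = "dice", config = eval_config()) {
  n <- counts$tp + counts$fp + counts$fn + counts$tn
  if (n <= 0) stop("empty counts")
  point <- metric_from_vectors(counts$tp, counts$fp, counts$fn, counts$tn,
                               metric)
  draws <- with_seed(config$seed, {
    stats::rmultinom(config$B, n,
                     c(counts$tp, counts$fp, counts$fn, counts$tn) / n)
  })
  reps <- metric_from_vectors(draws[1, ], draws[2, ], draws[3, ],
                              draws[4, ], metric)
  a <- (1 - config$ci_level) / 2
  qs <- stats::quantile(reps, c(a, 1 - a), names = FALSE)
  list(point = point, lo = qs[1], hi = qs[2])
}

#' Joint per-image confusion categories for two predictors
#'
#' Tabulates every pixel into the 8 categories (pred_A, pred_B, truth),
#' the sufficient statistic for paired resampling.
#'
#' @param predA,predB,truth aligned masks for one image.
#' @return numeric vector of 8 counts, index `1 + a + 2b + 4t`.
#' @export
joint_confusion <- function(predA, predB, truth) {
  a <- mask_matrix(predA); b <- mask_matrix(predB); t <- mask_matrix(truth)
  if (!all(dim(a) == dim(t)) || !all(dim(b) == dim(t))) {
    stop("shape mismatch")
  }
  idx <- 1 + a + 2 * b + 4 * t
  tabulate(idx, nbins = 8)
}

#' Paired pixel bootstrap comparison of two predictors
#'
#' For each replicate, every image's pixel population is resampled once
#' and both predictors are scored on the same resample (shared draws over
#' the 8 joint categories per image), so the replicate metric difference
#' reflects paired variability.  Two-sided p-value:
#' `2 * min(frac(diff <= 0), frac(diff >= 0))`, floored at `1/B` and
#' capped at 1.
#'
#' @param predsA,predsB,truths aligned lists of masks over the same truth.
#'   Alternatively pass `joint_by_image`, a list of 8-count vectors from
#'   [joint_confusion()], and leave the mask lists NULL.
#' @param metric `"dice"`, `"sensitivity"` or `"specificity"`.
#' @param config an [eval_config()].
#' @param joint_by_image optional precomputed joint category counts.
#' @return list with `p_value`, `observed_diff` (A minus B) and the
#'   replicate differences.
#' @export
paired_bootstrap_test <- function(predsA = NULL, predsB = NULL,
                                  truths = NULL, metric = "dice",
                                  config = eval_config(),
                                  joint_by_image = NULL) {
  if (is.null(joint_by_image)) {
    if (length(predsA) != length(truths) || length(predsB) != length(truths)) {
      stop("misaligned prediction/truth lists")
    }
    joint_by_image <- lapply(seq_along(truths), function(i) {
      joint_confusion(predsA[[i]], predsB[[i]], truths[[i]])
    })
  }
  B <- config$B
  tot <- with_seed(config$seed, {
    acc <- matrix(0, 8, B)
    for (jc in joint_by_image) {
      n <- sum(jc)
      if (n == 0) next
      acc <- acc + stats::rmultinom(B, n, jc / n)
    }
    acc
  })
  marg <- function(m, who) {
    # who = 1 for predictor A (bit a), 2 for predictor B (bit b)
    sel <- function(a, b, t) m[1 + a + 2 * b + 4 * t, , drop = FALSE]
    bit <- function(a, t) {
      if (who == 1) sel(a, 0, t) + sel(a, 1, t) else sel(0, a, t) + sel(1, a, t)
    }
    list(tp = colSums(bit(1, 1)), fp = colSums(bit(1, 0)),
         fn = colSums(bit(0, 1)), tn = colSums(bit(0, 0)))
  }
  ca <- marg(tot, 1); cb <- marg(tot, 2)
  diffs <- metric_from_vectors(ca$tp, ca$fp, ca$fn, ca$tn, metric) -
           metric_from_vectors(cb$tp, cb$fp, cb$fn, cb$tn, metric)
  obs <- Reduce(`+`, joint_by_image)
  oa <- marg(matrix(obs, ncol = 1), 1); ob <- marg(matrix(obs, ncol = 1), 2)
  observed <- metric_from_vectors(oa$tp, oa$fp, oa$fn, oa$tn, metric) -
              metric_from_vectors(ob$tp, ob$fp, ob$fn, ob$tn, metric)
  p <- 2 * min(mean(diffs <= 0), mean(diffs >= 0))
  p <- min(1, max(1 / B, p))
  list(p_value = p, observed_diff = observed, diffs = diffs)
}

# round half away from zero, with a tiny guard against binary
# representation of decimal ties
round_half_up <- function(x, digits = 4) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5 + sqrt(.Machine$double.eps)) / s
}

#' Comparison report of base models and ensemble
#'
#' Builds the comparison table: one row per base model, an "Average value"
#' row holding the arithmetic mean of the base-model metrics, and an
#' "Ensemble" row (optionally with confidence intervals and comparison
#' p-values).  Values are rounded to 4 decimals, halves away from zero.
#'
#' @param per_model named list of metric sets (as from [compute_metrics()]).
#' @param ensemble metric set for the ensemble (optional).
#' @param cis optional named list of `bootstrap_ci()` results keyed by
#'   metric name.
#' @param pvals optional named numeric vector of p-values keyed by metric.
#' @return object of class `metric_report` (list with `table`, `cis`,
#'   `pvals`).
#' @export
summarize_report <- function(per_model, ensemble = NULL, cis = NULL,
                             pvals = NULL) {
  if (!length(per_model)) stop("at least one model required")
  metrics <- c("dice", "sensitivity", "specificity")
  rows <- lapply(per_model, function(m) {
    vapply(metrics, function(k) round_half_up(m[[k]]), numeric(1))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- names(per_model) %||% paste0("model_", seq_along(rows))
  avg <- vapply(metrics, function(k) {
    round_half_up(mean(vapply(per_model, `[[`, numeric(1), k)))
  }, numeric(1))
  tab <- rbind(tab, "Average value" = avg)
  if (!is.null(ensemble)) {
    ens <- vapply(metrics, function(k) round_half_up(ensemble[[k]]),
                  numeric(1))
    tab <- rbind(tab, "Ensemble" = ens)
  }
  structure(list(table = as.data.frame(tab), cis = cis, pvals = pvals),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  print(format(x$table, nsmall = 4))
  if (!is.null(x$cis)) {
    for (k in names(x$cis)) {
      ci <- x$cis[[k]]
      cat(sprintf("ensemble %s: %.4f (CI %.4f-%.4f)\n", k, ci$point,
                  ci$lo, ci$hi))
    }
  }
  if (!is.null(x$pvals)) {
    cat("paired bootstrap p-values:",
        paste(sprintf("%s=%.4g", names(x$pvals), x$pvals), collapse = ", "),
        "\n")
  }
  invisible(x)
}
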