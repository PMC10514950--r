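# Shared fixtures, built in code.  The small synthetic pools are memoised
# per test run so several test files can reuse them.

fixture_env <- new.env(parent = emptyenv())

tiny_synth_config <- function(seed = 7) {
  synthetic_config(image_size = c(64, 64), seed = seed)
}

tiny_samples <- function(n = 12, seed = 7) {
  key <- sprintf("samples_%d_%d", n, seed)
  if (is.null(fixture_env[[key]])) {
    cfg <- tiny_synth_config(seed)
    fixture_env[[key]] <- lapply(seq_len(n), function(i) {
      generate_sample(cfg, i)
    })
  }
  fixture_env[[key]]
}

# brute-force per-pixel confusion oracle
loop_confusion <- function(pred, truth) {
  p <- if (inherits(pred, "binary_mask")) pred$mask else pred
  t <- if (inherits(truth, "binary_mask")) truth$mask else truth
  tp <- fp <- fn <- tn <- 0
  for (r in seq_len(nrow(p))) {
    for (c in seq_len(ncol(p))) {
      if (p[r, c] == 1 && t[r, c] == 1) tp <- tp + 1
      else if (p[r, c] == 1 && t[r, c] == 0) fp <- fp + 1
      else if (p[r, c] == 0 && t[r, c] == 1) fn <- fn + 1
      else tn <- tn + 1
    }
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# brute-force AUC over all positive-negative pairs, ties counted half
pairwise_auc <- function(probs, labels) {
  pos <- probs[labels == 1]; neg <- probs[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

new_counts_for_test <- function(tp, fp, fn, tn) {
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "confusion_counts")
}

random_mask <- function(h, w, p = 0.5) {
  matrix(as.integer(stats::runif(h * w) < p), h, w)
}
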