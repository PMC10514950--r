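# Combining base-model probability maps.

#' Ensemble configuration
#'
#' @param method `"unweighted"` (default; the published choice) or
#'   `"weighted"` (validation-loss weights).
#' @param M number of base models (default 4).
#' @param threshold decision cut-off in (0, 1); a pixel is positive iff its
#'   averaged probability strictly exceeds it (default 0.5).
#' @param weights optional M positive weights (weighted method only);
#'   normalized to sum to 1.
#' @return object of class `ensemble_config`.
#' @export
ensemble_config <- function(method = c("unweighted", "weighted"), M = 4L,
                            threshold = 0.5, weights = NULL) {
  method <- match.arg(method)
  if (M < 1) stop("M must be >= 1")
  if (!(threshold > 0 && threshold < 1)) stop("threshold must be in (0, 1)")
  if (!is.null(weights)) {
    if (length(weights) != M) stop("weights must have length M")
    if (any(weights <= 0)) stop("weights must be positive")
    weights <- weights / sum(weights)
  }
  structure(list(method = method, M = as.integer(M), threshold = threshold,
                 weights = weights), class = "ensemble_config")
}

#' Average probability maps
#'
#' Per-pixel arithmetic mean of the base-model probabilities (unweighted),
#' or the normalized weighted sum.  The ensemble prediction for every
#' pixel is `mean(p_i) > threshold`.
#'
#' @param maps list of [probability_map()]s sharing task and shape; length
#'   must equal `config$M`.
#' @param config an [ensemble_config()].
#' @return a [probability_map()].
#' @export
average_probabilities <- function(maps, config = ensemble_config(M = length(maps))) {
  if (length(maps) != config$M) {
    stop("expected ", config$M, " maps, got ", length(maps))
  }
  task <- maps[[1]]$task
  d <- dim(maps[[1]]$probs)
  for (m in maps) {
    if (m$task != task) stop("probability maps have mixed tasks")
    if (!all(dim(m$probs) == d)) stop("probability map shape mismatch")
  }
  w <- if (config$method == "weighted") {
    if (is.null(config$weights)) stop("weighted method needs weights")
    config$weights
  } else {
    rep(1 / length(maps), length(maps))
  }
  acc <- matrix(0, d[1], d[2])
  for (i in seq_along(maps)) acc <- acc + w[i] * maps[[i]]$probs
  probability_map(task, pmin(pmax(acc, 0), 1))
}

#' Weights from validation losses
#'
#' Inverse-loss weighting: `w_i = (1/loss_i) / sum_j (1/loss_j)`.  Lower
#' validation loss gives higher weight; weights sum to one.
#'
#' @param losses positive validation losses, one per base model.
#' @return normalized weights.
#' @export
weights_from_val_losses <- function(losses) {
  if (any(losses <= 0)) stop("losses must be positive")
  w <- 1 / losses
  w / sum(w)
}

#' Threshold a probability map
#'
#' Strict inequality: a pixel is positive iff `p > threshold`; a pixel at
#' exactly the threshold is negative.
#'
#' @param map a [probability_map()].
#' @param threshold cut-off in (0, 1).
#' @return a [binary_mask()].
#' @export
threshold_map <- function(map, threshold = 0.5) {
  if (!(threshold > 0 && threshold < 1)) stop("threshold must be in (0, 1)")
  p <- prob_matrix(map)
  binary_mask(map$task, matrix(as.integer(p > threshold), nrow(p), ncol(p)))
}
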