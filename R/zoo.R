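#' Describe a candidate segmentation network
#'
#' A model specification names one of the supported encoder-decoder
#' combinations: U-Net and U-Net++ decoders pair with `resnet34` or
#' `densenet121` encoders, DeepLabV3 and DeepLabV3+ heads pair with
#' `resnet34` or `resnet50`.  All networks emit a single-channel per-pixel
#' foreground probability map of the same spatial size as the input.
#'
#' @param architecture one of `"unet"`, `"unetplusplus"`, `"deeplabv3"`,
#'   `"deeplabv3plus"`.
#' @param encoder one of `"resnet34"`, `"resnet50"`, `"densenet121"`.
#' @param init weight initialization: `"scratch"` (He-normal everywhere) or
#'   `"imagenet"` (encoder loaded from a locally supplied ImageNet weights
#'   file, decoder random; see [build_model()]).
#' @param tiny logical; quarter-width variant intended for CPU runs and
#'   tests.  Tiny variants are excluded from parameter-count fidelity
#'   checks.
#' @return an object of class `cytoseg_spec`.
#' @export
model_spec <- function(architecture = c("unet", "unetplusplus", "deeplabv3",
                                        "deeplabv3plus"),
                       encoder = c("resnet34", "resnet50", "densenet121"),
                       init = c("scratch", "imagenet"),
                       tiny = FALSE) {
  architecture <- match.arg(architecture)
  encoder <- match.arg(encoder)
  init <- match.arg(init)
  allowed <- list(
    unet = c("resnet34", "densenet121"),
    unetplusplus = c("resnet34", "densenet121"),
    deeplabv3 = c("resnet34", "resnet50"),
    deeplabv3plus = c("resnet34", "resnet50"))
  if (!encoder %in% allowed[[architecture]]) {
    stop(sprintf("encoder '%s' does not pair with architecture '%s' (allowed: %s)",
                 encoder, architecture,
                 paste(allowed[[architecture]], collapse = ", ")))
  }
  structure(list(architecture = architecture, encoder = encoder,
                 init = init, tiny = isTRUE(tiny), out_channels = 1L),
            class = "cytoseg_spec")
}

#' @export
print.cytoseg_spec <- function(x, ...) {
  cat(sprintf("<cytoseg_spec> %s_%s (init=%s%s)\n", x$architecture,
              x$encoder, x$init, if (x$tiny) ", tiny" else ""))
  invisible(x)
}

spec_name <- function(spec) {
  paste0(spec$architecture, "_", spec$encoder, if (spec$tiny) "_tiny" else "")
}

#' List the supported architecture/encoder combinations
#'
#' Enumerates the eight convolutional candidate models: U-Net and U-Net++
#' with `resnet34`/`densenet121` encoders and DeepLabV3/DeepLabV3+ with
#' `resnet34`/`resnet50` encoders.
#'
#' @param init,tiny passed through to [model_spec()].
#' @return a list of `cytoseg_spec` objects.
#' @export
list_supported <- function(init = "scratch", tiny = FALSE) {
  combos <- rbind(
    c("unet", "resnet34"), c("unet", "densenet121"),
    c("unetplusplus", "resnet34"), c("unetplusplus", "densenet121"),
    c("deeplabv3", "resnet34"), c("deeplabv3", "resnet50"),
    c("deeplabv3plus", "resnet34"), c("deeplabv3plus", "resnet50"))
  lapply(seq_len(nrow(combos)), function(i) {
    model_spec(combos[i, 1], combos[i, 2], init = init, tiny = tiny)
  })
}

#' The four selected base models
#'
#' U-Net and U-Net++ over ResNet-34 and DenseNet-121 encoders: the four
#' networks whose averaged probability maps form the ensemble.
#'
#' @inheritParams list_supported
#' @return a list of four `cytoseg_spec` objects.
#' @export
base_model_specs <- function(init = "scratch", tiny = FALSE) {
  list(model_spec("unet", "resnet34", init, tiny),
       model_spec("unet", "densenet121", init, tiny),
       model_spec("unetplusplus", "resnet34", init, tiny),
       model_spec("unetplusplus", "densenet121", init, tiny))
}

#' Construct a segmentation network
#'
#' Builds the computation graph for a specification.  Weights are
#' materialized lazily: full-width graphs can be built and their parameters
#' counted without allocating ~25M weights.  With `init = "imagenet"` the
#' encoder weights must be supplied as a local RDS file (a named numeric
#' vector matching the encoder parameter layout) via `weights_file` or
#' `options(cytoseg.imagenet_weights = ...)`; pretrained weights are not
#' bundled with the package.
#'
#' @param spec a [model_spec()].
#' @param weights_file optional path to encoder weights for
#'   `init = "imagenet"`.
#' @return an object of class `cytoseg_model`.
#' @export
build_model <- function(spec, weights_file = NULL) {
  stopifnot(inherits(spec, "cytoseg_spec"))
  graph <- build_arch_graph(spec$architecture, spec$encoder,
                            width_mult = if (spec$tiny) 0.25 else 1)
  structure(list(spec = spec, graph = graph, params = NULL, state = NULL,
                 weights_file = weights_file, trained = FALSE),
            class = "cytoseg_model")
}

#' @export
print.cytoseg_model <- function(x, ...) {
  cat(sprintf("<cytoseg_model> %s: %s trainable parameters (%s)\n",
              spec_name(x$spec),
              format(count_parameters(x), big.mark = ","),
              if (is.null(x$params)) "weights not materialized"
              else if (x$trained) "trained" else "initialized"))
  invisible(x)
}

#' Count trainable parameters
#'
#' Total number of trainable scalars (convolution weights and biases,
#' batch-norm scale and shift).  Running batch-norm statistics are not
#' trainable and are excluded, matching the convention under which the
#' full-width counts reproduce the published table (e.g. 24,436,369 for
#' U-Net over ResNet-34).
#'
#' @param model a `cytoseg_model`.
#' @return integer-valued numeric scalar.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "cytoseg_model"))
  model$graph$n_params
}

# He-normal initialization for convolutions; unit scale / zero shift for
# batch-norm.  Deterministic under the current RNG state.
init_params <- function(graph) {
  params <- numeric(graph$n_params)
  for (sh in graph$shapes) {
    if (sh$type == "conv") {
      fan_in <- sh$cin * sh$k * sh$k
      nw <- fan_in * sh$cout
      params[sh$off + seq_len(nw)] <- stats::rnorm(nw, 0, sqrt(2 / fan_in))
      # biases (if any) stay 0
    } else if (sh$type == "dwconv") {
      fan_in <- sh$k * sh$k
      params[sh$off + seq_len(sh$n)] <- stats::rnorm(sh$n, 0, sqrt(2 / fan_in))
    } else if (sh$type == "bn") {
      params[sh$off + seq_len(sh$c)] <- 1
    }
  }
  params
}

init_state <- function(graph) {
  state <- numeric(graph$n_state)
  for (sh in graph$shapes) {
    if (sh$type == "bn") {
      state[sh$soff + sh$c + seq_len(sh$c)] <- 1  # running variance
    }
  }
  state
}

# Materialize weights if absent.  seed governs the random draw.
materialize_weights <- function(model, seed = 1L) {
  if (!is.null(model$params)) return(model)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  model$params <- init_params(model$graph)
  model$state <- init_state(model$graph)
  if (model$spec$init == "imagenet") {
    wf <- model$weights_file %||% getOption("cytoseg.imagenet_weights")
    if (is.null(wf) || !file.exists(wf %||% "")) {
      stop("init='imagenet' needs a local encoder weights RDS ",
           "(set options(cytoseg.imagenet_weights=...) or pass ",
           "weights_file to build_model); pretrained weights are not ",
           "bundled with the package")
    }
    enc_w <- readRDS(wf)
    if (length(enc_w) > length(model$params)) {
      stop("encoder weights file longer than model parameter vector")
    }
    model$params[seq_along(enc_w)] <- as.numeric(enc_w)
  }
  model
}

# normalize an 8-bit image array for a given init convention
normalize_input <- function(image, init) {
  x <- image / 255
  if (init == "imagenet") {
    mean <- c(0.485, 0.456, 0.406)
    sd <- c(0.229, 0.224, 0.225)
    for (ch in 1:3) x[, , ch] <- (x[, , ch] - mean[ch]) / sd[ch]
  }
  x
}

# stack a list of H x W x 3 arrays into the engine input layout
stack_batch <- function(images, init) {
  H <- dim(images[[1]])[1]; W <- dim(images[[1]])[2]
  x <- array(0, c(H, W, 3, length(images)))
  for (i in seq_along(images)) x[, , , i] <- normalize_input(images[[i]], init)
  x
}

# Run the network forward in inference mode; returns H x W x N logits.
model_forward <- function(model, x_batch, training = FALSE) {
  d <- dim(x_batch)
  res <- cpp_net_run(model$graph$nodes, model$params, model$state,
                     as.numeric(x_batch), as.integer(d),
                     training, FALSE, numeric(0), 1)
  array(res$out, c(res$H, res$W, d[4]))
}

#' Predict per-pixel foreground probabilities
#'
#' @param object a trained (or at least materialized) `cytoseg_model`.
#' @param images a list of H x W x 3 arrays with 8-bit values (0-255), or a
#'   single such array.  H and W must be divisible by 32.
#' @param task the segmentation task the map belongs to (`"cytoplasm"` or
#'   `"nucleus"`); recorded in the returned maps.
#' @param batch_size mini-batch size used during inference.
#' @param ... unused.
#' @return a list of [probability_map()] objects.
#' @export
predict.cytoseg_model <- function(object, images, task = "cytoplasm",
                                  batch_size = 8L, ...) {
  if (is.array(images) && length(dim(images)) == 3) images <- list(images)
  object <- materialize_weights(object)
  d <- dim(images[[1]])
  if (d[1] %% 32 != 0 || d[2] %% 32 != 0) {
    stop("input spatial size must be divisible by 32")
  }
  out <- vector("list", length(images))
  idx <- split(seq_along(images),
               ceiling(seq_along(images) / batch_size))
  for (batch in idx) {
    x <- stack_batch(images[batch], object$spec$init)
    z <- model_forward(object, x, training = FALSE)
    for (j in seq_along(batch)) {
      out[[batch[j]]] <- probability_map(task, stats::plogis(z[, , j]))
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

# evaluate an expression under a temporary seed, restoring the RNG after
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  expr
}
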