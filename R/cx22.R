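# Loading Cx22-style data and the train/validation split.

#' Convert a Cx22 MATLAB v7.3 container to the package disk format
#'
#' Cx22 distributes samples as MATLAB `.mat` files in HDF5 format.  The
#' HDF5 decoding is delegated to the system Python interpreter (h5py and
#' Pillow); everything downstream is R.  Dataset keys are auto-discovered
#' by array shape (the stack with a channel axis of size 3 is the image;
#' of the two mask stacks the one with larger foreground is cytoplasm) and
#' can be overridden via `keys`.
#'
#' @param container_path path to the `.mat` / HDF5 container.
#' @param out_dir output directory for PNG triplets.
#' @param keys optional named list/character vector with entries `image`,
#'   `cyto`, `nuc` giving the HDF5 dataset names.
#' @param python path to a Python interpreter with h5py and Pillow.
#' @return number of samples written.
#' @export
convert_cx22_container <- function(container_path, out_dir, keys = NULL,
                                   python = Sys.which("python")) {
  if (!file.exists(container_path)) {
    stop("container not found: ", container_path)
  }
  if (!nzchar(python)) stop("no python interpreter found on PATH")
  script <- system.file("python", "convert_cx22.py", package = "cytoseg")
  if (!nzchar(script)) stop("converter script not installed")
  args <- c(script, container_path, out_dir)
  if (!is.null(keys)) {
    keys <- as.list(keys)
    stopifnot(all(c("image", "cyto", "nuc") %in% names(keys)))
    args <- c(args, jsonlite::toJSON(keys, auto_unbox = TRUE))
  }
  res <- suppressWarnings(
    system2(python, shQuote(args), stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status") %||% 0L
  if (status != 0) {
    stop("container conversion failed: ", paste(res, collapse = "\n"))
  }
  as.integer(res[length(res)])
}

#' Load a dataset directory
#'
#' Reads every sample triplet in `dir` (the package disk format), in
#' lexicographic id order.  Images without both masks (or masks without an
#' image) are orphans and abort the load with their ids.
#'
#' @param dir dataset directory.
#' @return list of [image_sample()]s.
#' @export
load_dataset <- function(dir) {
  files <- list.files(dir, pattern = "\\.png$")
  ids <- sort(unique(sub("(_cyto|_nuc)?\\.png$", "", files)))
  if (!length(ids)) return(list())
  missing <- lapply(ids, function(id) {
    need <- paste0(id, c(".png", "_cyto.png", "_nuc.png"))
    need[!need %in% files]
  })
  bad <- lengths(missing) > 0
  if (any(bad)) {
    stop("orphan sample file(s) for id(s): ", paste(ids[bad], collapse = ", "))
  }
  lapply(ids, function(id) read_sample(dir, id))
}

#' Split sample ids into training and validation sets
#'
#' Uniformly random partition at the image-sample level, deterministic
#' given `seed`.  The training share is `round(ratio * n)`, within one
#' sample of `ratio`.
#'
#' @param ids character vector of sample ids.
#' @param ratio training fraction, in (0, 1); 0.9 reproduces the published
#'   splitting of the 400-image training set into 360/40.
#' @param seed RNG seed for the permutation.
#' @return object of class `dataset_split` with fields `train`, `val`,
#'   `ratio`, `seed`.
#' @export
split_train_val <- function(ids, ratio = 0.9, seed = 1L) {
  if (!(ratio > 0 && ratio < 1)) stop("ratio must be in (0, 1)")
  n <- length(ids)
  n_train <- round(ratio * n)
  perm <- with_seed(seed, sample(n))
  structure(list(train = ids[sort(perm[seq_len(n_train)])],
                 val = ids[sort(perm[setdiff(seq_len(n), seq_len(n_train))])],
                 ratio = ratio, seed = as.integer(seed)),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> %d train / %d val (ratio %.2f, seed %d)\n",
              length(x$train), length(x$val), x$ratio, x$seed))
  invisible(x)
}
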