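# Core domain types and the on-disk sample format.
#
# Conventions used throughout the package: rasters are row-major with the
# origin at the top-left; masks hold {0,1} in memory and {0,255} on disk
# (PNG, lossless); a sample on disk is the triplet <id>.png, <id>_cyto.png,
# <id>_nuc.png in one directory.

#' Construct an image sample
#'
#' One 8-bit RGB image together with its cytoplasm and nucleus ground-truth
#' masks.  Both segmentation tasks are binary: the positive class is
#' cytoplasm (whole-cell region) or nucleus, the negative class background.
#'
#' @param id sample identifier (string).
#' @param image H x W x 3 numeric array with integer values in 0-255.
#' @param cytoplasm_mask,nucleus_mask H x W matrices with values in {0,1}.
#' @return an object of class `image_sample`.
#' @export
image_sample <- function(id, image, cytoplasm_mask, nucleus_mask) {
  s <- structure(list(id = as.character(id), image = image,
                      cytoplasm_mask = cytoplasm_mask,
                      nucleus_mask = nucleus_mask),
                 class = "image_sample")
  v <- validate_sample(s)
  if (length(v)) stop("invalid sample '", id, "': ",
                      paste(v, collapse = "; "))
  s
}

#' @export
print.image_sample <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<image_sample> '%s' %dx%d, cyto %.1f%%, nuc %.1f%% positive\n",
              x$id, d[1], d[2], 100 * mean(x$cytoplasm_mask),
              100 * mean(x$nucleus_mask)))
  invisible(x)
}

#' Validate an image sample
#'
#' Reports every violated invariant without throwing: the image must be an
#' H x W x 3 8-bit raster with H, W >= 16, both masks must share its
#' spatial size and contain only the values 0 and 1.
#'
#' @param sample a list-like with fields `id`, `image`, `cytoplasm_mask`,
#'   `nucleus_mask` (e.g. an [image_sample()]).
#' @return character vector of violations; empty for a conforming sample.
#' @export
validate_sample <- function(sample) {
  v <- character()
  di <- dim(sample$image)
  if (length(di) != 3 || di[3] != 3) {
    v <- c(v, "image is not an H x W x 3 array")
    return(v)
  }
  if (di[1] < 16 || di[2] < 16) v <- c(v, "image smaller than 16 x 16")
  if (any(sample$image < 0 | sample$image > 255)) {
    v <- c(v, "image values outside 0-255")
  }
  for (field in c("cytoplasm_mask", "nucleus_mask")) {
    m <- sample[[field]]
    if (is.null(m)) { v <- c(v, paste0(field, " missing")); next }
    dm <- dim(m)
    if (length(dm) != 2 || dm[1] != di[1] || dm[2] != di[2]) {
      v <- c(v, paste0(field, " shape does not match image"))
      next
    }
    if (!all(m %in% c(0, 1))) v <- c(v, paste0(field, " has non-binary values"))
  }
  v
}

#' Binarize a stored mask raster
#'
#' Stored masks are 8-bit; lossy round trips (the original dataset was
#' JPEG-encoded at some point) can perturb values near 0/255.  A pixel is
#' foreground iff its stored value exceeds 127.
#'
#' @param raster H x W single-channel matrix with values in 0-255.
#' @param task optional task label attached to the result.
#' @return a [binary_mask()] when `task` is given, otherwise a plain 0/1
#'   matrix.
#' @export
binarize_stored_mask <- function(raster, task = NULL) {
  if (!is.null(dim(raster)) && length(dim(raster)) > 2) {
    stop("multi-channel raster: masks must be single-channel")
  }
  m <- matrix(as.integer(raster > 127), nrow = nrow(raster))
  if (is.null(task)) m else binary_mask(task, m)
}

#' Per-pixel foreground probabilities
#'
#' @param task `"cytoplasm"` or `"nucleus"`.
#' @param probs H x W matrix of probabilities in \[0, 1\].
#' @return object of class `probability_map`.
#' @export
probability_map <- function(task, probs) {
  task <- match.arg(task, c("cytoplasm", "nucleus"))
  stopifnot(is.matrix(probs))
  if (any(probs < 0 | probs > 1)) stop("probabilities outside [0, 1]")
  structure(list(task = task, probs = probs), class = "probability_map")
}

#' A binary segmentation mask
#'
#' @param task `"cytoplasm"` or `"nucleus"`.
#' @param mask H x W matrix with values in {0, 1}.
#' @return object of class `binary_mask`.
#' @export
binary_mask <- function(task, mask) {
  task <- match.arg(task, c("cytoplasm", "nucleus"))
  stopifnot(is.matrix(mask))
  if (!all(mask %in% c(0, 1))) stop("mask values must be 0 or 1")
  structure(list(task = task, mask = mask), class = "binary_mask")
}

mask_matrix <- function(x) {
  if (inherits(x, "binary_mask")) x$mask else x
}

prob_matrix <- function(x) {
  if (inherits(x, "probability_map")) x$probs else x
}

# one-pixel interior boundary of a binary mask (pixels set in the mask with
# at least one 4-neighbour outside it)
mask_boundary <- function(mask) {
  m <- mask_matrix(mask)
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(0L, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  core <- pad[2:(H + 1), 2:(W + 1)]
  eroded <- core &
    pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)] &
    pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)]
  (core == 1) & !eroded
}

#' Draw predicted boundaries over an image
#'
#' Renders the one-pixel contours of the predicted cytoplasm and nucleus
#' masks over the sample's image in two distinct colors.  Inputs are not
#' modified.
#'
#' @param sample an [image_sample()].
#' @param pred_cyto,pred_nuc predicted [binary_mask()]s (or 0/1 matrices)
#'   matching the image size.
#' @param cyto_color,nuc_color RGB triplets in 0-255.
#' @return H x W x 3 array in 0-255.
#' @export
render_overlay <- function(sample, pred_cyto, pred_nuc,
                           cyto_color = c(0, 200, 0),
                           nuc_color = c(255, 0, 0)) {
  img <- sample$image
  for (pred in list(pred_cyto, pred_nuc)) {
    m <- mask_matrix(pred)
    if (!all(dim(m) == dim(img)[1:2])) stop("prediction shape mismatch")
  }
  out <- img
  bc <- mask_boundary(pred_cyto)
  bn <- mask_boundary(pred_nuc)
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[bc] <- cyto_color[ch]
    plane[bn] <- nuc_color[ch]     # nucleus drawn on top
    out[, , ch] <- plane
  }
  out
}

# ---- disk format ---------------------------------------------------------

read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("reading JPEG requires the EBImage package")
    }
    img <- EBImage::readImage(path)
    a <- aperm(EBImage::imageData(img), c(2, 1, 3)) # EBImage is x,y ordered
  } else {
    a <- png::readPNG(path)
  }
  if (length(dim(a)) == 3 && dim(a)[3] == 4) a <- a[, , 1:3] # drop alpha
  round(a * 255)
}

read_mask_file <- function(path) {
  a <- read_image_file(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  binarize_stored_mask(a)
}

write_image_file <- function(image, path) {
  png::writePNG(image / 255, path)
}

write_mask_file <- function(mask, path) {
  png::writePNG(mask_matrix(mask) * 1.0, path) # {0,1} -> {0,255} on disk
}

#' Write one sample in the package disk format
#'
#' @param sample an [image_sample()].
#' @param dir output directory (created if needed).
#' @return the sample id, invisibly.
#' @export
write_sample <- function(sample, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_image_file(sample$image, file.path(dir, paste0(sample$id, ".png")))
  write_mask_file(sample$cytoplasm_mask,
                  file.path(dir, paste0(sample$id, "_cyto.png")))
  write_mask_file(sample$nucleus_mask,
                  file.path(dir, paste0(sample$id, "_nuc.png")))
  invisible(sample$id)
}

#' Read one sample from the package disk format
#'
#' @param dir directory holding `<id>.png`, `<id>_cyto.png`, `<id>_nuc.png`.
#' @param id sample identifier.
#' @return an [image_sample()].
#' @export
read_sample <- function(dir, id) {
  image_sample(id,
               read_image_file(file.path(dir, paste0(id, ".png"))),
               read_mask_file(file.path(dir, paste0(id, "_cyto.png"))),
               read_mask_file(file.path(dir, paste0(id, "_nuc.png"))))
}
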