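# Seeded generator of Pap-stain-like cytology images with exact ground
# truth.  Cells are filled rotated ellipses on a light noisy background,
# each carrying one darker interior ellipse (the nucleus).  The nucleus
# ellipse shares the cell's orientation and its semi-axes are a fixed
# fraction of the cell's, with the centre offset bounded so the nucleus is
# contained in the cell ellipse analytically (hence the pixelwise subset
# invariant holds by construction, before and after frame clipping).

#' Configuration for the synthetic cytology generator
#'
#' Defaults emulate the statistical structure of multi-cell Pap-stain
#' crops: a handful of overlapping cells, some cropped by the image
#' border, and nucleus pixels a small minority class (a few percent of the
#' frame, which is what motivates the positive-class weight of 8 used for
#' nucleus training).
#'
#' @param image_size integer (H, W), each >= 32.
#' @param n_cells_range inclusive integer range for the number of cells.
#' @param cyto_axis_range pixel range for cell ellipse semi-axes; default
#'   scales with the frame (12-21% of its shorter side).
#' @param nucleus_fraction_range nucleus-to-cell semi-axis ratio, in
#'   (0, 0.5].
#' @param border_crop_prob probability that a cell centre is placed within
#'   one semi-axis of the border so the cell is cropped by the frame.
#' @param overlap_allowed logical; if `FALSE`, cell centres are rejected
#'   (up to a retry budget) when closer than a semi-axis sum.
#' @param noise_sd gaussian pixel noise, 8-bit intensity units.
#' @param blur_sigma_range range of the gaussian blur applied to the image.
#' @param seed root seed; per-sample streams derive from `(seed, index)`.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(image_size = c(512L, 512L),
                             n_cells_range = c(3L, 8L),
                             cyto_axis_range = NULL,
                             nucleus_fraction_range = c(0.18, 0.32),
                             border_crop_prob = 0.3,
                             overlap_allowed = TRUE,
                             noise_sd = 4,
                             blur_sigma_range = c(0.5, 1.2),
                             seed = 1L) {
  image_size <- as.integer(image_size)
  if (length(image_size) != 2 || any(image_size < 32)) {
    stop("image_size must be two integers >= 32")
  }
  if (is.null(cyto_axis_range)) {
    cyto_axis_range <- round(c(0.12, 0.21) * min(image_size))
  }
  cfg <- list(image_size = image_size,
              n_cells_range = as.integer(n_cells_range),
              cyto_axis_range = cyto_axis_range,
              nucleus_fraction_range = nucleus_fraction_range,
              border_crop_prob = border_crop_prob,
              overlap_allowed = isTRUE(overlap_allowed),
              noise_sd = noise_sd,
              blur_sigma_range = blur_sigma_range,
              seed = as.integer(seed))
  for (f in c("n_cells_range", "cyto_axis_range", "nucleus_fraction_range",
              "blur_sigma_range")) {
    r <- cfg[[f]]
    if (length(r) != 2 || r[1] > r[2]) stop(f, " must be an ordered interval")
  }
  if (cfg$n_cells_range[1] < 0) stop("n_cells_range must be non-negative")
  if (cfg$nucleus_fraction_range[2] > 0.5 ||
      cfg$nucleus_fraction_range[1] <= 0) {
    stop("nucleus_fraction_range must lie in (0, 0.5]")
  }
  if (cfg$border_crop_prob < 0 || cfg$border_crop_prob > 1) {
    stop("border_crop_prob must be in [0, 1]")
  }
  if (cfg$noise_sd < 0 || any(cfg$blur_sigma_range < 0)) {
    stop("noise_sd and blur_sigma_range must be >= 0")
  }
  structure(cfg, class = "synthetic_config")
}

# pixel-centre membership of a rotated ellipse; xg/yg are 0-based column /
# row coordinate matrices
ellipse_mask <- function(xg, yg, cx, cy, a, b, theta) {
  dx <- xg - cx; dy <- yg - cy
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  u * u + v * v <= 1
}

# sample the geometry of one cell (plus contained nucleus)
sample_cell <- function(cfg, H, W) {
  a <- stats::runif(1, cfg$cyto_axis_range[1], cfg$cyto_axis_range[2])
  b <- a * stats::runif(1, 0.6, 1)
  theta <- stats::runif(1, 0, pi)
  r <- max(a, b)
  if (stats::runif(1) < cfg$border_crop_prob) {
    # centre within one semi-axis of the border: the cell is cropped
    edge <- sample.int(4, 1)
    off <- stats::runif(1, 0, r)
    cx <- switch(edge, off, W - 1 - off,
                 stats::runif(1, 0, W - 1), stats::runif(1, 0, W - 1))
    cy <- switch(edge, stats::runif(1, 0, H - 1), stats::runif(1, 0, H - 1),
                 off, H - 1 - off)
  } else {
    lo <- min(r, (W - 1) / 2)
    cx <- stats::runif(1, lo, W - 1 - lo)
    cy <- stats::runif(1, min(r, (H - 1) / 2), H - 1 - min(r, (H - 1) / 2))
  }
  frac <- stats::runif(1, cfg$nucleus_fraction_range[1],
                       cfg$nucleus_fraction_range[2])
  # nucleus centre offset in the cell's normalized coordinates, |d|<=1-frac
  ang <- stats::runif(1, 0, 2 * pi)
  rad <- stats::runif(1, 0, 1 - frac)
  nu <- rad * cos(ang); nv <- rad * sin(ang)
  ncx <- cx + (nu * a) * cos(theta) - (nv * b) * sin(theta)
  ncy <- cy + (nu * a) * sin(theta) + (nv * b) * cos(theta)
  list(cx = cx, cy = cy, a = a, b = b, theta = theta, frac = frac,
       ncx = ncx, ncy = ncy,
       hue = stats::runif(1), light = stats::runif(1, 0.75, 0.9))
}

hsv_to_rgb <- function(h, s, v) {
  i <- floor(h * 6) %% 6
  f <- h * 6 - floor(h * 6)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  switch(as.integer(i) + 1L,
         c(v, t, p), c(q, v, p), c(p, v, t),
         c(p, q, v), c(t, p, v), c(v, p, q))
}

#' Generate one synthetic cytology sample
#'
#' Deterministic given `(config$seed, index)`: samples in a dataset can be
#' generated independently and in any order.
#'
#' @param config a [synthetic_config()].
#' @param index sample index (non-negative integer).
#' @return an [image_sample()] with id `sprintf("synth_%05d", index)`.
#' @export
generate_sample <- function(config, index) {
  stopifnot(inherits(config, "synthetic_config"))
  H <- config$image_size[1]; W <- config$image_size[2]
  with_seed((config$seed %% 1000003L) * 2047L + as.integer(index) + 1L, {
    n_cells <- if (config$n_cells_range[1] == config$n_cells_range[2]) {
      config$n_cells_range[1]
    } else {
      sample(config$n_cells_range[1]:config$n_cells_range[2], 1)
    }
    xg <- matrix(rep(0:(W - 1), each = H), nrow = H)
    yg <- matrix(rep(0:(H - 1), W), nrow = H)

    cells <- list()
    tries <- 0
    while (length(cells) < n_cells && tries < 50 * max(1, n_cells)) {
      tries <- tries + 1
      cand <- sample_cell(config, H, W)
      if (!config$overlap_allowed && length(cells)) {
        dmin <- min(vapply(cells, function(cl) {
          sqrt((cl$cx - cand$cx)^2 + (cl$cy - cand$cy)^2) -
            (max(cl$a, cl$b) + max(cand$a, cand$b))
        }, numeric(1)))
        if (dmin < 0) next
      }
      cells[[length(cells) + 1]] <- cand
    }

    # background: near-white with a slight blue tint
    img <- array(0, c(H, W, 3))
    bg <- c(236, 240, 249) / 255
    for (ch in 1:3) img[, , ch] <- bg[ch]

    cyto <- matrix(0L, H, W)
    nuc <- matrix(0L, H, W)
    nuc_rgb_base <- c(0.35, 0.22, 0.45)  # dark purple

    for (cl in cells) {                  # back-to-front; masks take unions
      cm <- ellipse_mask(xg, yg, cl$cx, cl$cy, cl$a, cl$b, cl$theta)
      nm <- ellipse_mask(xg, yg, cl$ncx, cl$ncy,
                         cl$frac * cl$a, cl$frac * cl$b, cl$theta)
      cyto[cm] <- 1L
      nuc[nm] <- 1L
      # cytoplasm: semi-transparent cyan..pink wash
      hue <- if (cl$hue < 0.5) 0.52 + 0.06 * cl$hue else 0.87 + 0.06 * (cl$hue - 0.5)
      rgb <- hsv_to_rgb(hue %% 1, 0.35, cl$light)
      alpha <- 0.55
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[cm] <- (1 - alpha) * plane[cm] + alpha * rgb[ch]
        img[, , ch] <- plane
      }
      nrgb <- pmax(0, pmin(1, nuc_rgb_base + stats::runif(3, -0.05, 0.05)))
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[nm] <- 0.1 * plane[nm] + 0.9 * nrgb[ch]
        img[, , ch] <- plane
      }
    }

    sigma <- stats::runif(1, config$blur_sigma_range[1],
                          config$blur_sigma_range[2])
    if (sigma > 0) {
      for (ch in 1:3) img[, , ch] <- cpp_gauss_blur(img[, , ch], sigma)
    }
    if (config$noise_sd > 0) {
      img <- img + array(stats::rnorm(H * W * 3, 0, config$noise_sd / 255),
                         c(H, W, 3))
    }
    img <- round(pmin(pmax(img, 0), 1) * 255)  # first arg keeps the dims

    image_sample(sprintf("synth_%05d", as.integer(index)), img, cyto, nuc)
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_samples` triplets in the package disk format together with a
#' plain-text manifest (serialized config header, then one id per line).
#' The written masks round-trip exactly.
#'
#' @param config a [synthetic_config()].
#' @param n_samples number of samples (indices `1:n_samples`).
#' @param out_dir output directory.
#' @return character vector of sample ids, invisibly.
#' @export
generate_dataset <- function(config, n_samples, out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ids <- character(n_samples)
  for (i in seq_len(n_samples)) {
    ids[i] <- write_sample(generate_sample(config, i), out_dir)
  }
  header <- vapply(names(unclass(config)), function(k) {
    sprintf("# %s: %s", k, paste(config[[k]], collapse = " "))
  }, character(1))
  writeLines(c(header, ids), file.path(out_dir, "manifest.txt"))
  invisible(ids)
}

#' Read a dataset manifest
#'
#' @param dir dataset directory containing `manifest.txt`.
#' @return character vector of ids.
#' @export
read_manifest <- function(dir) {
  lines <- readLines(file.path(dir, "manifest.txt"))
  lines[!grepl("^#", lines) & nzchar(lines)]
}
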