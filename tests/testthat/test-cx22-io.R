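# The converter reads MATLAB v7.3 (HDF5) containers through the system
# Python (h5py + Pillow).  Fixture containers are built here with h5py so
# the convert -> load round trip is exercised end to end.

python_ok <- function() {
  py <- Sys.which("python")
  nzchar(py) && system2(py, c("-c", shQuote("import h5py, PIL")),
                        stdout = FALSE, stderr = FALSE) == 0
}

write_fixture_container <- function(path, n = 3, h = 24, w = 20,
                                    omit_nucleus = FALSE) {
  # deterministic pattern reproducible on the R side for pixel comparison
  script <- sprintf('
import h5py, numpy as np
n, h, w = %d, %d, %d
i, r, c = np.meshgrid(np.arange(n), np.arange(h), np.arange(w),
                      indexing="ij")
img = np.stack([(i*31 + r*7 + c*3 + ch) %% 256 for ch in range(3)],
               axis=-1).astype(np.uint8)
cyto = (((r + c + i) %% 3) == 0).astype(np.uint8) * 255
nuc = (((r*c + i) %% 11) == 0).astype(np.uint8) * 255
with h5py.File(r"%s", "w") as f:
    f.create_dataset("images", data=img)
    f.create_dataset("cyto_masks", data=cyto)
    if %s:
        f.create_dataset("nuc_masks", data=nuc)
', n, h, w, path, if (omit_nucleus) "False" else "True")
  f <- tempfile(fileext = ".py")
  writeLines(script, f)
  res <- system2(Sys.which("python"), f, stdout = TRUE, stderr = TRUE)
  stopifnot((attr(res, "status") %||% 0L) == 0L)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("container conversion round-trips samples pixelwise", {
  skip_if_not(python_ok(), "python with h5py/Pillow not available")
  container <- tempfile(fileext = ".mat")
  write_fixture_container(container, n = 3)
  out <- withr::local_tempdir()
  n <- convert_cx22_container(container, out)
  expect_equal(n, 3)
  expect_length(list.files(out, pattern = "\\.png$"), 9)

  samples <- load_dataset(out)
  expect_length(samples, 3)
  h <- 24; w <- 20
  rg <- matrix(0:(h - 1), h, w); cg <- matrix(0:(w - 1), h, w, byrow = TRUE)
  for (i in 0:2) {
    s <- samples[[i + 1]]
    expect_length(validate_sample(s), 0)
    for (ch in 0:2) {
      expect_equal(s$image[, , ch + 1], (i * 31 + rg * 7 + cg * 3 + ch) %% 256)
    }
    expect_equal(s$cytoplasm_mask,
                 matrix(as.integer((rg + cg + i) %% 3 == 0), h, w))
    expect_equal(s$nucleus_mask,
                 matrix(as.integer((rg * cg + i) %% 11 == 0), h, w))
  }
})

test_that("explicit key mapping overrides auto-discovery", {
  skip_if_not(python_ok(), "python with h5py/Pillow not available")
  container <- tempfile(fileext = ".mat")
  write_fixture_container(container, n = 2)
  out <- withr::local_tempdir()
  n <- convert_cx22_container(container, out,
                              keys = list(image = "images",
                                          cyto = "cyto_masks",
                                          nuc = "nuc_masks"))
  expect_equal(n, 2)
})

test_that("missing nucleus masks abort with the offending sample id", {
  skip_if_not(python_ok(), "python with h5py/Pillow not available")
  container <- tempfile(fileext = ".mat")
  write_fixture_container(container, n = 2, omit_nucleus = TRUE)
  out <- withr::local_tempdir()
  expect_error(convert_cx22_container(container, out), "sample_00001")
})

test_that("an empty container converts to zero samples", {
  skip_if_not(python_ok(), "python with h5py/Pillow not available")
  container <- tempfile(fileext = ".mat")
  f <- tempfile(fileext = ".py")
  writeLines(sprintf(
    'import h5py\nh5py.File(r"%s", "w").close()', container), f)
  system2(Sys.which("python"), f)
  out <- withr::local_tempdir()
  expect_equal(convert_cx22_container(container, out), 0)
})

test_that("load_dataset reports orphan files by id", {
  dir <- withr::local_tempdir()
  generate_dataset(tiny_synth_config(seed = 41), 2, dir)
  expect_length(load_dataset(dir), 2)
  file.remove(file.path(dir, "synth_00002_nuc.png"))
  expect_error(load_dataset(dir), "synth_00002")
  expect_length(load_dataset(withr::local_tempdir()), 0)
})

test_that("train/validation split has the stated sizes and is a partition", {
  ids <- sprintf("s%03d", 1:400)
  sp <- split_train_val(ids, 0.9, seed = 3)
  expect_length(sp$train, 360)
  expect_length(sp$val, 40)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_setequal(c(sp$train, sp$val), ids)

  sp2 <- split_train_val(ids, 0.9, seed = 3)
  expect_identical(sp, sp2)

  small <- split_train_val(letters[1:10], 0.5, seed = 1)
  expect_length(small$train, 5)
  expect_length(small$val, 5)
  expect_error(split_train_val(ids, 1.2), "ratio")

  set.seed(10)
  for (i in 1:10) {
    n <- sample(5:50, 1); ratio <- runif(1, 0.1, 0.9)
    s <- split_train_val(sprintf("x%d", 1:n), ratio, seed = i)
    expect_length(intersect(s$train, s$val), 0)
    expect_setequal(c(s$train, s$val), sprintf("x%d", 1:n))
    expect_lte(abs(length(s$train) - ratio * n), 1)
  }
})
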