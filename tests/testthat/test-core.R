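test_that("validate_sample passes conforming samples and reports violations", {
  s <- tiny_samples(1)[[1]]
  expect_length(validate_sample(s), 0)

  bad <- unclass(s)
  bad$cytoplasm_mask <- bad$cytoplasm_mask[1:32, 1:32]
  expect_match(validate_sample(bad), "shape", all = FALSE)

  bad2 <- unclass(s)
  bad2$nucleus_mask[3, 4] <- 3
  expect_match(validate_sample(bad2), "non-binary", all = FALSE)

  bad3 <- unclass(s)
  bad3$image <- bad3$image[, , 1]
  expect_match(validate_sample(bad3), "H x W x 3", all = FALSE)
})

test_that("binarize_stored_mask thresholds at >127 and is idempotent", {
  expect_equal(binarize_stored_mask(matrix(255, 4, 4)), matrix(1L, 4, 4))
  expect_equal(binarize_stored_mask(matrix(0, 4, 4)), matrix(0L, 4, 4))
  m <- matrix(c(0, 120, 128, 255), 2, 2)
  expect_equal(binarize_stored_mask(m), matrix(c(0L, 0L, 1L, 1L), 2, 2))
  # idempotent after scaling back to {0,255}
  once <- binarize_stored_mask(m)
  expect_equal(binarize_stored_mask(once * 255), once)
  expect_error(binarize_stored_mask(array(0, c(4, 4, 3))), "single-channel")
})

test_that("mask containers validate their values", {
  expect_error(binary_mask("cytoplasm", matrix(2, 2, 2)), "0 or 1")
  expect_error(probability_map("nucleus", matrix(1.2, 2, 2)), "\\[0, 1\\]")
  expect_error(probability_map("elsewhere", matrix(0.2, 2, 2)))
})

test_that("render_overlay draws contours without touching inputs", {
  s <- tiny_samples(1)[[1]]
  h <- nrow(s$cytoplasm_mask); w <- ncol(s$cytoplasm_mask)
  empty <- matrix(0L, h, w)

  out <- render_overlay(s, empty, empty)
  expect_identical(out, s$image)

  full <- matrix(1L, h, w)
  out2 <- render_overlay(s, full, empty, cyto_color = c(1, 2, 3))
  border <- matrix(FALSE, h, w)
  border[1, ] <- border[h, ] <- border[, 1] <- border[, w] <- TRUE
  expect_true(all(out2[, , 1][border] == 1))
  expect_identical(out2[, , 1][!border], s$image[, , 1][!border])

  # 10x10 square: contour equals direct boundary extraction of the square
  sq <- matrix(0L, h, w); sq[11:20, 21:30] <- 1L
  out3 <- render_overlay(s, sq, empty, cyto_color = c(7, 7, 7))
  expected <- sq == 1
  expected[12:19, 22:29] <- FALSE        # interior untouched
  for (ch in 1:3) {
    expect_true(all(out3[, , ch][expected] == 7))
    expect_identical(out3[, , ch][!expected], s$image[, , ch][!expected])
  }
  expect_error(render_overlay(s, matrix(0L, 8, 8), empty), "shape")
})

test_that("confusion counts accumulate associatively and commutatively", {
  set.seed(42)
  parts <- lapply(1:4, function(i) {
    confusion_counts(random_mask(8, 8), random_mask(8, 8))
  })
  left <- ((parts[[1]] + parts[[2]]) + parts[[3]]) + parts[[4]]
  right <- parts[[4]] + (parts[[3]] + (parts[[2]] + parts[[1]]))
  expect_equal(unclass(left), unclass(right))
})

test_that("samples round-trip losslessly through the disk format", {
  s <- tiny_samples(2)[[2]]
  dir <- withr::local_tempdir()
  write_sample(s, dir)
  back <- read_sample(dir, s$id)
  expect_identical(back$cytoplasm_mask, s$cytoplasm_mask)
  expect_identical(back$nucleus_mask, s$nucleus_mask)
  expect_equal(back$image, s$image)
})
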