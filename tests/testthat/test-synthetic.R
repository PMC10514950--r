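test_that("generation is deterministic and honours the cell-count range", {
  cfg <- tiny_synth_config()
  a <- generate_sample(cfg, 3)
  b <- generate_sample(cfg, 3)
  expect_identical(a, b)

  cfg0 <- synthetic_config(image_size = c(64, 64), n_cells_range = c(0, 0),
                           seed = 5)
  empty <- generate_sample(cfg0, 1)
  expect_true(all(empty$cytoplasm_mask == 0))
  expect_true(all(empty$nucleus_mask == 0))
  expect_true(mean(empty$image) > 180)   # light background
})

test_that("nucleus mask is contained in the cytoplasm mask", {
  for (s in tiny_samples(20)) {
    expect_true(all(s$nucleus_mask <= s$cytoplasm_mask))
  }
})

test_that("nucleus area matches the analytic ellipse-fraction bound", {
  cfg <- synthetic_config(image_size = c(512, 512), n_cells_range = c(5, 5),
                          nucleus_fraction_range = c(0.2, 0.3),
                          border_crop_prob = 0, seed = 9)
  s <- generate_sample(cfg, 1)
  nf <- mean(s$nucleus_mask)
  cf <- mean(s$cytoplasm_mask)
  expect_lt(nf, cf)
  expect_lt(nf, 0.05)
  # rasterized ratio must sit near the analytic frac^2 area ratio:
  # nucleus/cell area ratio is frac^2 with frac in [0.2, 0.3], so the
  # pooled nucleus fraction is at most 0.09 of the cytoplasm fraction
  # plus discretization (cells may overlap, which only lowers cf)
  expect_lt(nf / cf, 0.12)
  expect_gt(nf / cf, 0.03)
})

test_that("border cropping produces cells cut by the frame", {
  cfg <- synthetic_config(image_size = c(64, 64), border_crop_prob = 0.8,
                          seed = 21)
  touched <- vapply(1:12, function(i) {
    m <- generate_sample(cfg, i)$cytoplasm_mask
    sum(m[1, ], m[64, ], m[, 1], m[, 64]) > 0
  }, logical(1))
  expect_true(any(touched))
})

test_that("nucleus pixels are a small minority class under defaults", {
  fracs <- vapply(tiny_samples(50), function(s) mean(s$nucleus_mask),
                  numeric(1))
  expect_lt(mean(fracs), 0.05)
})

test_that("generate_dataset writes a lossless, manifest-listed dataset", {
  cfg <- tiny_synth_config(seed = 31)
  dir <- withr::local_tempdir()
  ids <- generate_dataset(cfg, 3, dir)
  expect_length(ids, 3)
  expect_length(list.files(dir, pattern = "\\.png$"), 9)
  expect_identical(read_manifest(dir), ids)

  loaded <- load_dataset(dir)
  for (i in seq_along(ids)) {
    orig <- generate_sample(cfg, i)
    expect_identical(loaded[[i]]$cytoplasm_mask, orig$cytoplasm_mask)
    expect_identical(loaded[[i]]$nucleus_mask, orig$nucleus_mask)
  }

  dir0 <- withr::local_tempdir()
  expect_length(generate_dataset(cfg, 0, dir0), 0)
  expect_length(list.files(dir0, pattern = "\\.png$"), 0)
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(image_size = c(16, 64)), ">= 32")
  expect_error(synthetic_config(nucleus_fraction_range = c(0.2, 0.6)),
               "0, 0.5")
  expect_error(synthetic_config(n_cells_range = c(5, 2)), "ordered")
  expect_error(synthetic_config(noise_sd = -1))
})
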