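test_that("spec pairing rules follow the candidate table", {
  expect_error(model_spec("deeplabv3", "densenet121"), "pair")
  expect_error(model_spec("unet", "resnet50"), "pair")
  expect_s3_class(model_spec("unet", "resnet34"), "cytoseg_spec")
  expect_s3_class(model_spec("deeplabv3plus", "resnet50"), "cytoseg_spec")
})

test_that("the zoo enumerates eight distinct buildable combinations", {
  specs <- list_supported()
  expect_length(specs, 8)
  keys <- vapply(specs, function(s) paste(s$architecture, s$encoder),
                 character(1))
  expect_length(unique(keys), 8)
  for (s in specs) {
    m <- build_model(s)
    expect_s3_class(m, "cytoseg_model")
    expect_gt(count_parameters(m), 1e5)
  }
})

test_that("full-width parameter counts reproduce the published table", {
  want <- c(unet_resnet34 = 24436369,
            unet_densenet121 = 13607633,
            unetplusplus_resnet34 = 26078609,
            unetplusplus_densenet121 = 30072273,
            deeplabv3_resnet34 = 26007105,
            deeplabv3_resnet50 = 39633729,
            deeplabv3plus_resnet34 = 22437457,
            deeplabv3plus_resnet50 = 26677585)
  for (s in list_supported()) {
    key <- paste0(s$architecture, "_", s$encoder)
    expect_equal(count_parameters(build_model(s)), unname(want[key]),
                 label = key)
  }
})

test_that("tiny variants are strictly smaller than full width", {
  full <- count_parameters(build_model(model_spec("unet", "resnet34")))
  tiny <- count_parameters(build_model(model_spec("unet", "resnet34",
                                                  tiny = TRUE)))
  expect_lt(tiny, full / 4)
})

test_that("forward pass preserves spatial size and emits probabilities", {
  spec <- model_spec("unet", "resnet34", tiny = TRUE)
  model <- cytoseg:::materialize_weights(build_model(spec), seed = 1)
  for (hw in list(c(64, 64), c(32, 96))) {
    img <- array(sample(0:255, prod(hw) * 3, replace = TRUE),
                 c(hw[1], hw[2], 3))
    maps <- predict(model, img, task = "cytoplasm")
    expect_length(maps, 1)
    expect_equal(dim(maps[[1]]$probs), hw)
    expect_true(all(maps[[1]]$probs >= 0 & maps[[1]]$probs <= 1))
  }
  expect_error(predict(model, array(0, c(50, 50, 3))), "divisible by 32")
})

test_that("deeplab heads also honour the forward contract", {
  spec <- model_spec("deeplabv3plus", "resnet50", tiny = TRUE)
  model <- cytoseg:::materialize_weights(build_model(spec), seed = 2)
  img <- array(runif(64 * 64 * 3) * 255, c(64, 64, 3))
  maps <- predict(model, img, task = "nucleus")
  expect_equal(dim(maps[[1]]$probs), c(64, 64))
  expect_true(all(maps[[1]]$probs >= 0 & maps[[1]]$probs <= 1))
})

test_that("imagenet initialization demands a local weights file", {
  spec <- model_spec("unet", "resnet34", init = "imagenet", tiny = TRUE)
  m <- build_model(spec)
  expect_error(cytoseg:::materialize_weights(m), "weights")
})
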