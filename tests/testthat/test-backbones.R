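test_that("relu6 clips at 0 and 6 and is identity between", {
  expect_equal(relu6(-3), 0)
  expect_equal(relu6(3), 3)
  expect_equal(relu6(100), 6)
  x <- seq(-10, 10, by = 0.5)
  expect_equal(relu6(x), pmin(pmax(x, 0), 6))
  expect_equal(dim(relu6(matrix(7, 2, 3))), c(2, 3))
})

test_that("every encoder exposes exactly five finite tap features offline", {
  set.seed(1)
  x <- array(rnorm(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  for (nm in c("vgg19", "resnet50", "mobilenetv2")) {
    enc <- build_encoder(nm, width = 1 / 8)
    taps <- encoder_features(enc, x)
    expect_length(taps, 5)
    for (tp in taps) expect_true(all(is.finite(tp)))
    # resolution halves tap to tap
    res <- vapply(taps, function(tp) dim(tp)[1], numeric(1))
    expect_equal(res, 64 / 2^(seq_len(5) - 1) / (enc$tap_strides[1]),
                 ignore_attr = TRUE)
    expect_equal(dim(taps[[1]])[4], 2)
  }
  expect_error(build_encoder("alexnet"), "unknown encoder")
})

test_that("vgg19 taps sit at native resolutions 224..14", {
  enc <- build_encoder("vgg19", width = 1 / 16)
  x <- array(0, c(224, 224, 3, 1))
  taps <- encoder_features(enc, x)
  expect_equal(vapply(taps, function(tp) dim(tp)[1], numeric(1)),
               c(224, 112, 56, 28, 14))
  expect_equal(enc$tap_strides, c(1L, 2L, 4L, 8L, 16L))
})

test_that("pretrained initialization requires an explicit weights file", {
  expect_error(build_encoder("vgg19", width = 1 / 8, pretrained = TRUE),
               "weights_file")
})

test_that("lateral projection yields the canonical uniform pyramid", {
  set.seed(2)
  net <- triunet:::new_net()
  enc <- build_encoder("resnet50", width = 1 / 8, net = net, group = "e")
  proj <- triunet:::build_projector(net, "n", enc$tap_channels, 8L, 64L)
  x <- triunet:::nd_const(array(rnorm(64 * 64 * 3), c(64, 64, 3, 1)))
  net$training <- FALSE
  pyr <- proj(enc$forward(x))
  sizes <- vapply(pyr, function(p) dim(p$value)[1], numeric(1))
  chans <- vapply(pyr, function(p) dim(p$value)[3], numeric(1))
  expect_equal(sizes, c(64, 32, 16, 8, 4))
  expect_equal(chans, rep(8, 5))
  # level already at the canonical resolution is left spatially untouched
  v <- triunet:::nd_const(array(1, c(16, 16, 2, 1)))
  expect_identical(triunet:::nd_resize_bilinear(v, 16L, 16L), v)
})

test_that("frozen encoders keep their weights while the decoder learns", {
  m <- build_model("single", profile = "tiny", trainable_encoders = FALSE,
                   seed = 3)
  pair <- phantom_pairs()[[1]]
  before <- lapply(m$net$params, function(p) p$value)
  tc <- train_config(alpha0 = 1e-3, Ne = 10L, epochs = 1L, batch_size = 1L,
                     seed = 1)
  train_model(m, list(train = list(pair)), tc, restore_best = FALSE)
  groups <- vapply(m$net$params, function(p) p$group, character(1))
  enc_same <- vapply(names(groups)[grepl("^encoder", groups)], function(nm)
    identical(before[[nm]], m$net$params[[nm]]$value), logical(1))
  dec_same <- vapply(names(groups)[groups == "decoder"], function(nm)
    identical(before[[nm]], m$net$params[[nm]]$value), logical(1))
  expect_true(all(enc_same))
  expect_false(all(dec_same))
})

test_that("depthwise separable fusion preserves shape at lower cost", {
  set.seed(4)
  x <- array(rnorm(28 * 28 * 32), c(28, 28, 32))
  r <- depthwise_fuse(x)
  expect_equal(dim(r$y), c(28, 28, 32, 1))
  expect_true(all(is.finite(r$y)))
  pc <- separable_param_count(32)
  expect_equal(pc$depthwise_separable, 32 * 9 + 32 * 32)
  expect_lt(pc$depthwise_separable, pc$dense)
  for (C in 2:8)
    expect_lt(separable_param_count(C)$depthwise_separable,
              separable_param_count(C)$dense)
})
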