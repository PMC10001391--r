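test_that("attention coefficients live in [0,1]; zero psi gives alpha = 1/2", {
  set.seed(1)
  xl <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  g <- array(rnorm(4 * 4 * 4), c(4, 4, 4))
  r <- attention_gate(xl, g, inter_ch = 6L)
  expect_true(all(r$alpha >= 0 & r$alpha <= 1))
  expect_equal(dim(r$out), dim(xl))
  expect_equal(dim(r$alpha), dim(xl)[1:2])
  # output/skip ratio equals alpha wherever the skip feature is non-zero
  a_full <- array(r$alpha, dim(xl))
  nz <- abs(xl) > 1e-8
  expect_equal((r$out / xl)[nz], a_full[nz], tolerance = 1e-10)
  # degenerate gate: psi weights and bias zero -> sigmoid(0) = 0.5
  r$layers$psi$w$value[] <- 0
  r$layers$psi$b$value[] <- 0
  r0 <- attention_gate(xl, g, gate = r$layers)
  expect_equal(as.vector(r0$alpha), rep(0.5, length(r0$alpha)))
  expect_equal(r0$out, xl / 2, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("cross-encoder fusion with averaging weights reproduces identical inputs", {
  set.seed(2)
  m <- build_model("multi", profile = "tiny", seed = 2)
  # averaging 1x1 kernel: each output channel takes mean of that channel
  # across the three stacked encoder copies
  pc <- m$profile$pyramid_channels
  for (l in 1:5) {
    ly <- m$net$layers[[sprintf("fuse.l%d", l)]]
    w <- array(0, dim(ly$w$value))
    for (c in seq_len(pc)) for (e in 0:2) w[1, 1, e * pc + c, c] <- 1 / 3
    ly$w$value <- w
    ly$b$value[] <- 0
  }
  lvl <- triunet:::nd_const(array(rnorm(8 * 8 * pc), c(8, 8, pc, 1)))
  merged <- triunet:::nd_concat(list(lvl, lvl, lvl))
  fused <- m$net$layers[["fuse.l1"]]$fwd(merged)
  expect_equal(fused$value, lvl$value, tolerance = 1e-12)
})

test_that("output head emits a 4-class per-pixel distribution", {
  m <- build_model("full", profile = "tiny", seed = 3)
  pair <- phantom_pairs()[[1]]
  p <- model_forward(m, pair$x)
  expect_equal(dim(p), c(64, 64, 4))
  sums <- apply(p, c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-5)
  lab <- predict_labels(m, pair$x)
  expect_true(all(lab %in% 0:3))
  expect_equal(dim(lab), c(64, 64))
})

test_that("upatt decoder doubles resolution per stage and rejects misaligned skips", {
  net <- triunet:::new_net()
  up <- triunet:::build_upatt(net, "u", 4L, 4L, 8L, 4L, TRUE, "d")
  net$training <- TRUE
  prev <- triunet:::nd_const(array(rnorm(4 * 4 * 4), c(4, 4, 4, 1)))
  skip <- triunet:::nd_const(array(rnorm(8 * 8 * 4), c(8, 8, 4, 1)))
  out <- up(prev, skip)
  expect_equal(dim(out$value), c(8, 8, 8, 1))
  bad <- triunet:::nd_const(array(0, c(16, 16, 4, 1)))
  expect_error(up(prev, bad), "not twice")
})

test_that("every ablation variant builds and maps input to valid probabilities", {
  pair <- phantom_pairs()[[2]]
  for (v in c("single", "multi", "multi_att", "multi_bifpn", "full")) {
    m <- build_model(v, profile = "tiny", seed = 4)
    expect_s3_class(m, "triunet_model")
    p <- model_forward(m, pair$x)
    expect_equal(dim(p), c(64, 64, 4))
    expect_true(all(is.finite(p)))
  }
  expect_error(build_model("resnet_only"), "unknown model variant")
  # the published method is the default variant
  expect_equal(build_model(profile = model_profile("tiny"))$variant, "full")
})

test_that("strongly negative psi bias suppresses the gated skip yet keeps valid outputs", {
  m <- build_model("full", profile = "tiny", seed = 5)
  for (nm in names(m$net$params))
    if (grepl("\\.ag\\.psi\\.b$", nm)) m$net$params[[nm]]$value[] <- -30
  pair <- phantom_pairs()[[1]]
  parts <- m$forward(pair$x, return_parts = TRUE)
  p <- parts$probs$value
  expect_true(all(is.finite(p)))
  expect_lt(max(abs(apply(p[, , , 1], c(1, 2), sum) - 1)), 1e-5)
  # with alpha ~ 0 the attention gates pass almost nothing through
  net <- triunet:::new_net()
  ag <- triunet:::build_attention_gate(net, "a", 4L, 4L, 4L, "g")
  ag$psi$b$value[] <- -30
  xl <- triunet:::nd_const(array(rnorm(8 * 8 * 4), c(8, 8, 4, 1)))
  gg <- triunet:::nd_const(array(rnorm(8 * 8 * 4), c(8, 8, 4, 1)))
  r <- ag$fwd(xl, gg)
  expect_lt(max(r$alpha$value), 1e-6)
  expect_lt(max(abs(r$out$value)), 1e-4)
})

test_that("attention parameters receive gradients from the dice loss", {
  m <- build_model("full", profile = "tiny", seed = 6)
  pair <- phantom_pairs()[[1]]
  b <- triunet:::stack_batch(list(pair))
  probs <- m$forward(b$x, training = TRUE)
  loss <- triunet:::nd_dice_loss(probs, b$g)
  triunet:::nd_zero_grads(m$net$params)
  triunet:::nd_backward(loss)
  att <- grep("\\.ag\\.(wx|wg|psi)\\.w$", names(m$net$params), value = TRUE)
  expect_gt(length(att), 0)
  for (nm in att) {
    expect_false(is.null(m$net$params[[nm]]$grad))
    expect_gt(max(abs(m$net$params[[nm]]$grad)), 0)
  }
})
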