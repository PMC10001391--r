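test_that("dice coefficient matches hand evaluation and its identities", {
  # P = (0.5, 0.5) against G = (1, 0): 2*0.5 / (0.25+0.25+1) = 0.6667
  P <- array(c(0.5, 0.5), c(2, 1, 1, 1))
  G <- array(c(1, 0), c(2, 1, 1, 1))
  expect_equal(dice_coefficient(P, G), 2 * 0.5 / (0.5 + 1),
               tolerance = 1e-4)
  # perfect overlap and disjoint binary masks
  A <- array(c(1, 0, 1, 0), c(2, 2, 1, 1))
  expect_equal(dice_coefficient(A, A), 1, tolerance = 1e-6)
  B <- array(c(0, 1, 0, 1), c(2, 2, 1, 1))
  expect_equal(dice_coefficient(A, B), 0, tolerance = 1e-5)
  expect_equal(dice_loss(A, A), 0, tolerance = 1e-6)
  # symmetric for binary inputs, bounded in [0, 1]
  set.seed(1)
  for (i in 1:5) {
    X <- array(rbinom(36, 1, 0.4), c(6, 6, 1, 1))
    Y <- array(rbinom(36, 1, 0.4), c(6, 6, 1, 1))
    expect_equal(dice_coefficient(X, Y), dice_coefficient(Y, X))
    expect_gte(dice_coefficient(X, Y), 0)
    expect_lte(dice_coefficient(X, Y), 1 + 1e-12)
  }
  expect_error(dice_coefficient(array(0, c(2, 2)), array(0, c(3, 3))),
               "mismatch")
})

test_that("dice loss node gradient agrees with finite differences", {
  set.seed(2)
  P <- array(runif(4 * 4 * 4), c(4, 4, 4, 1))
  G <- one_hot(matrix(sample(0:3, 16, TRUE), 4, 4))
  node <- triunet:::nd_node(P)
  loss <- triunet:::nd_dice_loss(node, G)
  expect_equal(loss$value[1], dice_loss(P, G), tolerance = 1e-12)
  triunet:::nd_backward(loss)
  dv <- array(rnorm(length(P)), dim(P))
  eps <- 1e-6
  num <- (dice_loss(P + eps * dv, G) - dice_loss(P - eps * dv, G)) / (2 * eps)
  expect_equal(sum(node$grad * dv), num, tolerance = 1e-5)
})

test_that("learning-rate schedule matches its endpoints and midpoint", {
  expect_equal(lr_schedule(0), 1e-4)
  expect_equal(lr_schedule(350), 0)
  expect_equal(lr_schedule(175), 1e-4 * 0.5^0.9, tolerance = 1e-12)
  expect_equal(lr_schedule(175), 5.3589e-5, tolerance = 1e-4)
  # strictly decreasing on [0, Ne]
  e <- 0:350
  expect_true(all(diff(lr_schedule(e)) < 0))
  expect_error(lr_schedule(351), "\\[0, Ne\\]")
  expect_error(lr_schedule(-1), "\\[0, Ne\\]")
})

test_that("dataset split is exact, disjoint and seed-deterministic", {
  ids <- sprintf("case%03d", 1:369)
  sp <- split_dataset(ids, c(0.8, 0.1, 0.1), seed = 1)
  expect_length(sp$train, 295)
  expect_length(sp$val, 37)
  expect_length(sp$test, 37)
  expect_setequal(c(sp$train, sp$val, sp$test), ids)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_length(intersect(sp$val, sp$test), 0)
  expect_identical(sp, split_dataset(ids, c(0.8, 0.1, 0.1), seed = 1))
  expect_false(identical(sp, split_dataset(ids, seed = 2)))
  expect_error(split_dataset(character(0)), "empty")
  expect_error(split_dataset(ids, c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("training logs epochs, honors the schedule and checkpoints the best dice", {
  pairs <- phantom_pairs()
  m <- build_model("single", profile = "tiny", seed = 7)
  tc <- train_config(alpha0 = 5e-3, Ne = 20L, epochs = 3L, batch_size = 2L,
                     seed = 3)
  h <- train_model(m, list(train = pairs[1:3], val = pairs[4]), tc)
  expect_s3_class(h, "train_history")
  expect_equal(nrow(h), 3)
  expect_lte(nrow(h), tc$Ne)
  expect_equal(h$lr, lr_schedule(0:2, 20L, 5e-3))
  expect_true(all(is.finite(h$train_loss)))
  best <- attr(h, "best_epoch")
  expect_gte(h$val_dice[best], max(h$val_dice))
  expect_error(train_model(m, list(train = list()), tc), "empty")
})

test_that("an optimizer step with zero learning rate changes nothing", {
  m <- build_model("single", profile = "tiny", seed = 8)
  pair <- phantom_pairs()[[1]]
  b <- triunet:::stack_batch(list(pair))
  before <- lapply(m$net$params, function(p) p$value)
  opt <- triunet:::adam_new(lr = 0)
  probs <- m$forward(b$x, training = TRUE)
  loss <- triunet:::nd_dice_loss(probs, b$g)
  triunet:::nd_zero_grads(m$net$params)
  triunet:::nd_backward(loss)
  triunet:::adam_step(opt, m$net$params)
  after <- lapply(m$net$params, function(p) p$value)
  expect_identical(before, after)
})
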