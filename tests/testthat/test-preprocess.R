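test_that("slice extraction returns the requested axial plane", {
  # volume whose plane k (0-based) holds the constant value k
  vox <- array(rep(0:9, each = 12 * 10), c(12, 10, 10))
  vol <- modality_volume(vox, "t1")
  expect_equal(unique(as.vector(extract_slice(vol, 4))), 4)
  # default for non-155 depth is the middle plane floor(D/2)
  expect_equal(unique(as.vector(extract_slice(vol))), 5)
  expect_equal(attr(extract_slice(vol, 0), "modality"), "t1")
  expect_error(extract_slice(vol, 10), "depth 10")
  expect_error(extract_slice(vol, -1), "out of range")
})

test_that("default slice index is 90 for 155-slice volumes, else middle", {
  expect_identical(default_slice_index(155L), 90L)
  expect_identical(default_slice_index(31L), 15L)
  expect_identical(default_slice_index(1L), 0L)
  vox <- array(0, c(4, 4, 1))
  expect_equal(dim(extract_slice(modality_volume(vox, "t2"))), c(4, 4))
})

test_that("center crop takes the middle window, trailing side absorbs odd margins", {
  ramp <- outer(1:240, 1:240, function(i, j) i * 1000 + j)
  out <- crop_center(ramp, 224)
  expect_equal(dim(out), c(224, 224))
  expect_equal(out, ramp[9:232, 9:232], ignore_attr = TRUE)
  # identity crop
  expect_equal(crop_center(out, 224), out)
  # odd difference: 7 -> 4, leading margin 1, trailing margin 2
  m <- matrix(1:49, 7, 7)
  expect_equal(crop_center(m, 4), m[2:5, 2:5], ignore_attr = TRUE)
  expect_error(crop_center(m, 8), "exceeds")
})

test_that("z-score uses the population standard deviation", {
  z <- zscore_normalize(c(1, 2, 3))
  expect_equal(z, c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  img <- matrix(rexp(400, 0.1), 20, 20)
  zi <- zscore_normalize(img)
  expect_lt(abs(mean(zi)), 1e-10)
  expect_lt(abs(sqrt(mean((zi - mean(zi))^2)) - 1), 1e-10)
  # idempotent up to floating tolerance
  expect_equal(zscore_normalize(zi), zi, tolerance = 1e-5)
  expect_error(zscore_normalize(matrix(3, 5, 5)), "constant")
})

test_that("gaussian denoising preserves constants and unit mass", {
  img <- matrix(7, 16, 16)
  expect_equal(gaussian_denoise(img, 2), img, tolerance = 1e-12)
  x <- matrix(rnorm(256), 16, 16)
  expect_identical(gaussian_denoise(x, 0), x)
  expect_error(gaussian_denoise(x, -1), "non-negative")
  # interior unit impulse: response is the normalized truncated kernel
  imp <- matrix(0, 15, 15); imp[8, 8] <- 1
  out <- gaussian_denoise(imp, 1)
  expect_equal(sum(out), 1, tolerance = 1e-12)
  r <- 3L
  k2 <- exp(-outer((-r:r)^2, (-r:r)^2, "+") / 2)
  k2 <- k2 / sum(k2)
  expect_equal(out[8, 8], k2[r + 1, r + 1], tolerance = 1e-12)
  expect_equal(out[(8 - r):(8 + r), (8 - r):(8 + r)], k2,
               tolerance = 1e-12)
})

test_that("modality stacking enforces order and tags", {
  a <- matrix(1, 4, 4); b <- matrix(2, 4, 4); d <- matrix(3, 4, 4)
  x <- assemble_input(a, b, d)
  expect_equal(dim(x), c(4, 4, 3))
  expect_equal(attr(x, "channel_order"), c("t1", "t1ce", "t2"))
  expect_equal(x[1, 1, ], c(1, 2, 3))
  # a flair-tagged slice cannot stand in for a required modality
  fl <- matrix(0, 4, 4); attr(fl, "modality") <- "flair"
  expect_error(assemble_input(a, b, fl), "flair")
  expect_error(assemble_input(a, b, matrix(0, 5, 4)), "shape")
})

test_that("full preprocessing of a BraTS-shaped case yields 224x224 pairs", {
  cfg <- phantom_config(shape = c(240L, 240L, 155L), seed = 3L)
  ph <- generate_phantom(cfg)
  case <- c(ph$volumes, list(seg = ph$labels))
  pair <- preprocess_case(case)
  expect_equal(dim(pair$x), c(224, 224, 3))
  expect_equal(dim(pair$y), c(224, 224))
  expect_true(all(pair$y %in% 0:3))
  expect_true(any(pair$y == 3))  # file code 4 remapped to class 3
  for (c in 1:3) {
    ch <- pair$x[, , c]
    expect_lt(abs(mean(ch)), 1e-6)
    expect_lt(abs(sqrt(mean((ch - mean(ch))^2)) - 1), 1e-4)
  }
})

test_that("label remapping is a 4 <-> 3 bijection and rejects junk", {
  lab <- matrix(c(0, 1, 2, 4), 2, 2)
  internal <- remap_labels_from_file(lab)
  expect_equal(sort(unique(as.vector(internal))), 0:3)
  expect_equal(remap_labels_to_file(internal), lab)
  expect_error(remap_labels_from_file(matrix(5, 2, 2)), "unexpected")
  expect_error(remap_labels_to_file(matrix(4L, 2, 2)), "unexpected")
})

test_that("augmentation is deterministic, label-preserving and involutive", {
  pair <- phantom_pairs()[[1]]
  aug1 <- augment_pair(pair$x, pair$y, seed = 5)
  aug2 <- augment_pair(pair$x, pair$y, seed = 5)
  expect_identical(aug1, aug2)
  expect_gte(length(aug1), 8)
  for (p in aug1) {
    expect_equal(dim(p$x)[1:2], dim(p$y))
    expect_equal(dim(p$x)[3], 3)
  }
  # flips/rotations permute pixels: label histogram is unchanged
  for (i in 2:6)
    expect_equal(table(aug1[[i]]$y), table(pair$y))
  # horizontal flip applied twice recovers the original
  hf <- aug1[[2]]
  expect_equal(hf$x[, rev(seq_len(ncol(hf$y))), ], unclass(pair$x),
               ignore_attr = TRUE)
  # geometric transforms commute with region extraction
  flip <- function(m) m[, rev(seq_len(ncol(m)))]
  rm_flip <- region_masks(flip(pair$y))
  flip_rm <- lapply(region_masks(pair$y), flip)
  for (r in names(rm_flip))
    expect_equal(rm_flip[[r]], flip_rm[[r]], ignore_attr = TRUE)
})
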