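test_that("region masks implement the WT/TC/EnT unions and nest properly", {
  lab <- matrix(0L, 4, 4)
  lab[1, 1] <- 1L; lab[2, 2] <- 2L; lab[3, 3] <- 3L
  rm <- region_masks(lab)
  expect_equal(sum(rm$WT), 3)
  expect_equal(sum(rm$TC), 2)
  expect_equal(sum(rm$EnT), 1)
  expect_true(all(rm$WT[rm$TC]))
  expect_true(all(rm$TC[rm$EnT]))
  empty <- region_masks(matrix(0L, 4, 4))
  for (r in names(empty)) expect_equal(sum(empty[[r]]), 0)
  expect_error(region_masks(matrix(4L, 2, 2)), "unexpected")
})

test_that("dsc and iou match hand counts and their algebraic identity", {
  G <- matrix(FALSE, 4, 4); S <- matrix(FALSE, 4, 4)
  G[1, 1:4] <- TRUE          # |G| = 4
  S[1, 3:4] <- TRUE; S[2, 1:2] <- TRUE  # |S| = 4, overlap 2
  expect_equal(dsc(G, S), 0.5)
  expect_equal(iou(G, S), 2 / 6)
  expect_equal(dsc(G, G), 1)
  expect_equal(iou(G, G), 1)
  D <- matrix(FALSE, 4, 4); D[4, 4] <- TRUE
  expect_equal(dsc(G, D), 0)
  E <- matrix(FALSE, 4, 4)
  expect_equal(dsc(E, E), 1)
  expect_equal(iou(E, E), 1)
  expect_error(dsc(G, matrix(FALSE, 3, 3)), "differ")
  # identity iou = dsc/(2-dsc), symmetry, ordering dsc >= iou
  for (i in 1:20) {
    A <- random_mask(9, i); B <- random_mask(9, i + 100)
    d <- dsc(A, B); j <- iou(A, B)
    expect_equal(j, d / (2 - d), tolerance = 1e-9)
    expect_equal(d, dsc(B, A))
    expect_equal(j, iou(B, A))
    expect_gte(d, j)
  }
})

test_that("dsc increases weakly as the prediction shrinks toward the truth", {
  G <- matrix(FALSE, 16, 16); G[5:9, 5:9] <- TRUE
  vals <- vapply(0:4, function(grow) {
    S <- matrix(FALSE, 16, 16)
    S[(5 - grow):(9 + grow), (5 - grow):(9 + grow)] <- TRUE
    dsc(G, S)
  }, numeric(1))
  expect_true(all(diff(vals) <= 0))  # growing away from G only hurts
})

test_that("hausdorff95 handles identity, offsets, spacing and empty masks", {
  M <- matrix(FALSE, 10, 10); M[3:6, 3:6] <- TRUE
  expect_equal(hausdorff95(M, M), 0)
  E <- matrix(FALSE, 10, 10)
  expect_equal(hausdorff95(E, E), 0)
  expect_true(is.na(hausdorff95(M, E)))
  expect_true(is.na(hausdorff95(E, M)))
  # single pixels at offset (3,4): the lone distance is 5
  A <- matrix(FALSE, 10, 10); A[2, 2] <- TRUE
  B <- matrix(FALSE, 10, 10); B[5, 6] <- TRUE
  expect_equal(hausdorff95(A, B), 5)
  expect_equal(hausdorff95(A, B, spacing = c(2, 2)), 10)
  expect_equal(hausdorff95(B, A), hausdorff95(A, B))
})

test_that("hausdorff95 equals the exhaustive boundary oracle on small masks", {
  set.seed(9)
  for (i in 1:30) {
    n <- sample(4:16, 1)
    Tm <- matrix(runif(n * n) < 0.3, n, n)
    Pm <- matrix(runif(n * n) < 0.3, n, n)
    got <- hausdorff95(Tm, Pm)
    want <- hd95_oracle(Tm, Pm)
    if (is.na(want)) expect_true(is.na(got)) else
      expect_equal(got, want, tolerance = 1e-12)
    # symmetry of the implementation
    expect_equal(hausdorff95(Pm, Tm), got, tolerance = 1e-12)
  }
})

test_that("pixel metrics reproduce confusion-table arithmetic", {
  # 10x10 field, |G| = 20, |S| = 25, TP = 15
  G <- matrix(FALSE, 10, 10); G[1:2, ] <- TRUE
  S <- matrix(FALSE, 10, 10); S[1, ] <- TRUE; S[2, 1:5] <- TRUE
  S[3:4, 1:5] <- TRUE
  expect_equal(sum(G), 20); expect_equal(sum(S), 25)
  expect_equal(sum(G & S), 15)
  pm <- pixel_metrics(G, S)
  expect_equal(pm$precision, 0.6)
  expect_equal(pm$recall, 0.75)
  expect_equal(pm$f1, 2 * 0.45 / 1.35, tolerance = 1e-12)
  expect_equal(pm$accuracy, 0.85)
  expect_false(pm$degenerate)
  # harmonic-mean identity
  expect_equal(pm$f1, 2 * pm$precision * pm$recall /
                 (pm$precision + pm$recall))
  perfect <- pixel_metrics(G, G)
  expect_equal(unlist(perfect[1:4]), c(accuracy = 1, precision = 1,
                                       recall = 1, f1 = 1))
  degen <- pixel_metrics(matrix(FALSE, 3, 3), matrix(FALSE, 3, 3))
  expect_true(degen$degenerate)
  expect_equal(degen$precision, 0)
})

test_that("feeding ground truth back as prediction gives perfect scores", {
  pairs <- phantom_pairs()
  gt <- lapply(pairs, `[[`, "y")
  report <- evaluate_predictions(gt, gt)
  expect_equal(report$region, c("WT", "TC", "EnT"))
  expect_equal(report$dsc, rep(1, 3))
  expect_equal(report$iou, rep(1, 3))
  expect_equal(report$hd95, rep(0, 3))
  expect_equal(report$accuracy, rep(1, 3))
  expect_equal(ncol(report), 8)
})

test_that("metrics from a real model lie in range and satisfy the identity per case", {
  pairs <- phantom_pairs()
  m <- build_model("single", profile = "tiny", seed = 10)
  report <- evaluate_split(m, pairs)
  frac <- unlist(report[c("dsc", "iou", "precision", "recall", "f1",
                          "accuracy")])
  expect_true(all(frac >= 0 & frac <= 1))
  expect_true(all(report$hd95 >= 0 | is.na(report$hd95)))
  for (p in pairs) {
    gm <- region_masks(p$y)
    sm <- region_masks(predict_labels(m, p$x))
    for (r in c("WT", "TC", "EnT")) {
      d <- dsc(gm[[r]], sm[[r]])
      expect_equal(iou(gm[[r]], sm[[r]]), d / (2 - d), tolerance = 1e-9)
    }
  }
})
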