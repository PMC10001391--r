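# Shared fixtures, generated programmatically and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

# four desk-scale phantom cases preprocessed to 64x64 training pairs
phantom_pairs <- function() {
  if (is.null(.fixture_cache$pairs)) {
    dirs <- synthesize_cases(file.path(tempdir(), "triunet-fixtures"),
                             n_cases = 4L, shape = c(64L, 64L, 32L),
                             seed = 7L)
    .fixture_cache$pairs <- lapply(dirs, function(d)
      preprocess_case(read_case(d), sigma = 0.5, target = 64L))
  }
  .fixture_cache$pairs
}

# a random binary mask with a blob-like structure
random_mask <- function(n, p_seed) {
  set.seed(p_seed)
  m <- matrix(runif(n * n) < 0.25, n, n)
  m
}

# straight-line evaluation of the eight bidirectional-pyramid assignments,
# independent of the package dataflow (used as the analytic oracle)
bifpn_oracle <- function(L, conv, up, down) {
  L4mid <- conv(L[[4]] + up(L[[5]]))
  L3mid <- conv(L[[3]] + up(L4mid))
  L2mid <- conv(L[[2]] + up(L3mid))
  L1out <- conv(L[[1]] + up(L2mid))
  L2out <- conv(L[[2]] + L2mid + down(L1out))
  L3out <- conv(L[[3]] + L3mid + down(L2out))
  L4out <- conv(L[[4]] + L4mid + down(L3out))
  L5out <- conv(L[[5]] + down(L4out))
  list(L1out, L2out, L3out, L4out, L5out)
}

# stub resizes for array-level pyramid checks
nearest_up2 <- function(x) {
  x[rep(seq_len(nrow(x)), each = 2), rep(seq_len(ncol(x)), each = 2)]
}
stride_down2 <- function(x) {
  x[seq(1, nrow(x), by = 2), seq(1, ncol(x), by = 2), drop = FALSE]
}

# exhaustive percentile-Hausdorff oracle: explicit loops over boundary
# points, literal directed sup-inf at the given percentile
hd95_oracle <- function(Tm, Pm, percentile = 0.95) {
  boundary_pts <- function(M) {
    n <- nrow(M); p <- ncol(M)
    pts <- NULL
    for (i in seq_len(n)) for (j in seq_len(p)) {
      if (!M[i, j]) next
      nb_bg <- (i == 1 || !M[i - 1, j]) || (i == n || !M[i + 1, j]) ||
        (j == 1 || !M[i, j - 1]) || (j == p || !M[i, j + 1])
      if (nb_bg) pts <- rbind(pts, c(i, j))
    }
    if (is.null(pts)) which(M, arr.ind = TRUE) else pts
  }
  if (!any(Tm) && !any(Pm)) return(0)
  if (!any(Tm) || !any(Pm)) return(NA_real_)
  bt <- boundary_pts(Tm != 0); bp <- boundary_pts(Pm != 0)
  d1 <- numeric(nrow(bt))
  for (i in seq_len(nrow(bt))) {
    best <- Inf
    for (j in seq_len(nrow(bp)))
      best <- min(best, sqrt(sum((bt[i, ] - bp[j, ])^2)))
    d1[i] <- best
  }
  d2 <- numeric(nrow(bp))
  for (j in seq_len(nrow(bp))) {
    best <- Inf
    for (i in seq_len(nrow(bt)))
      best <- min(best, sqrt(sum((bp[j, ] - bt[i, ])^2)))
    d2[j] <- best
  }
  max(quantile(d1, percentile, names = FALSE),
      quantile(d2, percentile, names = FALSE))
}
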