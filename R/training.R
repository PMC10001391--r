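# Training: dice loss over the four classes, Adam with polynomial
# learning-rate decay, random 80:10:10 splitting and best-validation-dice
# checkpointing.

#' Per-class dice coefficient
#'
#' For each class c: `2 * sum(p * g) / (sum(p^2) + sum(g^2))` with a
#' smoothing epsilon added to numerator and denominator, where `p` are
#' predicted probabilities and `g` the one-hot ground truth.
#'
#' @param P probability array `H x W x C (x N)`.
#' @param G one-hot array of the same shape.
#' @param eps smoothing constant (default 1e-6).
#' @return numeric vector of length C (one dice value per class).
#' @export
dice_coefficient <- function(P, G, eps = 1e-6) {
  if (!identical(dim(P), dim(G)))
    stop("dice: shape mismatch: ", paste(dim(P), collapse = "x"), " vs ",
         paste(dim(G), collapse = "x"))
  d <- dim(P)
  C <- if (length(d) >= 3) d[3] else 1L
  if (length(d) == 2) { dim(P) <- c(d, 1, 1); dim(G) <- c(d, 1, 1) }
  if (length(dim(P)) == 3) { dim(P) <- c(dim(P), 1); dim(G) <- c(dim(G), 1) }
  vapply(seq_len(C), function(c) {
    p <- P[, , c, ]; g <- G[, , c, ]
    (2 * sum(p * g) + eps) / (sum(p^2) + sum(g^2) + eps)
  }, numeric(1))
}

#' Dice loss
#'
#' `1 - mean(dice_coefficient(P, G))` over the four classes.
#' @inheritParams dice_coefficient
#' @return scalar loss.
#' @export
dice_loss <- function(P, G, eps = 1e-6) 1 - mean(dice_coefficient(P, G, eps))

# autodiff node version: probs node + one-hot array -> scalar loss node
nd_dice_loss <- function(probs, G, eps = 1e-6) {
  P <- probs$value
  d <- dim(P)
  C <- d[3]
  num <- den <- numeric(C)
  for (c in seq_len(C)) {
    p <- P[, , c, , drop = FALSE]; g <- G[, , c, , drop = FALSE]
    num[c] <- 2 * sum(p * g) + eps
    den[c] <- sum(p^2) + sum(g^2) + eps
  }
  loss <- 1 - mean(num / den)
  nd_node(array(loss, c(1, 1, 1, 1)), list(probs), function(gr) {
    g1 <- gr[1]
    dP <- array(0, d)
    for (c in seq_len(C)) {
      p <- P[, , c, , drop = FALSE]; g <- G[, , c, , drop = FALSE]
      # d/dp of -(1/C) * num/den
      dP[, , c, ] <- -g1 / C * (2 * g * den[c] - num[c] * 2 * p) / den[c]^2
    }
    list(dP)
  })
}

#' One-hot encode an integer label map
#'
#' @param labels `H x W` matrix (internal codes 0..C-1) or `H x W x N` array.
#' @param classes number of classes (default 4).
#' @return `H x W x classes x N` array.
#' @export
one_hot <- function(labels, classes = 4L) {
  d <- dim(labels)
  if (length(d) == 2) d <- c(d, 1L)
  dim(labels) <- d
  out <- array(0, c(d[1], d[2], classes, d[3]))
  for (c in seq_len(classes))
    out[, , c, ] <- (labels == (c - 1L)) * 1
  out
}

#' Polynomial learning-rate decay
#'
#' `alpha = alpha0 * (1 - e/Ne)^0.9` with `e` a 0-based epoch counter.
#'
#' @param e epoch counter, `0 <= e <= Ne`.
#' @param Ne total number of epochs (default 350).
#' @param alpha0 initial learning rate (default 1e-4).
#' @param power decay exponent (default 0.9).
#' @return the learning rate for epoch `e`.
#' @export
lr_schedule <- function(e, Ne = 350L, alpha0 = 1e-4, power = 0.9) {
  if (any(e < 0) || any(e > Ne))
    stop("epoch counter must lie in [0, Ne]")
  alpha0 * (1 - e / Ne)^power
}

#' Random train/validation/test split
#'
#' Deterministic under `seed`.  The training share is `floor(r1 * n)`; the
#' remainder is split evenly between validation and test (validation gets
#' the extra case when the remainder is odd), so 369 cases at 80:10:10
#' yield 295/37/37.
#'
#' @param case_ids character or integer vector of case identifiers.
#' @param ratios length-3 positive ratios summing to 1.
#' @param seed integer seed.
#' @return named list `train`, `val`, `test` of disjoint id vectors.
#' @export
split_dataset <- function(case_ids, ratios = c(0.8, 0.1, 0.1), seed = 0L) {
  if (!length(case_ids)) stop("cannot split an empty case list")
  if (abs(sum(ratios) - 1) > 1e-8) stop("split ratios must sum to 1")
  n <- length(case_ids)
  rs <- local_rng(seed)
  on.exit(restore_rng(rs))
  perm <- sample.int(n)
  n_train <- floor(ratios[1] * n)
  rest <- n - n_train
  n_val <- ceiling(rest / 2)
  n_test <- rest - n_val
  list(train = case_ids[perm[seq_len(n_train)]],
       val = case_ids[perm[n_train + seq_len(n_val)]],
       test = case_ids[perm[n_train + n_val + seq_len(n_test)]])
}

#' Train configuration
#'
#' Defaults follow the published protocol: dice loss, Adam, initial learning
#' rate 1e-4 decayed polynomially per epoch, at most 350 epochs, batch
#' size 5, 80:10:10 split.
#'
#' @param alpha0 initial learning rate.
#' @param Ne maximum number of epochs (the learning-rate schedule horizon).
#' @param batch_size mini-batch size.
#' @param split_ratios train/val/test ratios (must sum to 1).
#' @param seed RNG seed for shuffling.
#' @param epochs number of epochs actually run (default `Ne`); fewer than
#'   `Ne` corresponds to stopping training early on the same schedule.
#' @return list of class `train_config`.
#' @export
train_config <- function(alpha0 = 1e-4, Ne = 350L, batch_size = 5L,
                         split_ratios = c(0.8, 0.1, 0.1), seed = 0L,
                         epochs = NULL) {
  if (is.null(epochs)) epochs <- Ne
  stopifnot(Ne >= 1, batch_size >= 1, epochs >= 1, epochs <= Ne,
            abs(sum(split_ratios) - 1) < 1e-8)
  structure(list(alpha0 = alpha0, Ne = as.integer(Ne),
                 batch_size = as.integer(batch_size),
                 split_ratios = split_ratios, seed = as.integer(seed),
                 epochs = as.integer(epochs), loss = "dice"),
            class = "train_config")
}

stack_batch <- function(pairs) {
  d <- dim(pairs[[1]]$x)
  x <- array(0, c(d[1], d[2], 3, length(pairs)))
  g <- array(0, c(d[1], d[2], 4, length(pairs)))
  for (i in seq_along(pairs)) {
    x[, , , i] <- unclass(pairs[[i]]$x)
    g[, , , i] <- one_hot(pairs[[i]]$y)
  }
  list(x = x, g = g)
}

batch_metrics <- function(P, G) {
  dice <- mean(dice_coefficient(P, G))
  pred <- apply(P, c(1, 2, 4), which.max)
  truth <- apply(G, c(1, 2, 4), which.max)
  list(dice = dice, loss = 1 - dice, accuracy = mean(pred == truth))
}

eval_pairs <- function(model, pairs) {
  if (!length(pairs)) return(list(dice = NA_real_, loss = NA_real_,
                                  accuracy = NA_real_))
  b <- stack_batch(pairs)
  P <- model$forward(b$x, training = FALSE)$value
  batch_metrics(P, b$g)
}

#' Train a segmentation model
#'
#' Runs mini-batch Adam on the dice loss with the polynomial learning-rate
#' schedule stepped per epoch, logs per-epoch training/validation metrics
#' and keeps the weights of the epoch with the best validation dice.
#'
#' @param model a [build_model()] object (modified in place; the best
#'   weights are restored on completion when `restore_best = TRUE`).
#' @param data list with `train` and optionally `val`: lists of
#'   `list(x = slice, y = labels)` pairs.
#' @param config a [train_config()].
#' @param verbose print a line per epoch.
#' @param restore_best restore the best checkpoint into the model after
#'   training (default TRUE).
#' @return object of class `train_history`: data.frame of per-epoch metrics
#'   plus attributes `best_epoch` and `best_state`.
#' @export
train_model <- function(model, data, config = train_config(),
                        verbose = FALSE, restore_best = TRUE) {
  train <- data$train
  if (!length(train)) stop("empty training set")
  val <- data$val
  opt <- adam_new(lr = config$alpha0)
  rs <- local_rng(config$seed)
  on.exit(restore_rng(rs))
  hist <- data.frame()
  best <- list(dice = -Inf, epoch = NA_integer_, state = NULL)
  for (epoch in seq_len(config$epochs)) {
    lr <- lr_schedule(epoch - 1L, config$Ne, config$alpha0)
    opt$lr <- lr
    perm <- sample.int(length(train))
    tr_loss <- tr_dice <- tr_acc <- 0
    nb <- 0L
    for (start in seq(1, length(train), by = config$batch_size)) {
      idx <- perm[start:min(start + config$batch_size - 1L, length(train))]
      b <- stack_batch(train[idx])
      probs <- model$forward(b$x, training = TRUE)
      loss <- nd_dice_loss(probs, b$g)
      nd_zero_grads(model$net$params)
      nd_backward(loss)
      adam_step(opt, model$net$params)
      m <- batch_metrics(probs$value, b$g)
      tr_loss <- tr_loss + loss$value[1]
      tr_dice <- tr_dice + m$dice
      tr_acc <- tr_acc + m$accuracy
      nb <- nb + 1L
    }
    vm <- eval_pairs(model, val)
    row <- data.frame(epoch = epoch, lr = lr,
                      train_loss = tr_loss / nb, train_dice = tr_dice / nb,
                      train_accuracy = tr_acc / nb,
                      val_loss = vm$loss, val_dice = vm$dice,
                      val_accuracy = vm$accuracy)
    hist <- rbind(hist, row)
    sel_dice <- if (is.na(vm$dice)) tr_dice / nb else vm$dice
    if (sel_dice > best$dice) {
      best$dice <- sel_dice
      best$epoch <- epoch
      best$state <- net_state(model$net)
    }
    if (verbose)
      message(sprintf(
        "epoch %3d lr %.3g train dice %.4f val dice %s", epoch, lr,
        tr_dice / nb, ifelse(is.na(vm$dice), "-", sprintf("%.4f", vm$dice))))
  }
  if (restore_best && !is.null(best$state)) net_restore(model$net, best$state)
  structure(hist, class = c("train_history", "data.frame"),
            best_epoch = best$epoch, best_dice = best$dice,
            best_state = best$state)
}

#' @export
print.train_history <- function(x, ...) {
  cat(sprintf("<train_history: %d epochs, best epoch %d (dice %.4f)>\n",
              nrow(x), attr(x, "best_epoch"), attr(x, "best_dice")))
  print.data.frame(utils::tail(as.data.frame(x), 3), row.names = FALSE)
  invisible(x)
}
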