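# Network building blocks on top of the autodiff nodes: parameter registry,
# initializers, convolution + batch-norm layers, depthwise-separable blocks
# and the Adam optimizer.

new_net <- function(seed = NULL) {
  net <- new.env(parent = emptyenv())
  net$params <- list()
  net$layers <- list()
  net$training <- TRUE
  class(net) <- "triunet_net"
  net
}

#' He / Xavier weight initialization
#' @keywords internal
init_weights <- function(dim, scheme = c("he", "xavier", "zeros", "ones")) {
  scheme <- match.arg(scheme)
  n <- prod(dim)
  if (scheme == "zeros") return(array(0, dim))
  if (scheme == "ones") return(array(1, dim))
  if (length(dim) == 4) {
    fan_in <- dim[1] * dim[2] * dim[3]
    fan_out <- dim[1] * dim[2] * dim[4]
  } else {
    fan_in <- prod(dim)
    fan_out <- prod(dim)
  }
  sd <- if (scheme == "he") sqrt(2 / fan_in) else sqrt(2 / (fan_in + fan_out))
  array(stats::rnorm(n, 0, sd), dim)
}

add_param <- function(net, name, dim, scheme = "he", group = "model") {
  p <- nd_param(init_weights(dim, scheme), name = name, group = group)
  net$params[[name]] <- p
  p
}

#' 2-D convolution layer
#'
#' @param pad "same" keeps spatial size at stride 1; an integer pads
#'   explicitly.
#' @keywords internal
conv_layer <- function(net, name, k, cin, cout, stride = 1L, pad = "same",
                       bias = TRUE, scheme = "he", group = "model") {
  ly <- new.env(parent = emptyenv())
  ly$w <- add_param(net, paste0(name, ".w"), c(k, k, cin, cout),
                    scheme = scheme, group = group)
  ly$b <- if (bias) add_param(net, paste0(name, ".b"), c(cout),
                              scheme = "zeros", group = group) else NULL
  ly$stride <- as.integer(stride)
  ly$pad <- if (identical(pad, "same")) (k - 1L) %/% 2L else as.integer(pad)
  ly$fwd <- function(x) nd_conv2d(x, ly$w, ly$b, ly$stride, ly$pad)
  net$layers[[name]] <- ly
  ly
}

dwconv_layer <- function(net, name, k, channels, stride = 1L, pad = "same",
                         bias = FALSE, group = "model") {
  ly <- new.env(parent = emptyenv())
  ly$w <- add_param(net, paste0(name, ".w"), c(k, k, channels),
                    scheme = "he", group = group)
  # depthwise fan-in is k*k
  ly$w$value <- array(stats::rnorm(k * k * channels, 0, sqrt(2 / (k * k))),
                      c(k, k, channels))
  ly$b <- if (bias) add_param(net, paste0(name, ".b"), c(channels),
                              scheme = "zeros", group = group) else NULL
  ly$stride <- as.integer(stride)
  ly$pad <- if (identical(pad, "same")) (k - 1L) %/% 2L else as.integer(pad)
  ly$fwd <- function(x) nd_dwconv2d(x, ly$w, ly$b, ly$stride, ly$pad)
  net$layers[[name]] <- ly
  ly
}

#' Batch normalization layer
#'
#' Uses batch statistics in training mode and exponential running statistics
#' in evaluation mode.
#' @keywords internal
bn_layer <- function(net, name, channels, momentum = 0.1, eps = 1e-5,
                     group = "model") {
  ly <- new.env(parent = emptyenv())
  ly$gamma <- add_param(net, paste0(name, ".gamma"), c(channels), "ones",
                        group = group)
  ly$beta <- add_param(net, paste0(name, ".beta"), c(channels), "zeros",
                       group = group)
  ly$running_mean <- rep(0, channels)
  ly$running_var <- rep(1, channels)
  ly$momentum <- momentum
  ly$eps <- eps
  ly$fwd <- function(x) nd_batchnorm(x, ly, net$training)
  net$layers[[name]] <- ly
  ly
}

nd_batchnorm <- function(x, ly, training) {
  v <- x$value
  d <- dim(v)
  C <- d[3]
  eps <- ly$eps
  if (training) {
    xp <- aperm(v, c(1, 2, 4, 3))
    m <- d[1] * d[2] * d[4]
    xm <- matrix(xp, nrow = m, ncol = C)
    mu <- colMeans(xm)
    va <- colMeans(xm^2) - mu^2
    ly$running_mean <- (1 - ly$momentum) * ly$running_mean + ly$momentum * mu
    ly$running_var <- (1 - ly$momentum) * ly$running_var +
      ly$momentum * va * m / max(1, m - 1)
    sd_ <- sqrt(va + eps)
    xhat <- sweep(xm, 2, mu) / rep(sd_, each = m)
    g <- ly$gamma$value
    ym <- xhat * rep(g, each = m) + rep(ly$beta$value, each = m)
    y <- aperm(array(ym, dim = d[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
    nd_node(y, list(x, ly$gamma, ly$beta), function(gr) {
      grp <- matrix(aperm(gr, c(1, 2, 4, 3)), nrow = m, ncol = C)
      dgamma <- colSums(grp * xhat)
      dbeta <- colSums(grp)
      dxhat <- grp * rep(g, each = m)
      dxm <- (dxhat -
                rep(colMeans(dxhat), each = m) -
                xhat * rep(colMeans(dxhat * xhat), each = m)) /
        rep(sd_, each = m)
      dx <- aperm(array(dxm, dim = d[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
      list(dx, dgamma, dbeta)
    })
  } else {
    scale <- ly$gamma$value / sqrt(ly$running_var + eps)
    shift <- ly$beta$value - ly$running_mean * scale
    y <- v
    for (c in seq_len(C)) y[, , c, ] <- v[, , c, ] * scale[c] + shift[c]
    nd_node(y, list(x, ly$gamma, ly$beta), function(gr) {
      m <- d[1] * d[2] * d[4]
      grp <- matrix(aperm(gr, c(1, 2, 4, 3)), nrow = m, ncol = C)
      vp <- matrix(aperm(v, c(1, 2, 4, 3)), nrow = m, ncol = C)
      xhat <- sweep(vp, 2, ly$running_mean) /
        rep(sqrt(ly$running_var + eps), each = m)
      dgamma <- colSums(grp * xhat)
      dbeta <- colSums(grp)
      dx <- gr
      for (c in seq_len(C)) dx[, , c, ] <- gr[, , c, ] * scale[c]
      list(dx, dgamma, dbeta)
    })
  }
}

#' Convolution + batch norm + activation block
#' @keywords internal
conv_bn_act <- function(net, name, k, cin, cout, stride = 1L,
                        act = c("relu", "relu6", "linear"), group = "model") {
  act <- match.arg(act)
  conv <- conv_layer(net, paste0(name, ".conv"), k, cin, cout, stride,
                     bias = FALSE, group = group)
  bn <- bn_layer(net, paste0(name, ".bn"), cout, group = group)
  fwd <- function(x) {
    y <- bn$fwd(conv$fwd(x))
    switch(act, relu = nd_relu(y), relu6 = nd_relu6_op(y), linear = y)
  }
  list(conv = conv, bn = bn, fwd = fwd)
}

#' Depthwise-separable fusion block: 3x3 depthwise + 1x1 pointwise
#' convolution, batch normalization and activation after each convolution.
#' @keywords internal
dwsep_block <- function(net, name, channels, act = "relu6", group = "model") {
  dw <- dwconv_layer(net, paste0(name, ".dw"), 3L, channels, group = group)
  dwbn <- bn_layer(net, paste0(name, ".dwbn"), channels, group = group)
  pw <- conv_layer(net, paste0(name, ".pw"), 1L, channels, channels,
                   bias = FALSE, group = group)
  pwbn <- bn_layer(net, paste0(name, ".pwbn"), channels, group = group)
  actf <- if (act == "relu6") nd_relu6_op else nd_relu
  fwd <- function(x) actf(pwbn$fwd(pw$fwd(actf(dwbn$fwd(dw$fwd(x))))))
  list(dw = dw, pw = pw, fwd = fwd)
}

#' Count of trainable parameter values in a depthwise-separable block versus
#' a dense convolution with the same kernel and channel count.
#' @param channels channel count C.
#' @param k spatial kernel size (default 3).
#' @return named list with `depthwise_separable`, `dense` and `norm_params`.
#' @export
separable_param_count <- function(channels, k = 3) {
  list(depthwise_separable = channels * k * k + channels * channels,
       dense = channels * channels * k * k,
       norm_params = 4 * channels)
}

# ---- optimizer -------------------------------------------------------------

#' Adam optimizer state
#' @keywords internal
adam_new <- function(lr = 1e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt <- new.env(parent = emptyenv())
  opt$lr <- lr
  opt$beta1 <- beta1
  opt$beta2 <- beta2
  opt$eps <- eps
  opt$t <- 0L
  opt$m <- list()
  opt$v <- list()
  opt
}

adam_step <- function(opt, params) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  bc1 <- 1 - b1^opt$t
  bc2 <- 1 - b2^opt$t
  for (nm in names(params)) {
    p <- params[[nm]]
    if (!isTRUE(p$trainable) || is.null(p$grad)) next
    g <- p$grad
    m <- opt$m[[nm]]
    v <- opt$v[[nm]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    opt$m[[nm]] <- m
    opt$v[[nm]] <- v
    p$value <- p$value - opt$lr * (m / bc1) / (sqrt(v / bc2) + opt$eps)
  }
  invisible(opt)
}

# snapshot / restore parameter values (used for checkpointing)
net_state <- function(net) lapply(net$params, function(p) p$value)

net_restore <- function(net, state) {
  for (nm in names(state)) net$params[[nm]]$value <- state[[nm]]
  invisible(net)
}

set_trainable <- function(net, groups, trainable) {
  for (p in net$params)
    if (p$group %in% groups) p$trainable <- trainable
  invisible(net)
}
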