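# Minimal reverse-mode automatic differentiation over 4-D feature maps.
#
# A node is an environment holding a value (array with dim (H, W, C, N)),
# an accumulated gradient, its parent nodes and a backward closure that maps
# the node's gradient to a list of parent gradients.  Nodes are created in
# forward order; backpropagation visits reachable nodes in reverse creation
# order, which is a valid topological order for any tape built sequentially.

.tape <- new.env(parent = emptyenv())
.tape$id <- 0L

nd_next_id <- function() {
  .tape$id <- .tape$id + 1L
  .tape$id
}

#' Create an autodiff node
#'
#' @param value numeric array.
#' @param parents list of parent nodes the value was computed from.
#' @param backward function(grad) returning a list of gradients, one per
#'   parent (NULL entries allowed for parents that need no gradient).
#' @keywords internal
nd_node <- function(value, parents = list(), backward = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$backward <- backward
  e$grad <- NULL
  e$is_param <- FALSE
  e$id <- nd_next_id()
  class(e) <- "triunet_node"
  e
}

#' Create a parameter node
#' @keywords internal
nd_param <- function(value, name = NULL, group = "model", trainable = TRUE) {
  e <- nd_node(value)
  e$is_param <- TRUE
  e$name <- name
  e$group <- group
  e$trainable <- trainable
  e
}

nd_const <- function(value) nd_node(value)

#' Run backpropagation from a scalar loss node
#'
#' Accumulates gradients into `$grad` of every ancestor node.
#' @keywords internal
nd_backward <- function(loss) {
  stopifnot(inherits(loss, "triunet_node"), length(loss$value) == 1L)
  # collect reachable nodes
  seen <- new.env(parent = emptyenv())
  stack <- list(loss)
  nodes <- list()
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1L]] <- nd
    for (p in nd$parents) stack[[length(stack) + 1L]] <- p
  }
  ord <- order(vapply(nodes, function(nd) nd$id, integer(1)),
               decreasing = TRUE)
  loss$grad <- array(1, dim = c(1, 1, 1, 1))
  for (nd in nodes[ord]) {
    if (is.null(nd$backward) || is.null(nd$grad)) next
    gs <- nd$backward(nd$grad)
    for (i in seq_along(nd$parents)) {
      g <- gs[[i]]
      if (is.null(g)) next
      p <- nd$parents[[i]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(loss)
}

nd_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- elementwise ops -------------------------------------------------------

nd_relu <- function(x) {
  v <- x$value
  y <- pmax(v, 0)
  dim(y) <- dim(v)
  nd_node(y, list(x), function(g) list(g * (v > 0)))
}

nd_relu6_op <- function(x) {
  v <- x$value
  y <- pmin(pmax(v, 0), 6)
  dim(y) <- dim(v)
  nd_node(y, list(x), function(g) list(g * (v > 0 & v < 6)))
}

nd_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  dim(s) <- dim(x$value)
  nd_node(s, list(x), function(g) list(g * s * (1 - s)))
}

nd_add <- function(a, b) {
  nd_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

nd_add3 <- function(a, b, d) {
  nd_node(a$value + b$value + d$value, list(a, b, d),
          function(g) list(g, g, g))
}

# x * alpha with alpha a single-channel map broadcast across x's channels
nd_mul_gate <- function(x, alpha) {
  dx <- dim(x$value)
  a <- alpha$value
  ab <- array(a[, , rep(1L, dx[3]), , drop = FALSE], dim = dx)
  nd_node(x$value * ab, list(x, alpha), function(g) {
    ga <- rowSums(aperm(g * x$value, c(1, 2, 4, 3)), dims = 3)
    dim(ga) <- c(dx[1], dx[2], 1, dx[4])
    list(g * ab, ga)
  })
}

nd_concat <- function(xs) {
  dims <- lapply(xs, function(x) dim(x$value))
  chans <- vapply(dims, `[`, numeric(1), 3)
  d <- dims[[1]]
  d[3] <- sum(chans)
  y <- array(0, dim = d)
  off <- 0L
  for (i in seq_along(xs)) {
    y[, , off + seq_len(chans[i]), ] <- xs[[i]]$value
    off <- off + chans[i]
  }
  nd_node(y, xs, function(g) {
    out <- vector("list", length(xs))
    off <- 0L
    for (i in seq_along(xs)) {
      out[[i]] <- g[, , off + seq_len(chans[i]), , drop = FALSE]
      off <- off + chans[i]
    }
    out
  })
}

# ---- conv / pool / resize wrappers -----------------------------------------

nd_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L) {
  has_bias <- !is.null(b)
  bv <- if (has_bias) as.numeric(b$value) else numeric(0)
  y <- cpp_conv2d_fwd(x$value, w$value, bv, as.integer(stride),
                      as.integer(pad))
  parents <- if (has_bias) list(x, w, b) else list(x, w)
  nd_node(y, parents, function(g) {
    gr <- cpp_conv2d_bwd(x$value, w$value, g, as.integer(stride),
                         as.integer(pad), has_bias)
    if (has_bias) list(gr$dx, gr$dw, gr$db) else list(gr$dx, gr$dw)
  })
}

nd_dwconv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L) {
  has_bias <- !is.null(b)
  bv <- if (has_bias) as.numeric(b$value) else numeric(0)
  y <- cpp_dwconv2d_fwd(x$value, w$value, bv, as.integer(stride),
                        as.integer(pad))
  parents <- if (has_bias) list(x, w, b) else list(x, w)
  nd_node(y, parents, function(g) {
    gr <- cpp_dwconv2d_bwd(x$value, w$value, g, as.integer(stride),
                           as.integer(pad), has_bias)
    if (has_bias) list(gr$dx, gr$dw, gr$db) else list(gr$dx, gr$dw)
  })
}

nd_maxpool <- function(x, k = 2L, stride = k, pad = 0L) {
  r <- cpp_maxpool_fwd(x$value, as.integer(k), as.integer(stride),
                       as.integer(pad))
  H <- dim(x$value)[1]; W <- dim(x$value)[2]
  nd_node(r$y, list(x), function(g) {
    list(cpp_maxpool_bwd(r$idx, g, H, W))
  })
}

nd_resize_bilinear <- function(x, Ho, Wo) {
  d <- dim(x$value)
  if (d[1] == Ho && d[2] == Wo) return(x)
  y <- cpp_resize_bilinear_fwd(x$value, as.integer(Ho), as.integer(Wo))
  nd_node(y, list(x), function(g) {
    list(cpp_resize_bilinear_bwd(g, as.integer(d[1]), as.integer(d[2])))
  })
}

nd_upsample2 <- function(x) {
  d <- dim(x$value)
  nd_resize_bilinear(x, 2L * d[1], 2L * d[2])
}

# per-pixel softmax across the channel dimension
nd_softmax <- function(x) {
  v <- x$value
  d <- dim(v)
  m <- v[, , 1, , drop = FALSE]
  for (c in seq_len(d[3])[-1]) m <- pmax(m, v[, , c, , drop = FALSE])
  ex <- exp(v - array(m[, , rep(1L, d[3]), , drop = FALSE], dim = d))
  s <- ex[, , 1, , drop = FALSE]
  for (c in seq_len(d[3])[-1]) s <- s + ex[, , c, , drop = FALSE]
  p <- ex / array(s[, , rep(1L, d[3]), , drop = FALSE], dim = d)
  nd_node(p, list(x), function(g) {
    dot <- (g * p)[, , 1, , drop = FALSE]
    for (c in seq_len(d[3])[-1]) dot <- dot + (g * p)[, , c, , drop = FALSE]
    list(p * (g - array(dot[, , rep(1L, d[3]), , drop = FALSE], dim = d)))
  })
}
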