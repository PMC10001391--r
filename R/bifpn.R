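# Feature-pyramid fusion layers.
#
# fpn_topdown is the classical one-way top-down pyramid; bifpn_layer is the
# five-level bidirectional pyramid used in the production network.  Both are
# expressed as pure dataflow functions parameterized by the convolution and
# resize operations, so the same wiring runs on autodiff nodes inside the
# network and on plain arrays with stub operations in analytic checks.

#' Top-down feature pyramid dataflow
#'
#' Levels are ordered fine to coarse.  The coarsest output is
#' `conv(coarsest input)`; every finer output is
#' `conv(level input + resize(next-coarser output))`.
#'
#' @param levels list of feature maps (fine -> coarse), any length >= 1.
#' @param conv function `(slot_name, x) -> x'` applied after each sum.
#' @param resize_up function upsampling a coarser map by 2 to the finer
#'   level's size.
#' @param add binary addition (defaults to `+`).
#' @return list of output levels, same order and length.
#' @export
fpn_topdown <- function(levels, conv, resize_up, add = `+`) {
  n <- length(levels)
  if (n == 0) stop("fpn_topdown needs at least one level")
  out <- vector("list", n)
  out[[n]] <- conv(sprintf("P%dout", n), levels[[n]])
  if (n > 1)
    for (l in (n - 1):1)
      out[[l]] <- conv(sprintf("P%dout", l),
                       add(levels[[l]], resize_up(out[[l + 1]])))
  out
}

#' Five-level bidirectional pyramid dataflow
#'
#' Exactly the eight assignments of the 5-level layer: a top-down pass
#' producing L4mid, L3mid, L2mid, then L1out, followed by a bottom-up pass
#' producing L2out..L4out (three-term sums of the level input, its mid node
#' and the downsized finer output) and finally L5out.  L1 and L5 have no mid
#' node.
#'
#' @param levels list of exactly 5 feature maps, fine (L1) to coarse (L5).
#' @param conv function `(slot_name, x) -> x'`; slots are `"L4mid"`,
#'   `"L3mid"`, `"L2mid"`, `"L1out"`, `"L2out"`, `"L3out"`, `"L4out"`,
#'   `"L5out"`.
#' @param resize_up upsample-by-2 (coarse -> fine edge).
#' @param resize_down downsample-by-2 (fine -> coarse edge).
#' @param add,add3 2- and 3-term elementwise sums.
#' @return list of 5 output levels with the input resolutions and channels.
#' @export
bifpn_dataflow <- function(levels, conv, resize_up, resize_down,
                           add = `+`, add3 = function(a, b, d) a + b + d) {
  if (length(levels) != 5)
    stop("the bidirectional pyramid layer is defined for exactly 5 levels, ",
         "got ", length(levels))
  L <- levels
  m4 <- conv("L4mid", add(L[[4]], resize_up(L[[5]])))
  m3 <- conv("L3mid", add(L[[3]], resize_up(m4)))
  m2 <- conv("L2mid", add(L[[2]], resize_up(m3)))
  o1 <- conv("L1out", add(L[[1]], resize_up(m2)))
  o2 <- conv("L2out", add3(L[[2]], m2, resize_down(o1)))
  o3 <- conv("L3out", add3(L[[3]], m3, resize_down(o2)))
  o4 <- conv("L4out", add3(L[[4]], m4, resize_down(o3)))
  o5 <- conv("L5out", add(L[[5]], resize_down(o4)))
  list(o1, o2, o3, o4, o5)
}

#' Build a bidirectional pyramid network layer
#'
#' Creates the eight fusion blocks (each a depthwise-separable convolution:
#' 3x3 depthwise + 1x1 pointwise, batch normalization and activation after
#' each convolution) and returns a forward closure over autodiff nodes.
#' Upsampling is bilinear x2; downsampling is 2x2 max-pooling, both stride 2.
#'
#' @param net parameter registry.
#' @param group parameter group label.
#' @param channels uniform pyramid channel count.
#' @param repeats number of stacked passes (default 1).
#' @return function mapping a list of 5 nodes to a list of 5 nodes.
#' @keywords internal
build_bifpn <- function(net, group, channels, repeats = 1L) {
  slots <- c("L4mid", "L3mid", "L2mid", "L1out", "L2out", "L3out", "L4out",
             "L5out")
  passes <- lapply(seq_len(repeats), function(r) {
    blocks <- lapply(slots, function(s)
      dwsep_block(net, sprintf("%s.r%d.%s", group, r, s), channels,
                  group = group))
    names(blocks) <- slots
    blocks
  })
  function(pyramid) {
    for (r in seq_len(repeats)) {
      blocks <- passes[[r]]
      pyramid <- bifpn_dataflow(
        pyramid,
        conv = function(slot, x) blocks[[slot]]$fwd(x),
        resize_up = nd_upsample2,
        resize_down = function(x) nd_maxpool(x, 2L, 2L, 0L),
        add = nd_add, add3 = nd_add3)
    }
    pyramid
  }
}

#' Depthwise-separable fusion applied to a plain feature array
#'
#' Convenience wrapper building a standalone depthwise-separable block
#' (random weights) and running it on an `H x W x C (x N)` array; used to
#' inspect the block's shape-preservation and parameter economy.
#'
#' @param x feature array.
#' @param channels channel count (defaults to `dim(x)[3]`).
#' @return list with `y` (output array, same shape) and `params`
#'   (see [separable_param_count()]).
#' @export
depthwise_fuse <- function(x, channels = NULL) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  if (is.null(channels)) channels <- dim(x)[3]
  stopifnot(channels == dim(x)[3])
  net <- new_net()
  blk <- dwsep_block(net, "fuse", channels)
  net$training <- FALSE
  y <- blk$fwd(nd_const(x))$value
  list(y = y, params = separable_param_count(channels))
}
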