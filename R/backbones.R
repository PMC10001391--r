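# Encoder feature extractors.  Three classification topologies are built
# without their classification heads, each exposing five feature tap points:
#   vgg19       - last activation of each of the five conv blocks (pre-pool),
#                 native resolutions (S, S/2, S/4, S/8, S/16);
#   resnet50    - stem and the four bottleneck stages, strides 2..32;
#   mobilenetv2 - the five coarsest distinct-resolution stage outputs,
#                 strides 2..32.
# A width multiplier scales every channel count so a "tiny" profile with
# identical topology can run in tests.  A lateral 1x1 projection maps every
# tap to a uniform channel count at the canonical pyramid resolutions
# (S, S/2, S/4, S/8, S/16).

ENCODER_NAMES <- c("vgg19", "resnet50", "mobilenetv2")

round_ch <- function(c, width) max(1L, as.integer(round(c * width)))

#' Element-wise ReLU6 activation
#'
#' `min(max(x, 0), 6)` — the clipped rectifier used throughout MobileNetV2
#' and in the pyramid fusion blocks.
#'
#' @param x numeric scalar or array.
#' @return same shape as `x`.
#' @export
relu6 <- function(x) pmin(pmax(x, 0), 6)

# ---- VGG-19 ----------------------------------------------------------------

build_vgg19 <- function(net, group, cin = 3L, width = 1) {
  cfg <- list(c(64, 2), c(128, 2), c(256, 4), c(512, 4), c(512, 4))
  blocks <- list()
  prev <- cin
  for (b in seq_along(cfg)) {
    cout <- round_ch(cfg[[b]][1], width)
    convs <- list()
    for (i in seq_len(cfg[[b]][2])) {
      convs[[i]] <- conv_layer(net, sprintf("%s.b%d.conv%d", group, b, i),
                               3L, prev, cout, bias = TRUE, group = group)
      prev <- cout
    }
    blocks[[b]] <- convs
  }
  tap_channels <- vapply(cfg, function(z) round_ch(z[1], width), integer(1))
  forward <- function(x) {
    taps <- vector("list", 5)
    h <- x
    for (b in seq_along(blocks)) {
      for (conv in blocks[[b]]) h <- nd_relu(conv$fwd(h))
      taps[[b]] <- h
      if (b < 5) h <- nd_maxpool(h, 2L, 2L, 0L)
    }
    taps
  }
  list(forward = forward, tap_channels = tap_channels,
       tap_strides = c(1L, 2L, 4L, 8L, 16L))
}

# ---- ResNet50 --------------------------------------------------------------

bottleneck <- function(net, name, cin, mid, cout, stride, group) {
  c1 <- conv_bn_act(net, paste0(name, ".c1"), 1L, cin, mid, 1L, "relu", group)
  c2 <- conv_bn_act(net, paste0(name, ".c2"), 3L, mid, mid, stride, "relu",
                    group)
  c3 <- conv_bn_act(net, paste0(name, ".c3"), 1L, mid, cout, 1L, "linear",
                    group)
  short <- if (stride != 1L || cin != cout)
    conv_bn_act(net, paste0(name, ".sc"), 1L, cin, cout, stride, "linear",
                group) else NULL
  function(x) {
    y <- c3$fwd(c2$fwd(c1$fwd(x)))
    s <- if (is.null(short)) x else short$fwd(x)
    nd_relu(nd_add(y, s))
  }
}

build_resnet50 <- function(net, group, cin = 3L, width = 1) {
  ch <- function(c) round_ch(c, width)
  stem <- conv_bn_act(net, paste0(group, ".stem"), 7L, cin, ch(64), 2L,
                      "relu", group)
  stage_cfg <- list(c(64, 256, 3, 1), c(128, 512, 4, 2),
                    c(256, 1024, 6, 2), c(512, 2048, 3, 2))
  stages <- list()
  prev <- ch(64)
  for (s in seq_along(stage_cfg)) {
    z <- stage_cfg[[s]]
    blocks <- list()
    for (b in seq_len(z[3])) {
      blocks[[b]] <- bottleneck(net, sprintf("%s.s%d.b%d", group, s, b),
                                prev, ch(z[1]), ch(z[2]),
                                if (b == 1) z[4] else 1L, group)
      prev <- ch(z[2])
    }
    stages[[s]] <- blocks
  }
  tap_channels <- c(ch(64), vapply(stage_cfg, function(z) ch(z[2]),
                                   integer(1)))
  forward <- function(x) {
    taps <- vector("list", 5)
    h <- stem$fwd(x)
    taps[[1]] <- h
    h <- nd_maxpool(h, 3L, 2L, 1L)
    for (s in seq_along(stages)) {
      for (blk in stages[[s]]) h <- blk(h)
      taps[[s + 1]] <- h
    }
    taps
  }
  list(forward = forward, tap_channels = tap_channels,
       tap_strides = c(2L, 4L, 8L, 16L, 32L))
}

# ---- MobileNetV2 -----------------------------------------------------------

inverted_residual <- function(net, name, cin, cout, expand, stride, group) {
  mid <- cin * expand
  ex <- if (expand != 1L)
    conv_bn_act(net, paste0(name, ".ex"), 1L, cin, mid, 1L, "relu6", group)
  else NULL
  dw <- dwconv_layer(net, paste0(name, ".dw"), 3L, mid, stride, group = group)
  dwbn <- bn_layer(net, paste0(name, ".dwbn"), mid, group = group)
  pj <- conv_bn_act(net, paste0(name, ".pj"), 1L, mid, cout, 1L, "linear",
                    group)
  use_res <- stride == 1L && cin == cout
  function(x) {
    h <- if (is.null(ex)) x else ex$fwd(x)
    h <- nd_relu6_op(dwbn$fwd(dw$fwd(h)))
    h <- pj$fwd(h)
    if (use_res) nd_add(h, x) else h
  }
}

build_mobilenetv2 <- function(net, group, cin = 3L, width = 1) {
  ch <- function(c) round_ch(c, width)
  stem <- conv_bn_act(net, paste0(group, ".stem"), 3L, cin, ch(32), 2L,
                      "relu6", group)
  # (expand, channels, repeats, first-stride)
  cfg <- list(c(1, 16, 1, 1), c(6, 24, 2, 2), c(6, 32, 3, 2),
              c(6, 64, 4, 2), c(6, 96, 3, 1), c(6, 160, 3, 2),
              c(6, 320, 1, 1))
  groups_ <- list()
  prev <- ch(32)
  for (g in seq_along(cfg)) {
    z <- cfg[[g]]
    blocks <- list()
    for (b in seq_len(z[3])) {
      blocks[[b]] <- inverted_residual(net, sprintf("%s.g%d.b%d", group, g, b),
                                       prev, ch(z[2]), as.integer(z[1]),
                                       if (b == 1) as.integer(z[4]) else 1L,
                                       group)
      prev <- ch(z[2])
    }
    groups_[[g]] <- blocks
  }
  tap_after <- c(1L, 2L, 3L, 5L, 7L)  # stage groups at strides 2,4,8,16,32
  tap_channels <- vapply(cfg[tap_after], function(z) ch(z[2]), integer(1))
  forward <- function(x) {
    taps <- vector("list", 5)
    h <- stem$fwd(x)
    for (g in seq_along(groups_)) {
      for (blk in groups_[[g]]) h <- blk(h)
      hit <- match(g, tap_after)
      if (!is.na(hit)) taps[[hit]] <- h
    }
    taps
  }
  list(forward = forward, tap_channels = tap_channels,
       tap_strides = c(2L, 4L, 8L, 16L, 32L))
}

# ---- public encoder interface ----------------------------------------------

#' Build an encoder feature extractor
#'
#' Constructs one of the three supported encoder topologies without its
#' classification head.  A forward pass on an `S x S x 3` input yields the
#' five raw tap feature maps.
#'
#' @param name `"vgg19"`, `"resnet50"` or `"mobilenetv2"`.
#' @param width channel width multiplier (1 = the published widths).
#' @param pretrained load initial weights from `weights_file` instead of
#'   random initialization.  No weights ship with the package; the flag
#'   requires an explicit weights file (an RDS of a parameter-value list).
#' @param trainable when FALSE the encoder parameters are frozen (they
#'   receive no optimizer updates).
#' @param weights_file path to an RDS parameter snapshot (used when
#'   `pretrained = TRUE`).
#' @param net optionally an existing parameter registry to build into.
#' @param group parameter group label (used for freezing).
#' @return object of class `triunet_encoder` with elements `forward`
#'   (node -> list of 5 nodes), `tap_channels`, `tap_strides`, `net`.
#' @export
build_encoder <- function(name, width = 1, pretrained = FALSE,
                          trainable = TRUE, weights_file = NULL,
                          net = NULL, group = name) {
  if (!name %in% ENCODER_NAMES)
    stop("unknown encoder '", name, "'; expected one of: ",
         paste(ENCODER_NAMES, collapse = ", "))
  own_net <- is.null(net)
  if (own_net) net <- new_net()
  enc <- switch(name,
                vgg19 = build_vgg19(net, group, width = width),
                resnet50 = build_resnet50(net, group, width = width),
                mobilenetv2 = build_mobilenetv2(net, group, width = width))
  if (pretrained) {
    if (is.null(weights_file) || !file.exists(weights_file))
      stop("pretrained = TRUE requires an existing weights_file ",
           "(RDS parameter snapshot); none is bundled with the package")
    state <- readRDS(weights_file)
    net_restore(net, state[intersect(names(state), names(net$params))])
  }
  if (!trainable) set_trainable(net, group, FALSE)
  structure(list(name = name, forward = enc$forward,
                 tap_channels = enc$tap_channels,
                 tap_strides = enc$tap_strides,
                 net = net, group = group, width = width),
            class = "triunet_encoder")
}

#' Raw tap features of an encoder for a batch of images
#'
#' @param encoder a [build_encoder()] object.
#' @param x `H x W x 3` array or `H x W x 3 x N` batch.
#' @return list of 5 feature arrays (fine to coarse).
#' @export
encoder_features <- function(encoder, x) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  encoder$net$training <- FALSE
  taps <- encoder$forward(nd_const(x))
  lapply(taps, function(nd) nd$value)
}

#' Lateral projection of raw tap features onto the canonical pyramid
#'
#' Each tap is passed through a 1x1 convolution to a uniform channel count
#' and bilinearly resized (when needed) to the canonical resolutions
#' `(S, S/2, S/4, S/8, S/16)`.
#' @keywords internal
build_projector <- function(net, group, tap_channels, channels, input_size) {
  sizes <- as.integer(input_size / c(1L, 2L, 4L, 8L, 16L))
  convs <- lapply(seq_len(5), function(l)
    conv_layer(net, sprintf("%s.lat%d", group, l), 1L, tap_channels[l],
               channels, bias = TRUE, group = group))
  function(taps) {
    lapply(seq_len(5), function(l)
      nd_resize_bilinear(convs[[l]]$fwd(taps[[l]]), sizes[l], sizes[l]))
  }
}
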