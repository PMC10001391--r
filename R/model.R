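# Full network assembly: per-encoder pyramids, cross-encoder fusion, and the
# attention-gated decoder with a four-class softmax head.
#
# Ablation variants mirror the published build configurations:
#   single      - one encoder + plain decoder
#   multi       - three encoders + plain decoder
#   multi_att   - three encoders + attention decoder
#   multi_bifpn - three encoders + Bi-FPN + plain decoder
#   full        - three encoders + Bi-FPN + attention decoder (the method)

MODEL_VARIANTS <- c("single", "multi", "multi_att", "multi_bifpn", "full")

#' Model size profiles
#'
#' `"full"` is the published configuration: 224x224 inputs, published encoder
#' widths, 32-channel pyramids, 128-channel decoder and attention blocks.
#' `"tiny"` runs the identical topology at desk scale: 64x64 inputs, 1/8
#' encoder widths, 8-channel pyramids, 16-channel decoder/attention blocks.
#'
#' @param name `"full"` or `"tiny"`.
#' @return list of profile fields.
#' @export
model_profile <- function(name = c("full", "tiny")) {
  name <- match.arg(name)
  switch(name,
    full = list(name = "full", input_size = 224L, width = 1,
                pyramid_channels = 32L, decoder_channels = 128L,
                attention_channels = 128L),
    tiny = list(name = "tiny", input_size = 64L, width = 1 / 8,
                pyramid_channels = 8L, decoder_channels = 16L,
                attention_channels = 16L))
}

# ---- attention gate --------------------------------------------------------

#' Build an additive attention gate
#'
#' Computes `alpha = sigmoid(psi(relu(Wx x + Wg g + bg)) + bpsi)` with 1x1
#' channel-wise convolutions for Wx, Wg and psi (Xavier-initialized), and
#' gates the skip feature as `x * alpha` with alpha broadcast over channels.
#' The gating signal `g` must already be at the skip feature's resolution.
#' @keywords internal
build_attention_gate <- function(net, name, skip_ch, gate_ch, inter_ch,
                                 group) {
  wx <- conv_layer(net, paste0(name, ".wx"), 1L, skip_ch, inter_ch,
                   bias = FALSE, scheme = "xavier", group = group)
  wg <- conv_layer(net, paste0(name, ".wg"), 1L, gate_ch, inter_ch,
                   bias = TRUE, scheme = "xavier", group = group)
  psi <- conv_layer(net, paste0(name, ".psi"), 1L, inter_ch, 1L,
                    bias = TRUE, scheme = "xavier", group = group)
  list(wx = wx, wg = wg, psi = psi,
       fwd = function(xl, g) {
         q <- nd_relu(nd_add(wx$fwd(xl), wg$fwd(g)))
         alpha <- nd_sigmoid(psi$fwd(q))
         list(alpha = alpha, out = nd_mul_gate(xl, alpha))
       })
}

#' Standalone attention gate on plain arrays
#'
#' Builds a gate with fresh (Xavier) weights and applies it to a skip
#' feature and gating signal; the gating signal is bilinearly resized to the
#' skip resolution first when needed.
#'
#' @param xl skip feature, `H x W x C (x N)` array.
#' @param g gating signal array (any spatial size, same batch).
#' @param inter_ch intermediate attention channel count.
#' @param gate optionally the `layers` element of a previous call, to reuse
#'   (or inspect/modify) the gate weights.
#' @return list with `alpha` (attention coefficient map, values in \[0, 1\]),
#'   `out` (`xl * alpha`) and `layers` (the gate weights).
#' @export
attention_gate <- function(xl, g, inter_ch = 16L, gate = NULL) {
  single <- length(dim(xl)) == 3
  if (single) dim(xl) <- c(dim(xl), 1L)
  if (length(dim(g)) == 3) dim(g) <- c(dim(g), 1L)
  ag <- if (!is.null(gate)) gate else {
    net <- new_net()
    build_attention_gate(net, "ag", dim(xl)[3], dim(g)[3], inter_ch, "gate")
  }
  gn <- nd_resize_bilinear(nd_const(g), dim(xl)[1], dim(xl)[2])
  r <- ag$fwd(nd_const(xl), gn)
  alpha <- r$alpha$value
  out <- r$out$value
  if (single) {
    alpha <- alpha[, , 1, 1]
    dim(out) <- dim(out)[1:3]
  }
  list(alpha = alpha, out = out, layers = ag)
}

# ---- decoder ---------------------------------------------------------------

build_upatt <- function(net, name, prev_ch, skip_ch, dec_ch, att_ch,
                        attention, group) {
  gate <- NULL
  gs_conv <- NULL
  gs_bn <- NULL
  if (attention) {
    gs_conv <- conv_layer(net, paste0(name, ".gs"), 1L, prev_ch, att_ch,
                          bias = FALSE, group = group)
    gs_bn <- bn_layer(net, paste0(name, ".gsbn"), att_ch, group = group)
    gate <- build_attention_gate(net, paste0(name, ".ag"), skip_ch, att_ch,
                                 att_ch, group)
  }
  dc1 <- conv_bn_act(net, paste0(name, ".dc1"), 3L, prev_ch + skip_ch,
                     dec_ch, 1L, "relu", group)
  dc2 <- conv_bn_act(net, paste0(name, ".dc2"), 3L, dec_ch, dec_ch, 1L,
                     "relu", group)
  function(prev, skip) {
    pd <- dim(prev$value); sd_ <- dim(skip$value)
    if (sd_[1] != 2L * pd[1] || sd_[2] != 2L * pd[2])
      stop(sprintf("decoder stage %s: skip resolution %dx%d is not twice ",
                   name, sd_[1], sd_[2]),
           sprintf("the incoming %dx%d", pd[1], pd[2]))
    sk <- if (attention) {
      g <- nd_upsample2(gs_bn$fwd(gs_conv$fwd(prev)))
      gate$fwd(skip, g)$out
    } else skip
    up <- nd_upsample2(prev)
    dc2$fwd(dc1$fwd(nd_concat(list(up, sk))))
  }
}

# ---- full model ------------------------------------------------------------

#' Build the segmentation network
#'
#' Assembles encoders, lateral projections, optional per-encoder
#' bidirectional pyramid layers, cross-encoder fusion, the (plain or
#' attention-gated) decoder and the four-class softmax head.
#'
#' @param variant one of `"single"`, `"multi"`, `"multi_att"`,
#'   `"multi_bifpn"`, `"full"` (default `"full"`).
#' @param profile `"full"` (224x224, published widths) or `"tiny"`
#'   (64x64 desk-scale); alternatively a list from [model_profile()].
#' @param encoder encoder name for the `"single"` variant.
#' @param fusion `"concat"` (channel concatenation + 1x1 convolution, the
#'   default) or `"sum"` (elementwise sum + 1x1 convolution).
#' @param bifpn_repeats number of stacked pyramid passes.
#' @param trainable_encoders FALSE freezes all encoder parameters.
#' @param pretrained,weights_file optional initial encoder weights (RDS
#'   parameter snapshot); nothing is downloaded.
#' @param seed integer seed for weight initialization (reproducible builds).
#' @return object of class `triunet_model`.
#' @export
build_model <- function(variant = "full", profile = "full",
                        encoder = "vgg19", fusion = c("concat", "sum"),
                        bifpn_repeats = 1L, trainable_encoders = TRUE,
                        pretrained = FALSE, weights_file = NULL,
                        seed = NULL) {
  if (!variant %in% MODEL_VARIANTS)
    stop("unknown model variant '", variant, "'; expected one of: ",
         paste(MODEL_VARIANTS, collapse = ", "))
  fusion <- match.arg(fusion)
  if (is.character(profile)) profile <- model_profile(profile)
  if (!is.null(seed)) {
    rs <- local_rng(seed)
    on.exit(restore_rng(rs))
  }
  S <- profile$input_size
  pc <- profile$pyramid_channels
  dc <- profile$decoder_channels
  ac <- profile$attention_channels
  enc_names <- if (variant == "single") encoder else ENCODER_NAMES
  use_bifpn <- variant %in% c("multi_bifpn", "full")
  use_att <- variant %in% c("multi_att", "full")
  net <- new_net()
  encoders <- list()
  projectors <- list()
  bifpns <- list()
  for (nm in enc_names) {
    grp <- paste0("encoder_", nm)
    encoders[[nm]] <- build_encoder(nm, width = profile$width,
                                    pretrained = pretrained,
                                    weights_file = weights_file,
                                    net = net, group = grp)
    projectors[[nm]] <- build_projector(net, paste0("neck_", nm),
                                        encoders[[nm]]$tap_channels, pc, S)
    if (use_bifpn)
      bifpns[[nm]] <- build_bifpn(net, paste0("bifpn_", nm), pc,
                                  bifpn_repeats)
  }
  fuse_convs <- NULL
  if (length(enc_names) > 1) {
    cin <- if (fusion == "concat") 3L * pc else pc
    fuse_convs <- lapply(seq_len(5), function(l)
      conv_layer(net, sprintf("fuse.l%d", l), 1L, cin, pc, bias = TRUE,
                 group = "fusion"))
  }
  upatts <- list()
  prev_ch <- pc
  for (d in seq_len(4)) {
    upatts[[d]] <- build_upatt(net, sprintf("dec.up%d", d), prev_ch, pc, dc,
                               ac, use_att, "decoder")
    prev_ch <- dc
  }
  head_conv <- conv_layer(net, "head.conv", 1L, dc, 4L, bias = FALSE,
                          group = "decoder")
  head_bn <- bn_layer(net, "head.bn", 4L, group = "decoder")
  if (!trainable_encoders)
    set_trainable(net, paste0("encoder_", enc_names), FALSE)

  forward <- function(x, training = FALSE, return_parts = FALSE) {
    net$training <- training
    if (!inherits(x, "triunet_node")) {
      x <- unclass(x)
      if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
      x <- nd_const(x)
    }
    pyramids <- list()
    for (nm in enc_names) {
      p <- projectors[[nm]](encoders[[nm]]$forward(x))
      if (use_bifpn) p <- bifpns[[nm]](p)
      pyramids[[nm]] <- p
    }
    fused <- if (length(enc_names) == 1) {
      pyramids[[1]]
    } else {
      lapply(seq_len(5), function(l) {
        merged <- if (fusion == "concat")
          nd_concat(lapply(pyramids, `[[`, l))
        else
          nd_add3(pyramids[[1]][[l]], pyramids[[2]][[l]], pyramids[[3]][[l]])
        fuse_convs[[l]]$fwd(merged)
      })
    }
    h <- fused[[5]]
    for (d in seq_len(4)) h <- upatts[[d]](h, fused[[5 - d]])
    probs <- nd_softmax(head_bn$fwd(head_conv$fwd(h)))
    if (return_parts)
      list(probs = probs, pyramids = pyramids, fused = fused, decoder = h)
    else probs
  }

  structure(list(net = net, forward = forward, variant = variant,
                 profile = profile, encoders = encoders, fusion = fusion,
                 encoder_names = enc_names, use_bifpn = use_bifpn,
                 use_attention = use_att),
            class = "triunet_model")
}

#' @export
print.triunet_model <- function(x, ...) {
  np <- sum(vapply(x$net$params, function(p) length(p$value), numeric(1)))
  cat(sprintf(
    "<triunet_model '%s' (%s profile): %s encoder(s)%s%s, %d parameters>\n",
    x$variant, x$profile$name, paste(x$encoder_names, collapse = "+"),
    if (x$use_bifpn) " + Bi-FPN" else "",
    if (x$use_attention) " + attention decoder" else " + plain decoder",
    np))
  invisible(x)
}

#' @export
summary.triunet_model <- function(object, ...) {
  groups <- vapply(object$net$params, function(p) p$group, character(1))
  sizes <- vapply(object$net$params, function(p) length(p$value), numeric(1))
  df <- stats::aggregate(sizes, list(group = groups), sum)
  names(df)[2] <- "parameters"
  print(object)
  print(df, row.names = FALSE)
  invisible(df)
}

#' Forward pass returning class probabilities
#'
#' @param model a [build_model()] object.
#' @param x `H x W x 3` slice or `H x W x 3 x N` batch.
#' @param training use batch statistics in the normalization layers.
#' @return `H x W x 4 (x N)` array of per-pixel class probabilities in the
#'   channel order (background, necrotic core, edema/non-enhancing,
#'   enhancing).
#' @export
model_forward <- function(model, x, training = FALSE) {
  single <- length(dim(x)) == 3
  p <- model$forward(x, training = training)$value
  if (single) p <- p[, , , 1]
  p
}

#' Predict a label map for one slice
#'
#' Per-pixel argmax over the four class probabilities.
#'
#' @param model a [build_model()] object.
#' @param x `H x W x 3` preprocessed slice.
#' @return integer label matrix with internal codes 0..3.
#' @export
predict_labels <- function(model, x) {
  p <- model_forward(model, x)
  lab <- apply(p, c(1, 2), which.max) - 1L
  storage.mode(lab) <- "integer"
  lab
}
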