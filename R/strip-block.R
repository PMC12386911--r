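# StripBlock: directional depthwise (strip) convolution block for elongated
# structures such as pine crowns and trunks, plus the C3k2-style container
# that hosts a chain of them in the backbone.
#
# Strip attention factors a large square kernel into a horizontal 1 x k and a
# vertical k x 1 depthwise convolution after a 5 x 5 depthwise aggregation,
# then gates the branch input multiplicatively through a pointwise mix:
#   Attn(x) = x (*) Conv1x1(DWConv_{k x 1}(DWConv_{1 x k}(DWConv_{5 x 5}(x))))
# The block output uses a parallel dual residual with learnable per-channel
# layer scaling:
#   out = x + g1 * Attn(BN1(x)) + g2 * MLP(BN2(x))
# k = 10 by default; the even kernel gets asymmetric "same" padding
# (floor((k-1)/2) leading, ceiling trailing) so shapes are preserved exactly.

#' Configuration for StripBlock units
#'
#' @param channels Channel count the block operates on.
#' @param k Strip kernel length (default 10, balancing receptive field
#'   against cost).
#' @param mlp_expansion Hidden-width multiplier of the channel-mixing MLP.
#' @param drop_rate Dropout rate inside the MLP (`[0, 1)`; default 0).
#' @param layer_scale_init Initial value of the per-channel residual scales.
#' @return A list with class `stripBlockConfig`.
#' @export
stripBlockConfig <- function(channels, k = 10L, mlp_expansion = 4,
                             drop_rate = 0, layer_scale_init = 1e-2) {
  stopifnot(channels >= 1, k >= 2, mlp_expansion > 0,
            drop_rate >= 0, drop_rate < 1, layer_scale_init > 0)
  structure(list(channels = as.integer(channels), k = as.integer(k),
                 mlp_expansion = mlp_expansion, drop_rate = drop_rate,
                 layer_scale_init = layer_scale_init),
            class = "stripBlockConfig")
}

#' Strip attention unit
#'
#' Builds the multiplicative directional-convolution gate. The returned
#' module preserves the spatial and channel shape of its input.
#'
#' @param cfg A [stripBlockConfig()].
#' @return An internal network module; run it with `nnForward()`.
#' @export
stripAttention <- function(cfg) {
  ch <- cfg$channels; k <- cfg$k
  nnGate(nnSequential(
    nnConv2d(ch, ch, c(5, 5), groups = ch),        # local aggregation
    nnConv2d(ch, ch, c(1, k), groups = ch),        # horizontal strip
    nnConv2d(ch, ch, c(k, 1), groups = ch),        # vertical strip
    nnConv2d(ch, ch, c(1, 1))                      # pointwise mix
  ))
}

#' Strip MLP unit
#'
#' Inter-channel mixing: pointwise expansion, 3 x 3 depthwise, GELU,
#' dropout, pointwise projection. Shape preserving.
#'
#' @inheritParams stripAttention
#' @export
stripMLP <- function(cfg) {
  ch <- cfg$channels
  hidden <- max(1L, as.integer(round(ch * cfg$mlp_expansion)))
  nnSequential(
    nnConv2d(ch, hidden, c(1, 1)),
    nnConv2d(hidden, hidden, c(3, 3), groups = hidden),
    nnGELU(),
    nnDropout(cfg$drop_rate),
    nnConv2d(hidden, ch, c(1, 1))
  )
}

#' StripBlock
#'
#' Parallel dual-residual block combining [stripAttention()] and
#' [stripMLP()], each behind its own batch normalization and learnable
#' layer scale. With both scales zero the block is an exact identity in
#' evaluation mode.
#'
#' @inheritParams stripAttention
#' @export
stripBlock <- function(cfg) {
  ch <- cfg$channels
  newModule("cwStripBlock",
            bn1 = nnBatchNorm2d(ch),
            attn = stripAttention(cfg),
            ls1 = nnLayerScale(ch, cfg$layer_scale_init),
            bn2 = nnBatchNorm2d(ch),
            mlp = stripMLP(cfg),
            ls2 = nnLayerScale(ch, cfg$layer_scale_init))
}

#' @export
nnForward.cwStripBlock <- function(mod, x, train = FALSE) {
  a <- nnForward(mod$ls1, nnForward(mod$attn, nnForward(mod$bn1, x, train), train), train)
  b <- nnForward(mod$ls2, nnForward(mod$mlp, nnForward(mod$bn2, x, train), train), train)
  x + a + b
}

#' @export
nnBackward.cwStripBlock <- function(mod, dout) {
  da <- nnBackward(mod$bn1, nnBackward(mod$attn, nnBackward(mod$ls1, dout)))
  db <- nnBackward(mod$bn2, nnBackward(mod$mlp, nnBackward(mod$ls2, dout)))
  dout + da + db
}

# C3k2-style container ---------------------------------------------------
#
# Split / transform / concat / fuse: a pointwise convolution widens the
# input to two hidden streams; one stream runs through the block chain;
# both are concatenated and fused back by a second pointwise convolution.

newC3k2 <- function(in_ch, out_ch, blocks) {
  hidden <- max(1L, out_ch %/% 2L)
  newModule("cwC3k2",
            cv1 = nnConvBNAct(in_ch, 2L * hidden, k = 1),
            blocks = blocks,
            cv2 = nnConvBNAct(2L * hidden, out_ch, k = 1),
            hidden = hidden)
}

#' @export
nnForward.cwC3k2 <- function(mod, x, train = FALSE) {
  h <- mod$hidden
  y <- nnForward(mod$cv1, x, train)
  y1 <- sliceChannels(y, 1L, h)
  y2 <- sliceChannels(y, h + 1L, 2L * h)
  for (b in mod$blocks) y2 <- nnForward(b, y2, train)
  nnForward(mod$cv2, catChannels(list(y1, y2)), train)
}

#' @export
nnBackward.cwC3k2 <- function(mod, dout) {
  h <- mod$hidden
  dcat <- nnBackward(mod$cv2, dout)
  d1 <- sliceChannels(dcat, 1L, h)
  d2 <- sliceChannels(dcat, h + 1L, 2L * h)
  for (b in rev(mod$blocks)) d2 <- nnBackward(b, d2)
  nnBackward(mod$cv1, catChannels(list(d1, d2)))
}

#' C3k2 container with StripBlocks
#'
#' @param in_ch,out_ch Input and output channel counts.
#' @param n_blocks Number of StripBlocks on the transformed stream.
#' @param k Strip kernel length.
#' @param ... Passed to [stripBlockConfig()].
#' @export
c3k2Strip <- function(in_ch, out_ch, n_blocks = 1L, k = 10L, ...) {
  hidden <- max(1L, out_ch %/% 2L)
  cfg <- stripBlockConfig(hidden, k = k, ...)
  newC3k2(in_ch, out_ch, lapply(seq_len(n_blocks), function(i) stripBlock(cfg)))
}

# plain C3k2 (ablation baseline): residual 3x3 conv bottlenecks
c3k2Plain <- function(in_ch, out_ch, n_blocks = 1L) {
  hidden <- max(1L, out_ch %/% 2L)
  blocks <- lapply(seq_len(n_blocks), function(i)
    nnResidual(nnSequential(nnConvBNAct(hidden, hidden, 3), nnConvBNAct(hidden, hidden, 3))))
  newC3k2(in_ch, out_ch, blocks)
}
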