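# Channel-aware context attention (CAA) for the feature-fusion neck.
#
# A CAA unit squeezes local context with a stride-1 7 x 7 average pool, mixes
# channels pointwise, encodes direction with a horizontal 1 x k then vertical
# k x 1 depthwise convolution (k = 10), projects pointwise and gates the unit
# input through a logistic sigmoid:
#   CAA(x) = x (*) sigma(Conv1x1(DW_{k x 1}(DW_{1 x k}(Conv1x1(AvgPool7(x))))))
# Since the gate lies strictly in (0, 1), |CAA(x)| <= |x| elementwise. The
# pool is local (stride 1, padding 3): global pooling would collapse the map
# and leave nothing for the directional kernels to traverse.

#' Configuration for CAA units and their container
#'
#' @param channels Channel count the attention unit operates on.
#' @param k Strip kernel length for the directional convolutions.
#' @param pool_size Odd window of the local average pool (default 7).
#' @param n_units CAA units concatenated inside the container.
#' @return A list with class `caaConfig`.
#' @export
caaConfig <- function(channels, k = 10L, pool_size = 7L, n_units = 1L) {
  stopifnot(channels >= 1, k >= 2, pool_size >= 3, pool_size %% 2 == 1,
            n_units >= 1)
  structure(list(channels = as.integer(channels), k = as.integer(k),
                 pool_size = as.integer(pool_size),
                 n_units = as.integer(n_units)),
            class = "caaConfig")
}

#' Channel-aware attention unit
#'
#' @param cfg A [caaConfig()].
#' @return A shape-preserving network module; run with `nnForward()`.
#' @export
caaBlock <- function(cfg) {
  ch <- cfg$channels; k <- cfg$k
  nnSigmoidGate(nnSequential(
    nnAvgPool(cfg$pool_size),
    nnConv2d(ch, ch, c(1, 1)),
    nnConv2d(ch, ch, c(1, k), groups = ch),   # horizontal strip
    nnConv2d(ch, ch, c(k, 1), groups = ch),   # vertical strip
    nnConv2d(ch, ch, c(1, 1))
  ))
}

# container: y = Conv1x1(Concat(xh, CAA_1(xh), ..., CAA_n(xh)))
# with xh the input after a pointwise entry to the hidden width out/2
# (the usual C3k2 halving convention for the transformed stream).

#' C3k2 container with CAA units
#'
#' The input is brought to the hidden width by a pointwise entry
#' convolution; `n_units` CAA units are applied to that stream, their
#' outputs concatenated with it ((n_units + 1) x hidden channels) and
#' fused to `out_ch` by a pointwise convolution.
#'
#' @param in_ch,out_ch Input and output channel counts.
#' @param n_units Number of CAA units.
#' @param k Strip kernel length.
#' @param pool_size Average-pool window.
#' @export
c3k2Caa <- function(in_ch, out_ch, n_units = 1L, k = 10L, pool_size = 7L) {
  hidden <- max(1L, out_ch %/% 2L)
  cfg <- caaConfig(hidden, k = k, pool_size = pool_size, n_units = n_units)
  newModule("cwC3k2Caa",
            cv1 = nnConvBNAct(in_ch, hidden, k = 1),
            units = lapply(seq_len(n_units), function(i) caaBlock(cfg)),
            cv2 = nnConvBNAct((n_units + 1L) * hidden, out_ch, k = 1),
            hidden = hidden)
}

#' @export
nnForward.cwC3k2Caa <- function(mod, x, train = FALSE) {
  xh <- nnForward(mod$cv1, x, train)
  outs <- c(list(xh), lapply(mod$units, function(u) nnForward(u, xh, train)))
  nnForward(mod$cv2, catChannels(outs), train)
}

#' @export
nnBackward.cwC3k2Caa <- function(mod, dout) {
  h <- mod$hidden
  dcat <- nnBackward(mod$cv2, dout)
  dxh <- sliceChannels(dcat, 1L, h)
  for (i in seq_along(mod$units)) {
    dui <- sliceChannels(dcat, i * h + 1L, (i + 1L) * h)
    dxh <- dxh + nnBackward(mod$units[[i]], dui)
  }
  nnBackward(mod$cv1, dxh)
}
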