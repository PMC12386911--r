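# Minimal layer system for the detection network.
#
# Layers are mutable environments (reference semantics, needed for parameter
# updates and cached activations) with S3 dispatch on nnForward/nnBackward.
# Tensors are plain R arrays with dim (H, W, C, N); all heavy kernels live in
# src/conv.cpp. Backward passes require a preceding nnForward(..., train = TRUE).

newParam <- function(value) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$mom <- NULL
  class(e) <- "cwParam"
  e
}

accumGrad <- function(p, g) {
  if (is.null(p$grad)) p$grad <- g else p$grad <- p$grad + g
  invisible(p)
}

newModule <- function(cls, ...) {
  e <- new.env(parent = emptyenv())
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- c(cls, "cwModule")
  e
}

#' @keywords internal
nnForward <- function(mod, x, train = FALSE) UseMethod("nnForward")

#' @keywords internal
nnBackward <- function(mod, dout) UseMethod("nnBackward")

#' @keywords internal
nnParams <- function(mod) UseMethod("nnParams")

#' @export
nnParams.default <- function(mod) {
  out <- list()
  for (nm in ls(mod, sorted = TRUE)) {
    v <- get(nm, envir = mod)
    if (inherits(v, "cwParam")) out[[length(out) + 1L]] <- v
    else if (inherits(v, "cwModule")) out <- c(out, nnParams(v))
    else if (is.list(v)) for (el in v) if (inherits(el, "cwModule")) out <- c(out, nnParams(el))
  }
  out
}

nParameters <- function(mod) {
  sum(vapply(nnParams(mod), function(p) length(p$value), numeric(1)))
}

zeroGrads <- function(mod) {
  for (p in nnParams(mod)) p$grad <- NULL
  invisible(mod)
}

# One SGD-with-momentum step over every parameter of a module tree.
sgdStep <- function(mod, lr, momentum = 0.8, weight_decay = 0) {
  for (p in nnParams(mod)) {
    if (is.null(p$grad)) next
    g <- p$grad
    if (weight_decay > 0) g <- g + weight_decay * p$value
    p$mom <- if (is.null(p$mom)) g else momentum * p$mom + g
    p$value <- p$value - lr * p$mom
  }
  invisible(mod)
}

# state-dict style (de)serialization -------------------------------------

moduleState <- function(mod) {
  st <- list()
  walk <- function(m, prefix) {
    for (nm in ls(m, sorted = TRUE)) {
      v <- get(nm, envir = m)
      key <- paste0(prefix, nm)
      if (inherits(v, "cwParam")) st[[key]] <<- v$value
      else if (inherits(v, "cwModule")) walk(v, paste0(key, "."))
      else if (is.list(v)) {
        for (i in seq_along(v)) if (inherits(v[[i]], "cwModule"))
          walk(v[[i]], paste0(key, i, "."))
      } else if (nm %in% c("running_mean", "running_var")) st[[key]] <<- v
    }
  }
  walk(mod, "")
  st
}

loadModuleState <- function(mod, st) {
  walk <- function(m, prefix) {
    for (nm in ls(m, sorted = TRUE)) {
      v <- get(nm, envir = m)
      key <- paste0(prefix, nm)
      if (inherits(v, "cwParam")) {
        stopifnot(!is.null(st[[key]]))
        v$value <- st[[key]]
      } else if (inherits(v, "cwModule")) walk(v, paste0(key, "."))
      else if (is.list(v)) {
        for (i in seq_along(v)) if (inherits(v[[i]], "cwModule"))
          walk(v[[i]], paste0(key, i, "."))
      } else if (nm %in% c("running_mean", "running_var")) assign(nm, st[[key]], envir = m)
    }
  }
  walk(mod, "")
  invisible(mod)
}

# convolution --------------------------------------------------------------

samePad <- function(kh, kw) {
  # even kernels pad floor((k-1)/2) on the leading edge, ceiling on the trailing
  c(floor((kh - 1) / 2), ceiling((kh - 1) / 2),
    floor((kw - 1) / 2), ceiling((kw - 1) / 2))
}

nnConv2d <- function(in_ch, out_ch, k, stride = 1L, pad = "same",
                     groups = 1L, bias = TRUE) {
  if (length(k) == 1L) k <- c(k, k)
  stopifnot(in_ch %% groups == 0, out_ch %% groups == 0)
  cg <- in_ch %/% groups
  if (identical(pad, "same")) pad <- samePad(k[1], k[2])
  fan_in <- k[1] * k[2] * cg
  w <- array(stats::rnorm(k[1] * k[2] * cg * out_ch, sd = sqrt(2 / fan_in)),
             dim = c(k[1], k[2], cg, out_ch))
  newModule("cwConv2d",
            w = newParam(w),
            b = if (bias) newParam(numeric(out_ch)) else NULL,
            stride = as.integer(stride), pad = as.integer(pad),
            groups = as.integer(groups))
}

#' @export
nnForward.cwConv2d <- function(mod, x, train = FALSE) {
  if (train) mod$cache <- x
  .cw_conv2d_fwd(x, mod$w$value,
                 if (!is.null(mod$b)) mod$b$value else NULL,
                 mod$stride, mod$pad, mod$groups)
}

#' @export
nnBackward.cwConv2d <- function(mod, dout) {
  r <- .cw_conv2d_bwd(mod$cache, mod$w$value, dout, mod$stride, mod$pad,
                      mod$groups, TRUE, !is.null(mod$b))
  accumGrad(mod$w, r$dw)
  if (!is.null(mod$b)) accumGrad(mod$b, r$db)
  r$dx
}

# batch normalization ------------------------------------------------------

nnBatchNorm2d <- function(ch, momentum = 0.1, eps = 1e-5) {
  newModule("cwBatchNorm2d",
            gamma = newParam(rep(1, ch)), beta = newParam(numeric(ch)),
            running_mean = numeric(ch), running_var = rep(1, ch),
            momentum = momentum, eps = eps)
}

#' @export
nnForward.cwBatchNorm2d <- function(mod, x, train = FALSE) {
  if (train) {
    st <- .cw_channel_stats(x)
    invstd <- 1 / sqrt(st$var + mod$eps)
    xhat <- .cw_channel_affine(x, invstd, -st$mean * invstd)
    mod$running_mean <- (1 - mod$momentum) * mod$running_mean + mod$momentum * st$mean
    mod$running_var <- (1 - mod$momentum) * mod$running_var + mod$momentum * st$var
    mod$cache <- list(xhat = xhat, invstd = invstd)
    .cw_channel_affine(xhat, mod$gamma$value, mod$beta$value)
  } else {
    invstd <- 1 / sqrt(mod$running_var + mod$eps)
    .cw_channel_affine(x, mod$gamma$value * invstd,
                       mod$beta$value - mod$running_mean * invstd * mod$gamma$value)
  }
}

#' @export
nnBackward.cwBatchNorm2d <- function(mod, dout) {
  ca <- mod$cache
  d <- dim(dout)
  m <- d[1] * d[2] * d[4]
  sum_dy <- .cw_channel_stats(dout)$mean * m
  sum_dy_xhat <- .cw_channel_dot(dout, ca$xhat)
  accumGrad(mod$gamma, sum_dy_xhat)
  accumGrad(mod$beta, sum_dy)
  .cw_bn_bwd(dout, ca$xhat, mod$gamma$value, ca$invstd, sum_dy, sum_dy_xhat, TRUE)
}

# per-channel learnable residual scaling (layer scale) ----------------------

nnLayerScale <- function(ch, init = 1e-2) {
  newModule("cwLayerScale", gamma = newParam(rep(init, ch)))
}

#' @export
nnForward.cwLayerScale <- function(mod, x, train = FALSE) {
  if (train) mod$cache <- x
  .cw_channel_affine(x, mod$gamma$value, numeric(length(mod$gamma$value)))
}

#' @export
nnBackward.cwLayerScale <- function(mod, dout) {
  accumGrad(mod$gamma, .cw_channel_dot(dout, mod$cache))
  .cw_channel_affine(dout, mod$gamma$value, numeric(length(mod$gamma$value)))
}

# activations ---------------------------------------------------------------

nnSiLU <- function() newModule("cwSiLU")

#' @export
nnForward.cwSiLU <- function(mod, x, train = FALSE) {
  s <- 1 / (1 + exp(-x))
  if (train) mod$cache <- list(x = x, s = s)
  x * s
}

#' @export
nnBackward.cwSiLU <- function(mod, dout) {
  ca <- mod$cache
  dout * ca$s * (1 + ca$x * (1 - ca$s))
}

nnGELU <- function() newModule("cwGELU")

#' @export
nnForward.cwGELU <- function(mod, x, train = FALSE) {
  p <- stats::pnorm(x)
  if (train) mod$cache <- list(x = x, p = p)
  x * p
}

#' @export
nnBackward.cwGELU <- function(mod, dout) {
  ca <- mod$cache
  dout * (ca$p + ca$x * stats::dnorm(ca$x))
}

nnDropout <- function(rate = 0) newModule("cwDropout", rate = rate)

#' @export
nnForward.cwDropout <- function(mod, x, train = FALSE) {
  if (!train || mod$rate <= 0) {
    mod$cache <- NULL
    return(x)
  }
  keep <- 1 - mod$rate
  mask <- array(stats::rbinom(length(x), 1L, keep) / keep, dim = dim(x))
  mod$cache <- mask
  x * mask
}

#' @export
nnBackward.cwDropout <- function(mod, dout) {
  if (is.null(mod$cache)) dout else dout * mod$cache
}

# pooling / resampling -------------------------------------------------------

nnAvgPool <- function(k) {
  stopifnot(k %% 2 == 1, k >= 3)
  newModule("cwAvgPool", k = as.integer(k))
}

#' @export
nnForward.cwAvgPool <- function(mod, x, train = FALSE) .cw_avgpool_same(x, mod$k)

#' @export
nnBackward.cwAvgPool <- function(mod, dout) .cw_avgpool_same(dout, mod$k)

nnUpsample2 <- function() newModule("cwUpsample2")

#' @export
nnForward.cwUpsample2 <- function(mod, x, train = FALSE) .cw_upsample2(x)

#' @export
nnBackward.cwUpsample2 <- function(mod, dout) .cw_upsample2_bwd(dout)

# containers ------------------------------------------------------------------

nnSequential <- function(...) {
  mods <- list(...)
  if (length(mods) == 1L && is.list(mods[[1]]) && !inherits(mods[[1]], "cwModule"))
    mods <- mods[[1]]
  newModule("cwSequential", children = mods)
}

#' @export
nnForward.cwSequential <- function(mod, x, train = FALSE) {
  for (m in mod$children) x <- nnForward(m, x, train)
  x
}

#' @export
nnBackward.cwSequential <- function(mod, dout) {
  for (m in rev(mod$children)) dout <- nnBackward(m, dout)
  dout
}

# y = x + inner(x)
nnResidual <- function(inner) newModule("cwResidual", inner = inner)

#' @export
nnForward.cwResidual <- function(mod, x, train = FALSE) {
  x + nnForward(mod$inner, x, train)
}

#' @export
nnBackward.cwResidual <- function(mod, dout) {
  dout + nnBackward(mod$inner, dout)
}

# y = x * inner(x)  (multiplicative gate, identity multiplier)
nnGate <- function(inner) newModule("cwGate", inner = inner)

#' @export
nnForward.cwGate <- function(mod, x, train = FALSE) {
  fx <- nnForward(mod$inner, x, train)
  if (train) mod$cache <- list(x = x, fx = fx)
  x * fx
}

#' @export
nnBackward.cwGate <- function(mod, dout) {
  ca <- mod$cache
  dout * ca$fx + nnBackward(mod$inner, dout * ca$x)
}

# y = x * sigmoid(inner(x))  (attention gate)
nnSigmoidGate <- function(inner) newModule("cwSigmoidGate", inner = inner)

#' @export
nnForward.cwSigmoidGate <- function(mod, x, train = FALSE) {
  s <- 1 / (1 + exp(-nnForward(mod$inner, x, train)))
  if (train) mod$cache <- list(x = x, s = s)
  x * s
}

#' @export
nnBackward.cwSigmoidGate <- function(mod, dout) {
  ca <- mod$cache
  dout * ca$s + nnBackward(mod$inner, dout * ca$x * ca$s * (1 - ca$s))
}

# channel helpers --------------------------------------------------------------

catChannels <- function(xs) {
  d <- dim(xs[[1]])
  cs <- vapply(xs, function(x) dim(x)[3], numeric(1))
  out <- array(0, dim = c(d[1], d[2], sum(cs), d[4]))
  at <- 0L
  for (x in xs) {
    cc <- dim(x)[3]
    out[, , (at + 1L):(at + cc), ] <- x
    at <- at + cc
  }
  out
}

sliceChannels <- function(x, from, to) {
  x[, , from:to, , drop = FALSE]
}

# standard conv -> BN -> SiLU unit
nnConvBNAct <- function(in_ch, out_ch, k = 3, stride = 1) {
  nnSequential(nnConv2d(in_ch, out_ch, k, stride = stride, bias = FALSE),
               nnBatchNorm2d(out_ch), nnSiLU())
}
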