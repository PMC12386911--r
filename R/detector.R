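# Anchor-free single-stage detector: strip-convolution backbone, CAA fusion
# neck, and a per-cell head trained with binary cross-entropy classification
# plus the SDIoU box-regression loss.
#
# The head predicts, at every cell of three pyramid levels (strides 8/16/32),
# four box values (left/top/right/bottom distances through softplus, in
# stride units) and one logit per class. Assignment is center-region based:
# a ground-truth box supervises the cells of its best-matching stride whose
# centers fall inside its central half, plus always the cell containing its
# center.

#' Detector configuration
#'
#' @param input_size Square network input side in px; must be divisible by
#'   the largest stride. The full-scale regime uses 640; desk-scale smoke
#'   runs use smaller inputs.
#' @param n_classes Number of foreground classes (default 2: Weak, Dead).
#' @param width_multiple,depth_multiple Channel/depth scaling ratios applied
#'   to the pico base widths (8, 16, 32, 48, 64 channels).
#' @param strides Pyramid strides.
#' @param box_loss_weight,cls_loss_weight Loss component weights.
#' @param conf_threshold,nms_iou_threshold Decoding thresholds.
#' @param use_strip,use_caa,use_sdiou Ablation toggles: replace the strip
#'   backbone blocks / CAA neck blocks with plain C3k2 bottlenecks, or the
#'   SDIoU box loss with plain 1 - IoU.
#' @param k Strip kernel length.
#' @return A list with class `detectorConfig`.
#' @export
detectorConfig <- function(input_size = 640L, n_classes = 2L,
                           width_multiple = 1, depth_multiple = 1,
                           strides = c(8L, 16L, 32L),
                           box_loss_weight = 7.5, cls_loss_weight = 0.5,
                           conf_threshold = 0.25, nms_iou_threshold = 0.45,
                           use_strip = TRUE, use_caa = TRUE, use_sdiou = TRUE,
                           k = 10L) {
  stopifnot(input_size %% max(strides) == 0, n_classes >= 1,
            width_multiple > 0, depth_multiple > 0,
            box_loss_weight > 0, cls_loss_weight > 0,
            conf_threshold >= 0, conf_threshold <= 1,
            nms_iou_threshold >= 0, nms_iou_threshold <= 1)
  base <- c(8L, 16L, 32L, 48L, 64L)
  widths <- pmax(4L, as.integer(round(base * width_multiple)))
  structure(list(input_size = as.integer(input_size),
                 n_classes = as.integer(n_classes),
                 width_multiple = width_multiple,
                 depth_multiple = depth_multiple,
                 widths = widths,
                 n_blocks = max(1L, as.integer(round(depth_multiple))),
                 strides = as.integer(strides),
                 box_loss_weight = box_loss_weight,
                 cls_loss_weight = cls_loss_weight,
                 conf_threshold = conf_threshold,
                 nms_iou_threshold = nms_iou_threshold,
                 use_strip = isTRUE(use_strip), use_caa = isTRUE(use_caa),
                 use_sdiou = isTRUE(use_sdiou), k = as.integer(k)),
            class = "detectorConfig")
}

#' Training configuration
#'
#' Defaults follow the full-scale training regime (SGD, learning rate 0.01,
#' momentum 0.8, batch 16, 300 epochs); desk-scale runs override `epochs`
#' and `batch_size`.
#'
#' @param learning_rate,batch_size,epochs,momentum Optimizer settings.
#' @param seed Integer seed controlling all training randomness.
#' @return A list with class `trainConfig`.
#' @export
trainConfig <- function(learning_rate = 0.01, batch_size = 16L,
                        epochs = 300L, momentum = 0.8, seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1,
            momentum >= 0, momentum < 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), momentum = momentum,
                 seed = as.integer(seed)),
            class = "trainConfig")
}

#' Build the detection network
#'
#' @param cfg A [detectorConfig()].
#' @return A network module (environment) usable with [detectorForward()],
#'   [trainDetector()] and [predictBoxes()].
#' @export
buildDetector <- function(cfg) {
  w <- cfg$widths; nb <- cfg$n_blocks; k <- cfg$k
  bb <- function(ic, oc) {
    if (cfg$use_strip) c3k2Strip(ic, oc, n_blocks = nb, k = k)
    else c3k2Plain(ic, oc, n_blocks = nb)
  }
  nk <- function(ic, oc) {
    if (cfg$use_caa) c3k2Caa(ic, oc, n_units = nb, k = k)
    else c3k2Plain(ic, oc, n_blocks = nb)
  }
  head_ <- function(ch) nnSequential(nnConvBNAct(ch, ch, 3),
                                     nnConv2d(ch, 4L + cfg$n_classes, 1))
  net <- newModule("cwDetector",
    cfg = NULL,
    stem = nnConvBNAct(3L, w[1], 3, stride = 2),
    d1 = nnConvBNAct(w[1], w[2], 3, stride = 2), b1 = bb(w[2], w[2]),
    d2 = nnConvBNAct(w[2], w[3], 3, stride = 2), b2 = bb(w[3], w[3]),
    d3 = nnConvBNAct(w[3], w[4], 3, stride = 2), b3 = bb(w[4], w[4]),
    d4 = nnConvBNAct(w[4], w[5], 3, stride = 2), b4 = bb(w[5], w[5]),
    up1 = nnUpsample2(), n1 = nk(w[5] + w[4], w[4]),
    up2 = nnUpsample2(), n2 = nk(w[4] + w[3], w[3]),
    dA = nnConvBNAct(w[3], w[3], 3, stride = 2), n3 = nk(w[3] + w[4], w[4]),
    dB = nnConvBNAct(w[4], w[4], 3, stride = 2), n4 = nk(w[4] + w[5], w[5]),
    h3 = head_(w[3]), h4 = head_(w[4]), h5 = head_(w[5]))
  net$cfg <- cfg
  net
}

#' Forward pass of the detector
#'
#' @param net Network from [buildDetector()].
#' @param x Input batch, array (H, W, 3, N) in `[0, 1]`.
#' @param train Cache activations for a following backward pass.
#' @return List of three raw prediction arrays, one per stride, each
#'   (H/s, W/s, 4 + n_classes, N).
#' @export
detectorForward <- function(net, x, train = FALSE) {
  s <- nnForward(net$stem, x, train)
  s <- nnForward(net$b1, nnForward(net$d1, s, train), train)
  p3 <- nnForward(net$b2, nnForward(net$d2, s, train), train)
  p4 <- nnForward(net$b3, nnForward(net$d3, p3, train), train)
  p5 <- nnForward(net$b4, nnForward(net$d4, p4, train), train)
  u1 <- nnForward(net$up1, p5, train)
  n4 <- nnForward(net$n1, catChannels(list(u1, p4)), train)
  u2 <- nnForward(net$up2, n4, train)
  n3 <- nnForward(net$n2, catChannels(list(u2, p3)), train)
  a <- nnForward(net$dA, n3, train)
  n4b <- nnForward(net$n3, catChannels(list(a, n4)), train)
  b <- nnForward(net$dB, n4b, train)
  n5b <- nnForward(net$n4, catChannels(list(b, p5)), train)
  list(nnForward(net$h3, n3, train),
       nnForward(net$h4, n4b, train),
       nnForward(net$h5, n5b, train))
}

# Backward through the full graph; grads is a list of three arrays shaped
# like the head outputs.
detectorBackward <- function(net, grads) {
  w <- net$cfg$widths
  dn3 <- nnBackward(net$h3, grads[[1]])
  dn4b <- nnBackward(net$h4, grads[[2]])
  dn5b <- nnBackward(net$h5, grads[[3]])
  dc <- nnBackward(net$n4, dn5b)
  db_ <- sliceChannels(dc, 1L, w[4])
  dp5 <- sliceChannels(dc, w[4] + 1L, w[4] + w[5])
  dn4b <- dn4b + nnBackward(net$dB, db_)
  dc <- nnBackward(net$n3, dn4b)
  da <- sliceChannels(dc, 1L, w[3])
  dn4 <- sliceChannels(dc, w[3] + 1L, w[3] + w[4])
  dn3 <- dn3 + nnBackward(net$dA, da)
  dc <- nnBackward(net$n2, dn3)
  du2 <- sliceChannels(dc, 1L, w[4])
  dp3 <- sliceChannels(dc, w[4] + 1L, w[4] + w[3])
  dn4 <- dn4 + nnBackward(net$up2, du2)
  dc <- nnBackward(net$n1, dn4)
  du1 <- sliceChannels(dc, 1L, w[5])
  dp4 <- sliceChannels(dc, w[5] + 1L, w[5] + w[4])
  dp5 <- dp5 + nnBackward(net$up1, du1)
  dp4 <- dp4 + nnBackward(net$d4, nnBackward(net$b4, dp5))
  dp3 <- dp3 + nnBackward(net$d3, nnBackward(net$b3, dp4))
  ds <- nnBackward(net$d2, nnBackward(net$b2, dp3))
  nnBackward(net$stem, nnBackward(net$d1, nnBackward(net$b1, ds)))
}

# target assignment ---------------------------------------------------------

# Pick the pyramid level whose stride best matches the box scale.
bestLevel <- function(w, h, strides) {
  side <- sqrt(w * h)
  which.min(abs(log2(pmax(side, 1e-6) / (8 * strides))))
}

#' Assign ground-truth boxes to head cells
#'
#' @param truths List (length = batch) of box data.frames with `cx, cy, w,
#'   h, class_id` in input-frame pixels (may have zero rows).
#' @param cfg A [detectorConfig()].
#' @return List per level: data.frame with 0-based `cell_h`, `cell_w`,
#'   1-based image index `img`, `class_id`, and the target box fields.
#' @export
assignTargets <- function(truths, cfg) {
  size <- cfg$input_size
  out <- lapply(cfg$strides, function(s) {
    data.frame(cell_h = integer(), cell_w = integer(), img = integer(),
               class_id = integer(), cx = numeric(), cy = numeric(),
               w = numeric(), h = numeric(), area = numeric())
  })
  for (n in seq_along(truths)) {
    tt <- truths[[n]]
    if (is.null(tt) || nrow(tt) == 0) next
    # clip to image bounds
    co <- boxCorners(tt)
    co$x1 <- pmax(0, co$x1); co$y1 <- pmax(0, co$y1)
    co$x2 <- pmin(size, co$x2); co$y2 <- pmin(size, co$y2)
    keep <- co$x2 - co$x1 > 1 & co$y2 - co$y1 > 1
    if (!any(keep)) next
    tt <- cbind(boxFromCorners(co$x1[keep], co$y1[keep], co$x2[keep], co$y2[keep]),
                class_id = tt$class_id[keep])
    for (i in seq_len(nrow(tt))) {
      lv <- bestLevel(tt$w[i], tt$h[i], cfg$strides)
      s <- cfg$strides[lv]
      g <- size %/% s
      # cells whose centers fall in the central half of the box
      jc <- floor(tt$cx[i] / s); ic <- floor(tt$cy[i] / s)
      js <- which((seq_len(g) - 0.5) * s >= tt$cx[i] - tt$w[i] / 4 &
                  (seq_len(g) - 0.5) * s <= tt$cx[i] + tt$w[i] / 4) - 1L
      is_ <- which((seq_len(g) - 0.5) * s >= tt$cy[i] - tt$h[i] / 4 &
                   (seq_len(g) - 0.5) * s <= tt$cy[i] + tt$h[i] / 4) - 1L
      cells <- expand.grid(cell_h = union(is_, min(max(ic, 0L), g - 1L)),
                           cell_w = union(js, min(max(jc, 0L), g - 1L)))
      add <- data.frame(cells, img = n, class_id = tt$class_id[i],
                        cx = tt$cx[i], cy = tt$cy[i], w = tt$w[i], h = tt$h[i],
                        area = tt$w[i] * tt$h[i])
      out[[lv]] <- rbind(out[[lv]], add)
    }
  }
  # a cell claimed by several boxes keeps the smallest one (finest signal)
  for (lv in seq_along(out)) {
    t_ <- out[[lv]]
    if (nrow(t_) == 0) next
    key <- paste(t_$img, t_$cell_h, t_$cell_w)
    t_ <- t_[order(t_$area), ]
    out[[lv]] <- t_[!duplicated(paste(t_$img, t_$cell_h, t_$cell_w)), ]
  }
  out
}

# decoding -------------------------------------------------------------------

softplus <- function(x) ifelse(x > 20, x, log1p(exp(x)))
dsoftplus <- function(x) 1 / (1 + exp(-x))

# Decode raw box channels (matrix n x 4, columns l/t/r/b) at given cells.
decodeBoxes <- function(raw, cell_h, cell_w, stride) {
  xc <- (cell_w + 0.5) * stride
  yc <- (cell_h + 0.5) * stride
  l <- softplus(raw[, 1]) * stride; t <- softplus(raw[, 2]) * stride
  r <- softplus(raw[, 3]) * stride; b <- softplus(raw[, 4]) * stride
  data.frame(x1 = xc - l, y1 = yc - t, x2 = xc + r, y2 = yc + b)
}

# loss ------------------------------------------------------------------------

#' Detection loss: classification BCE + SDIoU box regression
#'
#' Classification is binary cross-entropy with logits over every cell and
#' class (one-vs-all), normalized by the number of assigned cells; the box
#' component is the mean SDIoU loss (or plain 1 - IoU under the ablation
#' toggle) over assigned cells. When gradients are requested they are
#' returned as arrays shaped like the raw predictions.
#'
#' @param preds List of raw prediction arrays from [detectorForward()].
#' @param targets Assignment from [assignTargets()].
#' @param cfg A [detectorConfig()].
#' @param params An [sdiouParams()].
#' @param with_grad Also compute gradients.
#' @return List with `total`, `cls`, `box` scalars (and `grads` when
#'   requested).
#' @export
computeLoss <- function(preds, targets, cfg, params = sdiouParams(),
                        with_grad = FALSE) {
  nc <- cfg$n_classes
  n_pos <- sum(vapply(targets, nrow, numeric(1)))
  norm <- max(1, n_pos)
  cls_sum <- 0
  box_sum <- 0
  grads <- vector("list", length(preds))
  for (lv in seq_along(preds)) {
    p <- preds[[lv]]
    d <- dim(p)
    tgt <- array(0, dim = c(d[1], d[2], nc, d[4]))
    t_ <- targets[[lv]]
    if (nrow(t_) > 0) {
      idx <- cbind(t_$cell_h + 1L, t_$cell_w + 1L, t_$class_id + 1L, t_$img)
      tgt[idx] <- 1
    }
    z <- p[, , 4L + seq_len(nc), , drop = FALSE]
    cls_sum <- cls_sum + sum(pmax(z, 0) - z * tgt + log1p(exp(-abs(z))))
    if (with_grad) {
      g <- array(0, dim = d)
      g[, , 4L + seq_len(nc), ] <-
        cfg$cls_loss_weight * (1 / (1 + exp(-z)) - tgt) / norm
      grads[[lv]] <- g
    }
    if (nrow(t_) > 0) {
      s <- cfg$strides[lv]
      raw_idx <- lapply(1:4, function(ch)
        p[cbind(t_$cell_h + 1L, t_$cell_w + 1L, ch, t_$img)])
      raw <- do.call(cbind, raw_idx)
      dec <- decodeBoxes(raw, t_$cell_h, t_$cell_w, s)
      pb <- boxFromCorners(dec$x1, dec$y1, dec$x2, dec$y2)
      gt <- axisBox(t_$cx, t_$cy, t_$w, t_$h)
      li <- if (cfg$use_sdiou) sdiouLoss(pb, gt, params) else 1 - boxIoU(pb, gt)
      box_sum <- box_sum + sum(li)
      if (with_grad) {
        gb <- if (cfg$use_sdiou) sdiouGrad(pb, gt, params)
              else iouLossGrad(pb, gt)
        # chain center/size -> corners -> l/t/r/b -> raw
        dx1 <- 0.5 * gb[, "cx"] - gb[, "w"]
        dx2 <- 0.5 * gb[, "cx"] + gb[, "w"]
        dy1 <- 0.5 * gb[, "cy"] - gb[, "h"]
        dy2 <- 0.5 * gb[, "cy"] + gb[, "h"]
        dl <- -dx1; dt <- -dy1; dr <- dx2; db_ <- dy2
        scale <- cfg$box_loss_weight / norm * s
        draw <- cbind(dl, dt, dr, db_) * dsoftplus(raw) * scale
        for (ch in 1:4) {
          idx4 <- cbind(t_$cell_h + 1L, t_$cell_w + 1L, ch, t_$img)
          grads[[lv]][idx4] <- grads[[lv]][idx4] + draw[, ch]
        }
      }
    }
  }
  cls <- cfg$cls_loss_weight * cls_sum / norm
  box <- cfg$box_loss_weight * box_sum / norm
  out <- list(total = cls + box, cls = cls, box = box, n_pos = n_pos)
  if (with_grad) out$grads <- grads
  out
}

# numeric gradient of the plain 1 - IoU loss (ablation comparator)
iouLossGrad <- function(b1, b2, eps = 1e-4) {
  g <- matrix(0, nrow(b1), 4, dimnames = list(NULL, c("cx", "cy", "w", "h")))
  scale <- pmax(pmax(b1$w, b1$h), 1)
  for (j in 1:4) {
    h <- eps * scale
    up <- b1; dn <- b1
    up[[j]] <- up[[j]] + h; dn[[j]] <- dn[[j]] - h
    if (j >= 3) dn[[j]] <- pmax(dn[[j]], 1e-6)
    g[, j] <- ((1 - boxIoU(up, b2)) - (1 - boxIoU(dn, b2))) / (up[[j]] - dn[[j]])
  }
  g
}

# prediction -------------------------------------------------------------------

#' Letterbox an image to a square network input
#'
#' Preserves aspect ratio, pads with mid-gray, nearest-neighbour resampling.
#'
#' @param img Array (H, W, 3) in `[0, 1]`.
#' @param size Target side length.
#' @return List with `image`, `scale`, `pad_x`, `pad_y`.
#' @export
letterboxImage <- function(img, size) {
  h <- dim(img)[1]; w <- dim(img)[2]
  scale <- min(size / w, size / h)
  nw <- max(1L, as.integer(round(w * scale)))
  nh <- max(1L, as.integer(round(h * scale)))
  ri <- pmin(h, pmax(1L, ceiling((seq_len(nh) - 0.5) / scale)))
  ci <- pmin(w, pmax(1L, ceiling((seq_len(nw) - 0.5) / scale)))
  resized <- img[ri, ci, , drop = FALSE]
  out <- array(0.5, dim = c(size, size, 3))
  pad_y <- (size - nh) %/% 2L
  pad_x <- (size - nw) %/% 2L
  out[pad_y + seq_len(nh), pad_x + seq_len(nw), ] <- resized
  list(image = out, scale = scale, pad_x = pad_x, pad_y = pad_y)
}

# greedy class-wise non-maximum suppression; returns kept row indices
nmsKeep <- function(boxes, scores, iou_thr) {
  ord <- order(scores, decreasing = TRUE)
  keep <- integer()
  while (length(ord) > 0) {
    i <- ord[1]
    keep <- c(keep, i)
    ord <- ord[-1]
    if (length(ord) == 0) break
    ious <- boxIoU(boxes[rep(i, length(ord)), , drop = FALSE],
                   boxes[ord, , drop = FALSE])
    ord <- ord[ious <= iou_thr]
  }
  keep
}

#' Run the detector on one image
#'
#' Letterboxes the image, decodes every cell, filters by confidence,
#' applies class-wise NMS and maps boxes back to the original frame.
#'
#' @param net Network from [buildDetector()] (evaluation mode is used).
#' @param img Array (H, W, 3) in `[0, 1]`.
#' @param cfg The detector configuration (defaults to `net$cfg`).
#' @param conf_threshold,nms_iou_threshold Optional overrides.
#' @return A detection data.frame (`cx, cy, w, h, class_id, confidence`),
#'   possibly with zero rows, clipped to the image bounds.
#' @export
predictBoxes <- function(net, img, cfg = net$cfg,
                         conf_threshold = cfg$conf_threshold,
                         nms_iou_threshold = cfg$nms_iou_threshold) {
  lb <- letterboxImage(img, cfg$input_size)
  x <- array(lb$image, dim = c(dim(lb$image), 1L))
  preds <- detectorForward(net, x, train = FALSE)
  dets <- decodePredictions(preds, cfg, conf_threshold, nms_iou_threshold)
  if (nrow(dets) == 0) return(dets)
  # back to original frame
  co <- boxCorners(dets)
  co$x1 <- (co$x1 - lb$pad_x) / lb$scale; co$x2 <- (co$x2 - lb$pad_x) / lb$scale
  co$y1 <- (co$y1 - lb$pad_y) / lb$scale; co$y2 <- (co$y2 - lb$pad_y) / lb$scale
  h <- dim(img)[1]; w <- dim(img)[2]
  co$x1 <- pmax(0, pmin(w, co$x1)); co$x2 <- pmax(0, pmin(w, co$x2))
  co$y1 <- pmax(0, pmin(h, co$y1)); co$y2 <- pmax(0, pmin(h, co$y2))
  ok <- co$x2 - co$x1 > 0.5 & co$y2 - co$y1 > 0.5
  if (!any(ok)) return(dets[integer(), ])
  out <- boxFromCorners(co$x1[ok], co$y1[ok], co$x2[ok], co$y2[ok])
  out$class_id <- dets$class_id[ok]
  out$confidence <- dets$confidence[ok]
  out
}

# decode raw head outputs (single image in batch slot 1) to detections in
# the network input frame
decodePredictions <- function(preds, cfg, conf_threshold, nms_iou_threshold) {
  nc <- cfg$n_classes
  all <- list()
  for (lv in seq_along(preds)) {
    p <- preds[[lv]]
    d <- dim(p)
    s <- cfg$strides[lv]
    prob <- 1 / (1 + exp(-p[, , 4L + seq_len(nc), 1, drop = FALSE]))
    for (cl in seq_len(nc)) {
      pc <- prob[, , cl, 1]
      hit <- which(pc >= conf_threshold, arr.ind = TRUE)
      if (length(hit) == 0) next
      hit <- matrix(hit, ncol = 2)
      raw <- vapply(1:4, function(ch) p[cbind(hit, ch, 1L)], numeric(nrow(hit)))
      raw <- matrix(raw, ncol = 4)
      dec <- decodeBoxes(raw, hit[, 1] - 1L, hit[, 2] - 1L, s)
      b <- boxFromCorners(dec$x1, dec$y1, dec$x2, dec$y2)
      b$class_id <- cl - 1L
      b$confidence <- pc[hit]
      all[[length(all) + 1L]] <- b
    }
  }
  if (length(all) == 0)
    return(data.frame(cx = numeric(), cy = numeric(), w = numeric(),
                      h = numeric(), class_id = integer(),
                      confidence = numeric()))
  dets <- do.call(rbind, all)
  kept <- list()
  for (cl in unique(dets$class_id)) {
    sub <- dets[dets$class_id == cl, , drop = FALSE]
    kept[[length(kept) + 1L]] <-
      sub[nmsKeep(sub, sub$confidence, nms_iou_threshold), , drop = FALSE]
  }
  out <- do.call(rbind, kept)
  out[order(out$confidence, decreasing = TRUE), , drop = FALSE]
}

# training ---------------------------------------------------------------------

#' Train the detector on in-memory scenes
#'
#' Scenes are lists with `image` (H, W, 3 array, the network input size) and
#' `truths` (box data.frame with `class_id`). SGD with momentum and cosine
#' learning-rate decay; loss components are logged per epoch.
#'
#' @param net Network from [buildDetector()].
#' @param scenes Training scenes.
#' @param train_cfg A [trainConfig()].
#' @param params An [sdiouParams()].
#' @param val_scenes Optional held-out scenes; mAP@0.5 is computed at the
#'   end of training when supplied.
#' @param verbose Print per-epoch losses.
#' @return Invisibly, a list with the per-epoch loss log (`history`) and
#'   final `val_map` (NA when no validation scenes given).
#' @export
trainDetector <- function(net, scenes, train_cfg = trainConfig(),
                          params = sdiouParams(), val_scenes = NULL,
                          verbose = FALSE) {
  cfg <- net$cfg
  set.seed(train_cfg$seed)
  nsc <- length(scenes)
  bs <- min(train_cfg$batch_size, nsc)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        cls = numeric(), box = numeric())
  for (ep in seq_len(train_cfg$epochs)) {
    lr <- train_cfg$learning_rate *
      (0.5 * (1 + cos(pi * (ep - 1) / max(1, train_cfg$epochs))) * 0.9 + 0.1)
    ord <- sample.int(nsc)
    tot <- c(loss = 0, cls = 0, box = 0); nb <- 0
    for (at in seq(1, nsc, by = bs)) {
      idx <- ord[at:min(at + bs - 1, nsc)]
      x <- array(0, dim = c(cfg$input_size, cfg$input_size, 3, length(idx)))
      truths <- vector("list", length(idx))
      for (i in seq_along(idx)) {
        x[, , , i] <- scenes[[idx[i]]]$image
        truths[[i]] <- scenes[[idx[i]]]$truths
      }
      preds <- detectorForward(net, x, train = TRUE)
      tg <- assignTargets(truths, cfg)
      ls <- computeLoss(preds, tg, cfg, params, with_grad = TRUE)
      zeroGrads(net)
      detectorBackward(net, ls$grads)
      sgdStep(net, lr, train_cfg$momentum)
      tot <- tot + c(ls$total, ls$cls, ls$box); nb <- nb + 1
    }
    history <- rbind(history, data.frame(epoch = ep, loss = tot[1] / nb,
                                         cls = tot[2] / nb, box = tot[3] / nb))
    if (verbose)
      message(sprintf("epoch %3d  lr %.4f  loss %.4f (cls %.4f box %.4f)",
                      ep, lr, tot[1] / nb, tot[2] / nb, tot[3] / nb))
  }
  val_map <- NA_real_
  if (!is.null(val_scenes)) val_map <- evaluateScenes(net, val_scenes)$map
  invisible(list(history = history, val_map = val_map))
}

# checkpointing -----------------------------------------------------------------

CHECKPOINT_VERSION <- 1L

#' Save / load detector checkpoints
#'
#' A checkpoint is a single serialized file holding the format version, the
#' detector configuration and the full parameter/buffer state.
#'
#' @param net Network to save.
#' @param path File path.
#' @export
saveCheckpoint <- function(net, path) {
  saveRDS(list(version = CHECKPOINT_VERSION, cfg = net$cfg,
               state = moduleState(net)), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @return `loadCheckpoint()` returns the rebuilt network.
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  stopifnot(identical(ck$version, CHECKPOINT_VERSION))
  net <- buildDetector(ck$cfg)
  loadModuleState(net, ck$state)
  net
}
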