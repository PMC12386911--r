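# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: straight-line transcriptions, pixel counting and
# exhaustive enumeration only.

# IoU by counting unit cells on the integer grid (boxes with integer corners)
rasterIoU <- function(c1, c2) {
  # c = c(x1, y1, x2, y2), integers
  cells <- function(cc) {
    if (cc[3] <= cc[1] || cc[4] <= cc[2]) return(matrix(numeric(), ncol = 2))
    as.matrix(expand.grid(x = cc[1]:(cc[3] - 1), y = cc[2]:(cc[4] - 1)))
  }
  k1 <- cells(c1); k2 <- cells(c2)
  key <- function(m) paste(m[, 1], m[, 2])
  inter <- length(intersect(key(k1), key(k2)))
  uni <- length(union(key(k1), key(k2)))
  list(iou = inter / uni, union = uni)
}

# straight-line evaluation of the SDIoU definition (IoU, v, alpha, beta,
# center-distance term), independent of the package implementation
sdiouOracle <- function(b1, b2, delta = 0.5, smax = 8100) {
  c1 <- c(b1[1] - b1[3] / 2, b1[2] - b1[4] / 2, b1[1] + b1[3] / 2, b1[2] + b1[4] / 2)
  c2 <- c(b2[1] - b2[3] / 2, b2[2] - b2[4] / 2, b2[1] + b2[3] / 2, b2[2] + b2[4] / 2)
  iw <- max(0, min(c1[3], c2[3]) - max(c1[1], c2[1]))
  ih <- max(0, min(c1[4], c2[4]) - max(c1[2], c2[2]))
  inter <- iw * ih
  iou <- inter / (b1[3] * b1[4] + b2[3] * b2[4] - inter)
  v <- 4 / pi^2 * (atan(b2[3] / b2[4]) - atan(b1[3] / b1[4]))^2
  alpha <- if (v == 0) 0 else v / (1 - iou + v)
  beta <- delta * (1 - log(1 + b2[3] * b2[4]) / log(1 + smax))
  beta <- min(max(beta, 0), delta)
  rho2 <- (b1[1] - b2[1])^2 + (b1[2] - b2[2])^2
  ew <- max(c1[3], c2[3]) - min(c1[1], c2[1])
  eh <- max(c1[4], c2[4]) - min(c1[2], c2[2])
  (delta - beta) + (1 - delta + beta) * iou - alpha * v -
    (1 + delta - beta) * rho2 / (ew^2 + eh^2)
}

# brute-force all-points AP: for every recall level, scan for the maximum
# precision at recall >= r (no cummax shortcut)
bruteAP <- function(tp, n_truth) {
  if (length(tp) == 0 || n_truth == 0) return(0)
  rec <- cumsum(tp) / n_truth
  prec <- cumsum(tp) / seq_along(tp)
  ap <- 0
  prev_r <- 0
  for (i in seq_along(tp)) {
    p_env <- max(prec[i:length(prec)])
    ap <- ap + (rec[i] - prev_r) * p_env
    prev_r <- rec[i]
  }
  ap
}

# exhaustive detection-truth matching maximizing the TP count over all
# admissible injective assignments (same class, IoU >= thr)
bruteForceTP <- function(dets, truths, iou_thr = 0.5) {
  if (nrow(dets) == 0 || nrow(truths) == 0) return(0)
  adm <- matrix(FALSE, nrow(dets), nrow(truths))
  for (i in seq_len(nrow(dets)))
    for (j in seq_len(nrow(truths)))
      if (dets$class_id[i] == truths$class_id[j])
        adm[i, j] <- boxIoU(dets[i, ], truths[j, ]) >= iou_thr
  best <- 0
  recurse <- function(i, used, tp) {
    if (tp + (nrow(dets) - i + 1) <= best) return()
    if (i > nrow(dets)) { best <<- max(best, tp); return() }
    for (j in which(adm[i, ] & !used)) {
      used[j] <- TRUE
      recurse(i + 1, used, tp + 1)
      used[j] <- FALSE
    }
    recurse(i + 1, used, tp)
  }
  recurse(1, rep(FALSE, nrow(truths)), 0)
  best
}

# naive direct 2-d convolution (single channel, zero padding), for the
# separability oracle
naiveConv2d <- function(x, kern, pad_t, pad_l) {
  H <- nrow(x); W <- ncol(x); kh <- nrow(kern); kw <- ncol(kern)
  out <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    s <- 0
    for (a in 1:kh) for (b in 1:kw) {
      ii <- i - pad_t + a - 1; jj <- j - pad_l + b - 1
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        s <- s + x[ii, jj] * kern[a, b]
    }
    out[i, j] <- s
  }
  out
}

# random valid boxes for property sweeps
randomBoxes <- function(n, lim = 200, min_side = 1, max_side = 80) {
  w <- runif(n, min_side, max_side)
  h <- runif(n, min_side, max_side)
  axisBox(runif(n, 0, lim), runif(n, 0, lim), w, h)
}

# small mixed ortho/oblique scene sets for detector tests
makeScenes <- function(n, seed0, image_size = 128L) {
  lapply(seq_len(n), function(i) {
    cfg <- sceneConfig(image_size, if (i %% 2 == 0) "oblique" else "ortho")
    sc <- renderScene(cfg, seed0 + i)
    list(image = sceneImage(sc), truths = sceneTruths(sc))
  })
}
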