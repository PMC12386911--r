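# Detector assembly, target assignment, loss, decoding and checkpoints.

tinyCfg <- function(...) detectorConfig(input_size = 64L,
                                        width_multiple = 0.5, ...)

test_that("the default detector emits three pyramid levels at 640", {
  set.seed(1)
  cfg <- detectorConfig()
  net <- buildDetector(cfg)
  x <- array(runif(640 * 640 * 3), dim = c(640, 640, 3, 1))
  p <- detectorForward(net, x)
  expect_equal(dim(p[[1]])[1:2], c(80, 80))
  expect_equal(dim(p[[2]])[1:2], c(40, 40))
  expect_equal(dim(p[[3]])[1:2], c(20, 20))
  expect_equal(dim(p[[1]])[3], 4 + cfg$n_classes)
})

test_that("width scaling strictly reduces the parameter count", {
  set.seed(2)
  full <- crownwatch:::nParameters(buildDetector(detectorConfig(input_size = 64)))
  half <- crownwatch:::nParameters(
    buildDetector(detectorConfig(input_size = 64, width_multiple = 0.5)))
  expect_lt(half, full)
  expect_error(detectorConfig(input_size = 100), "input_size")
})

test_that("evaluation-mode forward is deterministic", {
  set.seed(3)
  net <- buildDetector(tinyCfg())
  x <- array(runif(64 * 64 * 3), dim = c(64, 64, 3, 1))
  expect_identical(detectorForward(net, x), detectorForward(net, x))
})

test_that("target assignment covers center cells at the matching stride", {
  cfg <- detectorConfig(input_size = 640)
  tg <- assignTargets(list(data.frame(cx = 320, cy = 320, w = 64, h = 64,
                                      class_id = 0L)), cfg)
  expect_gte(nrow(tg[[1]]), 1)           # 64 px box lands on stride 8
  expect_equal(nrow(tg[[2]]), 0)
  expect_equal(tg[[1]]$class_id[1], 0L)
  empty <- assignTargets(list(data.frame(cx = numeric(), cy = numeric(),
                                         w = numeric(), h = numeric(),
                                         class_id = integer())), cfg)
  expect_true(all(vapply(empty, nrow, numeric(1)) == 0))
})

test_that("disjoint boxes claim disjoint cell sets", {
  cfg <- detectorConfig(input_size = 640)
  tg <- assignTargets(list(data.frame(cx = c(100, 500), cy = c(100, 500),
                                      w = 60, h = 60, class_id = c(0L, 1L))),
                      cfg)
  cells <- tg[[1]]
  a <- cells[cells$class_id == 0, c("cell_h", "cell_w")]
  b <- cells[cells$class_id == 1, c("cell_h", "cell_w")]
  expect_gt(nrow(a), 0); expect_gt(nrow(b), 0)
  expect_equal(nrow(merge(a, b)), 0)
  # oracle: every claimed cell center lies inside its box's central region
  for (i in seq_len(nrow(cells))) {
    cxc <- (cells$cell_w[i] + 0.5) * 8
    cyc <- (cells$cell_h[i] + 0.5) * 8
    expect_lte(abs(cxc - cells$cx[i]), cells$w[i] / 4 + 8)
    expect_lte(abs(cyc - cells$cy[i]), cells$h[i] / 4 + 8)
  }
})

test_that("loss vanishes on exact predictions and scales linearly", {
  cfg <- tinyCfg()
  truths <- list(data.frame(cx = 32, cy = 32, w = 20, h = 24, class_id = 0L))
  tg <- assignTargets(truths, cfg)
  # build raw predictions that decode exactly to the target at every
  # assigned cell, with saturated correct class scores
  preds <- lapply(seq_along(cfg$strides), function(lv) {
    s <- cfg$strides[lv]
    g <- cfg$input_size %/% s
    p <- array(0, dim = c(g, g, 4 + cfg$n_classes, 1))
    p[, , 5, ] <- -40
    p[, , 6, ] <- -40
    t_ <- tg[[lv]]
    for (i in seq_len(nrow(t_))) {
      xc <- (t_$cell_w[i] + 0.5) * s; yc <- (t_$cell_h[i] + 0.5) * s
      dist <- c(xc - (t_$cx[i] - t_$w[i] / 2), yc - (t_$cy[i] - t_$h[i] / 2),
                (t_$cx[i] + t_$w[i] / 2) - xc, (t_$cy[i] + t_$h[i] / 2) - yc)
      raw <- log(expm1(dist / s))
      for (ch in 1:4) p[t_$cell_h[i] + 1, t_$cell_w[i] + 1, ch, 1] <- raw[ch]
      p[t_$cell_h[i] + 1, t_$cell_w[i] + 1, 5 + t_$class_id[i], 1] <- 40
    }
    p
  })
  ls <- computeLoss(preds, tg, cfg)
  expect_lt(ls$box, 1e-8)
  expect_lt(ls$cls, 1e-8)
  cfg2 <- tinyCfg(box_loss_weight = 15)
  preds2 <- lapply(preds, function(p) { p[, , 1:4, ] <- 0.3; p })
  l1 <- computeLoss(preds2, tg, tinyCfg())
  l2 <- computeLoss(preds2, tg, cfg2)
  expect_equal(l2$box, 2 * l1$box, tolerance = 1e-9)
})

test_that("no assigned cells gives a classification-only loss", {
  cfg <- tinyCfg()
  tg <- assignTargets(list(crownwatch:::emptyDetections()[, 1:4] |>
                             cbind(class_id = integer())), cfg)
  preds <- lapply(cfg$strides, function(s) {
    g <- cfg$input_size %/% s
    array(rnorm(g * g * (4 + cfg$n_classes)), dim = c(g, g, 6, 1))
  })
  ls <- computeLoss(preds, tg, cfg)
  expect_equal(ls$box, 0)
  expect_gt(ls$cls, 0)
})

test_that("loss gradients agree with finite differences at assigned cells", {
  set.seed(5)
  cfg <- tinyCfg()
  truths <- list(data.frame(cx = c(20, 44), cy = c(20, 44), w = c(14, 10),
                            h = c(12, 16), class_id = c(0L, 1L)))
  tg <- assignTargets(truths, cfg)
  preds <- lapply(cfg$strides, function(s) {
    g <- cfg$input_size %/% s
    array(rnorm(g * g * 6, sd = 0.5), dim = c(g, g, 6, 1))
  })
  ls <- computeLoss(preds, tg, cfg, with_grad = TRUE)
  for (lv in 1:3) {
    t_ <- tg[[lv]]
    if (nrow(t_) == 0) next
    for (pick in seq_len(min(3, nrow(t_)))) {
      for (ch in c(1, 3, 5)) {
        idx <- c(t_$cell_h[pick] + 1, t_$cell_w[pick] + 1, ch, 1)
        eps <- 1e-5
        pp <- preds; pp[[lv]][idx[1], idx[2], idx[3], 1] <-
          pp[[lv]][idx[1], idx[2], idx[3], 1] + eps
        pm <- preds; pm[[lv]][idx[1], idx[2], idx[3], 1] <-
          pm[[lv]][idx[1], idx[2], idx[3], 1] - eps
        want <- (computeLoss(pp, tg, cfg)$total -
                 computeLoss(pm, tg, cfg)$total) / (2 * eps)
        got <- ls$grads[[lv]][idx[1], idx[2], idx[3], 1]
        expect_equal(got, want, tolerance = 1e-3)
      }
    }
  }
})

test_that("one optimizer step moves every parameter group", {
  set.seed(6)
  cfg <- tinyCfg()
  net <- buildDetector(cfg)
  scenes <- makeScenes(2, 40, image_size = 64L)
  x <- array(0, dim = c(64, 64, 3, 2))
  for (i in 1:2) x[, , , i] <- scenes[[i]]$image
  preds <- detectorForward(net, x, train = TRUE)
  tg <- assignTargets(lapply(scenes, `[[`, "truths"), cfg)
  ls <- computeLoss(preds, tg, cfg, with_grad = TRUE)
  crownwatch:::zeroGrads(net)
  crownwatch:::detectorBackward(net, ls$grads)
  before <- lapply(crownwatch:::nnParams(net), function(p) p$value)
  crownwatch:::sgdStep(net, 0.05)
  after <- lapply(crownwatch:::nnParams(net), function(p) p$value)
  moved <- mapply(function(a, b) max(abs(a - b)) > 0, before, after)
  expect_true(all(moved))
})

test_that("decoding respects thresholds, suppression and the letterbox", {
  set.seed(7)
  net <- buildDetector(tinyCfg())
  img <- makeScenes(1, 90, image_size = 64L)[[1]]$image
  expect_equal(nrow(predictBoxes(net, img, conf_threshold = 1.0)), 0)
  # two identical boxes: suppression keeps one
  b <- data.frame(cx = c(30, 30), cy = c(30, 30), w = c(10, 10),
                  h = c(10, 10))
  keep <- crownwatch:::nmsKeep(b, c(0.9, 0.8), 0.45)
  expect_equal(keep, 1L)
  # letterbox round trip within a pixel
  img_rect <- array(runif(100 * 60 * 3), dim = c(60, 100, 3))
  lb <- letterboxImage(img_rect, 64)
  box <- axisBox(50, 30, 40, 20)
  fwd <- data.frame(cx = box$cx * lb$scale + lb$pad_x,
                    cy = box$cy * lb$scale + lb$pad_y,
                    w = box$w * lb$scale, h = box$h * lb$scale)
  back <- data.frame(cx = (fwd$cx - lb$pad_x) / lb$scale,
                     cy = (fwd$cy - lb$pad_y) / lb$scale,
                     w = fwd$w / lb$scale, h = fwd$h / lb$scale)
  expect_lt(max(abs(unlist(back - box))), 1)
})

test_that("checkpoints round-trip the network exactly", {
  set.seed(8)
  net <- buildDetector(tinyCfg())
  img <- makeScenes(1, 91, image_size = 64L)[[1]]$image
  f <- tempfile(fileext = ".rds")
  saveCheckpoint(net, f)
  net2 <- loadCheckpoint(f)
  expect_equal(predictBoxes(net, img, conf_threshold = 0.1),
               predictBoxes(net2, img, conf_threshold = 0.1))
  expect_equal(net2$cfg$width_multiple, 0.5)
})

test_that("ablation toggles produce buildable distinct variants", {
  set.seed(9)
  combos <- expand.grid(strip = c(TRUE, FALSE), caa = c(TRUE, FALSE),
                        sd = c(TRUE, FALSE))
  x <- array(runif(64 * 64 * 3), dim = c(64, 64, 3, 1))
  for (i in seq_len(nrow(combos))) {
    cfg <- tinyCfg(use_strip = combos$strip[i], use_caa = combos$caa[i],
                   use_sdiou = combos$sd[i])
    net <- buildDetector(cfg)
    p <- detectorForward(net, x)
    expect_equal(dim(p[[1]])[1:2], c(8, 8))
  }
  with_strip <- buildDetector(tinyCfg(use_strip = TRUE))
  without <- buildDetector(tinyCfg(use_strip = FALSE))
  expect_false(crownwatch:::nParameters(with_strip) ==
               crownwatch:::nParameters(without))
})

test_that("training reduces the loss on a small synthetic set", {
  set.seed(10)
  cfg <- tinyCfg()
  net <- buildDetector(cfg)
  scenes <- makeScenes(12, 300, image_size = 64L)
  res <- trainDetector(net, scenes,
                       trainConfig(batch_size = 6, epochs = 5, seed = 2))
  h <- res$history
  expect_lt(h$loss[nrow(h)], h$loss[1])
  expect_lt(h$box[nrow(h)], h$box[1])
})
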