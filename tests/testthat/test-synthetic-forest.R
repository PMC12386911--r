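# Synthetic UAV forest scene generator.

test_that("scenes are bit-identical per (config, seed)", {
  cfg <- sceneConfig(96, "ortho")
  a <- renderScene(cfg, 5)
  b <- renderScene(cfg, 5)
  expect_identical(sceneImage(a), sceneImage(b))
  expect_identical(sceneTruths(a), sceneTruths(b))
  c_ <- renderScene(cfg, 6)
  expect_false(identical(sceneImage(a), sceneImage(c_)))
})

test_that("an all-healthy stand produces zero annotations", {
  cfg <- sceneConfig(96, "ortho",
                     class_mix = c(healthy = 1, weak = 0, dead = 0))
  expect_equal(nrow(sceneTruths(renderScene(cfg, 3))), 0)
})

test_that("a zero occlusion budget yields disjoint crowns", {
  cfg <- sceneConfig(128, "ortho", n_trees = c(5L, 7L),
                     occlusion_max_fraction = 0)
  for (s in 1:5) {
    tr <- sceneMetadata(renderScene(cfg, s))$trees
    b <- axisBox(tr$cx, tr$cy, tr$w, tr$h)
    for (i in seq_len(nrow(b) - 1))
      for (j in (i + 1):nrow(b))
        expect_equal(boxIoU(b[i, ], b[j, ]), 0)
  }
})

test_that("an impossible packing raises a generation error", {
  cfg <- sceneConfig(64, "ortho", n_trees = c(150L, 150L),
                     occlusion_max_fraction = 0)
  expect_error(renderScene(cfg, 1), "generation error")
})

test_that("ortho annotations respect the size cap and view statistics", {
  cap <- 90 * 128 / 640
  ratios_o <- c(); ratios_q <- c()
  for (s in 1:50) {
    to <- sceneTruths(renderScene(sceneConfig(128, "ortho"), 200 + s))
    tq <- sceneTruths(renderScene(sceneConfig(128, "oblique"), 500 + s))
    if (nrow(to)) {
      expect_true(all(pmax(to$w, to$h) <= cap + 1e-9))
      ratios_o <- c(ratios_o, to$h / to$w)
    }
    if (nrow(tq)) ratios_q <- c(ratios_q, tq$h / tq$w)
  }
  expect_gt(length(ratios_o), 100)
  expect_gt(length(ratios_q), 100)
  expect_lte(median(ratios_o), 1.25)
  expect_gte(median(ratios_q), 2)
})

test_that("annotation class frequencies track the configured mix", {
  cfg <- sceneConfig(96, "ortho",
                     class_mix = c(healthy = 0.4, weak = 0.35, dead = 0.25))
  n_weak <- 0; n_dead <- 0; n_trees <- 0
  for (s in 1:200) {
    sc <- renderScene(cfg, 3000 + s)
    tt <- sceneTruths(sc)
    n_weak <- n_weak + sum(tt$class_id == 0)
    n_dead <- n_dead + sum(tt$class_id == 1)
    n_trees <- n_trees + nrow(sceneMetadata(sc)$trees)
  }
  # visible-extent filtering can drop a few crowns, so compare against the
  # binomial expectation with a 20% band
  expect_lt(abs(n_weak / n_trees - 0.35), 0.35 * 0.2)
  expect_lt(abs(n_dead / n_trees - 0.25), 0.25 * 0.2)
})

test_that("generated datasets split 7:3 and regenerate identically", {
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  unlink(c(d1, d2), recursive = TRUE)
  cfg <- sceneConfig(64, "ortho", n_trees = c(3L, 5L))
  generateDataset(cfg, 10, d1, seed = 7)
  generateDataset(cfg, 10, d2, seed = 7)
  expect_length(readLines(file.path(d1, "train.txt")), 7)
  expect_length(readLines(file.path(d1, "val.txt")), 3)
  for (f in list.files(file.path(d1, "labels")))
    expect_identical(readLines(file.path(d1, "labels", f)),
                     readLines(file.path(d2, "labels", f)))
  man <- yaml::read_yaml(file.path(d1, "manifest.yaml"))
  expect_equal(man$n_images, 10)
  expect_length(man$image_seeds, 10)
})

test_that("emitted labels round trip through the dataset reader", {
  d <- file.path(tempdir(), "ds_rt")
  unlink(d, recursive = TRUE)
  cfg <- sceneConfig(96, "oblique", n_trees = c(4L, 6L))
  generateDataset(cfg, 4, d, seed = 11)
  for (i in 1:4) {
    stem <- sprintf("scene_%04d", i)
    sc <- renderScene(cfg, crownwatch:::deriveSeeds(11, 4)[i])
    back <- yoloToPixels(readYoloLabels(file.path(d, "labels",
                                                  paste0(stem, ".txt"))),
                         96, 96)
    tt <- sceneTruths(sc)
    expect_equal(nrow(back), nrow(tt))
    if (nrow(tt)) {
      expect_lt(max(abs(back$cx - tt$cx)), 0.5)
      expect_lt(max(abs(back$w - tt$w)), 0.5)
    }
    img <- readImagePNG(file.path(d, "images", paste0(stem, ".png")))
    expect_lt(max(abs(img - sceneImage(sc))), 1 / 255)
  }
})

test_that("perturbed truths behave as detections downstream", {
  set.seed(61)
  truth_list <- lapply(1:5, function(i)
    sceneTruths(renderScene(sceneConfig(128, "ortho"), 700 + i)))
  # zero noise, confidence 1: perfect detector
  clean <- lapply(seq_along(truth_list), function(i)
    perturbDetections(truth_list[[i]], jitter_sd = 0, fp_rate = 0,
                      conf_range = c(1, 1), image_size = 128, seed = i))
  expect_equal(mAP(evaluateDetections(clean, truth_list)), 1.0)
  # all boxes shifted off-image: nothing matches
  off <- lapply(clean, function(d) { d$cx <- d$cx + 1e4; d })
  expect_equal(mAP(evaluateDetections(off, truth_list)), 0)
})

test_that("jittered detection TP counts match a per-pair IoU check", {
  set.seed(62)
  for (i in 1:5) {
    tt <- sceneTruths(renderScene(sceneConfig(128, "ortho"), 800 + i))
    if (nrow(tt) == 0) next
    d <- perturbDetections(tt, jitter_sd = 0.15, fp_rate = 0,
                           image_size = 128, seed = i)
    m <- matchDetections(d, tt, 0.5)
    # truths are disjoint, so a jittered copy can only match its source:
    # the TP count is the number of copies with IoU >= 0.5 to that source
    want <- sum(vapply(seq_len(nrow(d)), function(j) {
      src <- tt[tt$class_id == d$class_id[j], , drop = FALSE]
      if (nrow(src) == 0) return(FALSE)
      any(boxIoU(d[rep(j, nrow(src)), ], src) >= 0.5)
    }, logical(1)))
    expect_equal(sum(m$counts$TP), want)
  }
})
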