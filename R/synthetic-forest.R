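# Seeded generator of UAV-style forest scenes.
#
# Scenes emulate low-altitude RGB capture over a woodwasp outbreak stand:
# crowded conifer crowns in three visual health classes on a cluttered
# green/brown ground texture. Two viewing regimes are modeled: nadir
# orthophoto (small, near-square crowns, largest annotated target capped at
# 90 px at the 640 px reference resolution) and oblique (tall crowns with a
# visible trunk, height/width ratios 2-5). Healthy crowns are rendered but
# never annotated — the published labeling scheme marks only Weak and Dead
# trees, so healthy canopy is background the detector must learn to ignore.
# Crown pixel sizes are specified at the 640 px reference and scale with
# image_size (constant ground-sampling fraction), so smaller desk-scale
# scenes keep the same scene statistics.

#' Scene generator configuration
#'
#' @param image_size Square scene side in px (default 640).
#' @param view_mode `"ortho"` (nadir) or `"oblique"`.
#' @param n_trees Integer range (min, max) of trees per scene.
#' @param class_mix Proportions (healthy, weak, dead); must sum to 1.
#' @param crown_size_range Crown size range in px at the 640 px reference:
#'   the larger box side in ortho mode, the crown width in oblique mode.
#' @param aspect_ratio_range Height/width range: near-square for ortho,
#'   elongated for oblique.
#' @param occlusion_max_fraction Maximum allowed pairwise overlap (area of
#'   intersection over the smaller crown box) when placing trees.
#' @param color_jitter Magnitude of per-tree palette jitter.
#' @param background_clutter Magnitude of ground texture/clutter.
#' @param seed Default seed used by [renderScene()] when none is passed.
#' @return A list with class `sceneConfig`.
#' @export
sceneConfig <- function(image_size = 640L,
                        view_mode = c("ortho", "oblique"),
                        n_trees = c(8L, 16L),
                        class_mix = c(healthy = 0.40, weak = 0.35, dead = 0.25),
                        crown_size_range = NULL,
                        aspect_ratio_range = NULL,
                        occlusion_max_fraction = 0.3,
                        color_jitter = 0.05,
                        background_clutter = 0.10,
                        seed = 1L) {
  view_mode <- match.arg(view_mode)
  stopifnot(image_size >= 32, abs(sum(class_mix) - 1) < 1e-9,
            length(n_trees) == 2, n_trees[1] >= 1, n_trees[2] >= n_trees[1],
            occlusion_max_fraction >= 0, occlusion_max_fraction < 1)
  if (is.null(crown_size_range))
    crown_size_range <- if (view_mode == "ortho") c(30, 90) else c(25, 60)
  if (is.null(aspect_ratio_range))
    aspect_ratio_range <- if (view_mode == "ortho") c(0.8, 1.25) else c(2, 5)
  structure(list(image_size = as.integer(image_size), view_mode = view_mode,
                 n_trees = as.integer(n_trees), class_mix = class_mix,
                 crown_size_range = crown_size_range,
                 aspect_ratio_range = aspect_ratio_range,
                 occlusion_max_fraction = occlusion_max_fraction,
                 color_jitter = color_jitter,
                 background_clutter = background_clutter,
                 seed = as.integer(seed)),
            class = "sceneConfig")
}

# fixed named crown palettes (RGB in [0,1]); jittered per tree
CROWN_PALETTE <- list(
  healthy = c(0.06, 0.26, 0.07),   # dense deep green
  weak    = c(0.46, 0.43, 0.11),   # yellowing, sparse
  dead    = c(0.42, 0.35, 0.27))   # bare gray-brown

TRUNK_COLOR <- c(0.30, 0.22, 0.15)

# smooth low-frequency noise field via bilinear interpolation of a coarse grid
smoothNoise <- function(h, w, gs = 8L) {
  g <- matrix(stats::rnorm((gs + 1) * (gs + 1)), gs + 1)
  ry <- seq(0, gs, length.out = h)
  rx <- seq(0, gs, length.out = w)
  iy <- pmin(floor(ry), gs - 1); fy <- ry - iy
  ix <- pmin(floor(rx), gs - 1); fx <- rx - ix
  a <- g[cbind(rep(iy + 1, w), rep(ix + 1, each = h))]
  b <- g[cbind(rep(iy + 2, w), rep(ix + 1, each = h))]
  c_ <- g[cbind(rep(iy + 1, w), rep(ix + 2, each = h))]
  d <- g[cbind(rep(iy + 2, w), rep(ix + 2, each = h))]
  fyv <- rep(fy, w); fxv <- rep(fx, each = h)
  matrix(a * (1 - fyv) * (1 - fxv) + b * fyv * (1 - fxv) +
         c_ * (1 - fyv) * fxv + d * fyv * fxv, h, w)
}

#' Render one synthetic forest scene
#'
#' Deterministic per `(cfg, seed)`: the same pair reproduces the image and
#' annotations bit for bit. Trees are placed by rejection sampling under
#' the occlusion budget and drawn back to front; annotations are the
#' bounding boxes of each Weak/Dead tree's *visible* pixels (amodal-free,
#' as an annotator boxes what is seen).
#'
#' @param cfg A [sceneConfig()].
#' @param seed Integer seed (defaults to `cfg$seed`).
#' @return A [ForestScene-class] object.
#' @export
renderScene <- function(cfg, seed = cfg$seed) {
  set.seed(seed)
  sz <- cfg$image_size
  scale <- sz / 640
  img <- renderBackground(sz, cfg$background_clutter)
  n <- if (cfg$n_trees[1] == cfg$n_trees[2]) cfg$n_trees[1] else
    sample(cfg$n_trees[1]:cfg$n_trees[2], 1)
  classes <- sample(c("healthy", "weak", "dead"), n, replace = TRUE,
                    prob = cfg$class_mix)
  trees <- placeTrees(n, cfg, scale)
  trees$class <- classes
  # draw back (small cy) to front (large cy) so closer crowns occlude
  ord <- order(trees$cy)
  owner <- matrix(0L, sz, sz)
  for (i in ord) {
    dr <- drawTree(img, owner, trees[i, ], i, cfg)
    img <- dr$img; owner <- dr$owner
  }
  truths <- visibleBoxes(owner, trees, sz)
  methods::new("ForestScene", image = img, truths = truths,
               metadata = list(seed = seed, view_mode = cfg$view_mode,
                               image_size = sz, trees = trees,
                               palette = CROWN_PALETTE))
}

renderBackground <- function(sz, clutter) {
  base <- c(0.20, 0.30, 0.15)
  low <- smoothNoise(sz, sz, 8L)
  fine <- matrix(stats::runif(sz * sz, -1, 1), sz)
  img <- array(0, dim = c(sz, sz, 3))
  tint <- smoothNoise(sz, sz, 4L)  # brown/green patchiness
  for (ch in 1:3) {
    img[, , ch] <- base[ch] + clutter * (0.6 * low + 0.25 * fine) +
      clutter * 0.5 * tint * (c(0.4, 0.1, -0.2)[ch])
  }
  pmin(pmax(img, 0), 1)
}

placeTrees <- function(n, cfg, scale) {
  sz <- cfg$image_size
  rng <- cfg$crown_size_range * scale
  out <- data.frame(cx = numeric(n), cy = numeric(n), w = numeric(n),
                    h = numeric(n), trunk = numeric(n))
  placed <- 0L
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try_ in 1:60) {
      ar <- stats::runif(1, cfg$aspect_ratio_range[1], cfg$aspect_ratio_range[2])
      if (cfg$view_mode == "ortho") {
        side <- stats::runif(1, rng[1], rng[2])
        if (ar >= 1) { h <- side; w <- side / ar } else { w <- side; h <- side * ar }
      } else {
        w <- stats::runif(1, rng[1], rng[2])
        h <- min(w * ar, 0.9 * sz)
      }
      trunk <- if (cfg$view_mode == "oblique") 0.22 * h else 0
      cx <- stats::runif(1, w / 2 + 1, sz - w / 2 - 1)
      cy <- stats::runif(1, h / 2 + 1, sz - h / 2 - 1)
      cand <- data.frame(cx = cx, cy = cy, w = w, h = h)
      if (placed == 0L) { ok <- TRUE; break }
      prev <- out[seq_len(placed), , drop = FALSE]
      ca <- boxCorners(cand); pa <- boxCorners(prev)
      iw <- pmax(0, pmin(ca$x2, pa$x2) - pmax(ca$x1, pa$x1))
      ih <- pmax(0, pmin(ca$y2, pa$y2) - pmax(ca$y1, pa$y1))
      ov <- iw * ih / pmin(cand$w * cand$h, prev$w * prev$h)
      if (all(ov <= cfg$occlusion_max_fraction)) { ok <- TRUE; break }
    }
    if (!ok)
      stop("generation error: cannot place ", n, " trees within the ",
           "occlusion budget ", cfg$occlusion_max_fraction)
    placed <- placed + 1L
    out[i, ] <- c(cx, cy, w, h, trunk)
  }
  out
}

# Draw one tree into the image; returns updated image and owner mask.
drawTree <- function(img, owner, tree, idx, cfg) {
  sz <- cfg$image_size
  col0 <- CROWN_PALETTE[[tree$class]]
  col <- pmin(pmax(col0 + stats::rnorm(3, sd = cfg$color_jitter), 0), 1)
  crown_h <- tree$h - tree$trunk
  cy_crown <- tree$cy - tree$trunk / 2
  r0 <- max(1L, floor(tree$cy - tree$h / 2)); r1 <- min(sz, ceiling(tree$cy + tree$h / 2))
  c0 <- max(1L, floor(tree$cx - tree$w / 2)); c1 <- min(sz, ceiling(tree$cx + tree$w / 2))
  if (r1 < r0 || c1 < c0) return(list(img = img, owner = owner))
  ys <- (r0:r1) - 0.5; xs <- (c0:c1) - 0.5
  dy <- outer(ys - cy_crown, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - tree$cx)
  d <- (dx / (tree$w / 2))^2 + (dy / (crown_h / 2))^2
  alpha <- ifelse(d < 1, sqrt(pmax(0, 1 - d)), 0)
  dens <- switch(tree$class, healthy = 1.0, weak = 0.78, dead = 0.60)
  alpha <- alpha * dens
  if (tree$class == "weak") {
    # thinned, dying top: attenuate the upper half of the crown
    topfrac <- (dy / (crown_h / 2) + 1) / 2   # 0 at top, 1 at bottom
    alpha <- alpha * (0.45 + 0.55 * pmin(pmax(topfrac, 0), 1))
  }
  if (tree$class == "dead") {
    # sparse bare branches: speckled coverage
    spk <- matrix(stats::runif(length(d)), nrow(d)) < 0.62
    alpha <- alpha * ifelse(spk, 1, 0.15)
  }
  # needle texture
  alpha <- alpha * (0.8 + 0.2 * matrix(stats::runif(length(d)), nrow(d)))
  for (ch in 1:3)
    img[r0:r1, c0:c1, ch] <- img[r0:r1, c0:c1, ch] * (1 - alpha) + col[ch] * alpha
  owner[r0:r1, c0:c1][alpha > 0.40] <- idx
  if (tree$trunk > 0) {
    tw <- max(2, 0.10 * tree$w)
    tr0 <- max(1L, floor(tree$cy + tree$h / 2 - tree$trunk))
    tr1 <- min(sz, ceiling(tree$cy + tree$h / 2))
    tc0 <- max(1L, floor(tree$cx - tw / 2)); tc1 <- min(sz, ceiling(tree$cx + tw / 2))
    if (tr1 >= tr0 && tc1 >= tc0) {
      for (ch in 1:3) img[tr0:tr1, tc0:tc1, ch] <- TRUNK_COLOR[ch]
      owner[tr0:tr1, tc0:tc1] <- idx
    }
  }
  list(img = img, owner = owner)
}

# bounding boxes of visible (topmost) pixels per annotated tree
visibleBoxes <- function(owner, trees, sz) {
  empty <- data.frame(cx = numeric(), cy = numeric(), w = numeric(),
                      h = numeric(), class_id = integer())
  rows <- list()
  for (i in seq_len(nrow(trees))) {
    cls <- trees$class[i]
    if (!cls %in% c("weak", "dead")) next
    hit <- which(owner == i, arr.ind = TRUE)
    if (nrow(hit) < 4) next
    y1 <- min(hit[, 1]) - 1; y2 <- max(hit[, 1])
    x1 <- min(hit[, 2]) - 1; x2 <- max(hit[, 2])
    if (x2 - x1 < 2 || y2 - y1 < 2) next
    rows[[length(rows) + 1L]] <-
      data.frame(cx = (x1 + x2) / 2, cy = (y1 + y2) / 2,
                 w = x2 - x1, h = y2 - y1,
                 class_id = if (cls == "weak") 0L else 1L)
  }
  if (length(rows)) do.call(rbind, rows) else empty
}

#' Generate a dataset of scenes on disk
#'
#' Writes `images/` (PNG), `labels/` (YOLO txt, normalized), `train.txt` /
#' `val.txt` stem lists from a seeded 7:3 shuffle, `classes.txt` and a
#' `manifest.yaml` recording the configuration and every per-image seed.
#'
#' @param cfg A [sceneConfig()] (or a list of configs cycled over, e.g. to
#'   mix ortho and oblique scenes).
#' @param n_images Number of scenes.
#' @param out_dir Output directory (created).
#' @param seed Master seed; per-image seeds are derived from it.
#' @param split_ratio Train fraction (default 0.7).
#' @return Invisibly, the manifest list.
#' @export
generateDataset <- function(cfg, n_images, out_dir, seed = 1L,
                            split_ratio = 0.7) {
  cfgs <- if (inherits(cfg, "sceneConfig")) list(cfg) else cfg
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "labels"), recursive = TRUE, showWarnings = FALSE)
  seeds <- deriveSeeds(seed, n_images)
  stems <- sprintf("scene_%04d", seq_len(n_images))
  for (i in seq_len(n_images)) {
    ci <- cfgs[[(i - 1L) %% length(cfgs) + 1L]]
    sc <- renderScene(ci, seeds[i])
    ok <- tryCatch({
      writeImagePNG(sceneImage(sc), file.path(out_dir, "images",
                                              paste0(stems[i], ".png")))
      writeYoloLabels(pixelsToYolo(sceneTruths(sc), ci$image_size,
                                   ci$image_size),
                      file.path(out_dir, "labels", paste0(stems[i], ".txt")))
      TRUE
    }, error = function(e) stop("I/O failure under ", out_dir, ": ",
                                conditionMessage(e)))
  }
  sp <- splitDataset(stems, split_ratio, seed)
  writeLines(sp$train, file.path(out_dir, "train.txt"))
  writeLines(sp$val, file.path(out_dir, "val.txt"))
  writeClassMap(defaultClassMap(), file.path(out_dir, "classes.txt"))
  manifest <- list(n_images = n_images, master_seed = seed,
                   split_ratio = split_ratio,
                   image_seeds = as.list(stats::setNames(seeds, stems)),
                   configs = lapply(cfgs, unclass))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

deriveSeeds <- function(seed, n) {
  (as.numeric(seed) * 10007 + 131 * seq_len(n)) %% 2147483647
}

#' Perturb ground truth into synthetic detections
#'
#' Produces jittered copies of truth boxes with controlled positional noise
#' and assigned confidences, plus injected false positives, to exercise the
#' evaluation and survey modules without training a model.
#'
#' @param truths Box data.frame with `class_id`.
#' @param jitter_sd Center/size jitter, as a fraction of each box side.
#' @param fp_rate Expected false positives per true box.
#' @param miss_rate Fraction of truths dropped (misses).
#' @param conf_range Confidence range for true detections (FPs draw from
#'   the lower half).
#' @param image_size Scene size, for FP placement and clipping.
#' @param seed Integer seed.
#' @return Detection data.frame (`cx, cy, w, h, class_id, confidence`).
#' @export
perturbDetections <- function(truths, jitter_sd = 0.05, fp_rate = 0.1,
                              miss_rate = 0, conf_range = c(0.6, 1),
                              image_size = 640L, seed = 1L) {
  set.seed(seed)
  n <- nrow(truths)
  keep <- stats::runif(n) >= miss_rate
  t_ <- truths[keep, , drop = FALSE]
  out <- emptyDetections()
  if (nrow(t_)) {
    out <- data.frame(
      cx = t_$cx + stats::rnorm(nrow(t_), sd = jitter_sd * t_$w),
      cy = t_$cy + stats::rnorm(nrow(t_), sd = jitter_sd * t_$h),
      w = pmax(2, t_$w * exp(stats::rnorm(nrow(t_), sd = jitter_sd))),
      h = pmax(2, t_$h * exp(stats::rnorm(nrow(t_), sd = jitter_sd))),
      class_id = t_$class_id,
      confidence = stats::runif(nrow(t_), conf_range[1], conf_range[2]))
  }
  n_fp <- stats::rpois(1, fp_rate * max(1, n))
  if (n_fp > 0) {
    w <- stats::runif(n_fp, 10, 60) * image_size / 640
    h <- w * stats::runif(n_fp, 0.8, 1.25)
    fp <- data.frame(
      cx = stats::runif(n_fp, max(w) / 2, image_size - max(w) / 2),
      cy = stats::runif(n_fp, max(h) / 2, image_size - max(h) / 2),
      w = w, h = h,
      class_id = sample(0:1, n_fp, replace = TRUE),
      confidence = stats::runif(n_fp, 0.05, mean(conf_range)))
    out <- rbind(out, fp)
  }
  out
}
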