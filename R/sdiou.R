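# Axis-aligned box arithmetic and the size/shape-adaptive SDIoU similarity.
#
# Boxes are rows of a data.frame with columns cx, cy, w, h in pixels
# (center/size form). All functions are vectorized row-wise over box pairs.

#' Construct axis-aligned boxes in center/size form
#'
#' @param cx,cy Box center coordinates in pixels.
#' @param w,h Box width and height in pixels; must be strictly positive.
#' @param class_id Optional integer class id per box.
#' @param confidence Optional detection confidence in `[0, 1]`.
#' @return A `data.frame` with one row per box and columns `cx`, `cy`, `w`,
#'   `h` (plus `class_id`/`confidence` when supplied).
#' @examples
#' axisBox(50, 50, 10, 20)
#' @export
axisBox <- function(cx, cy, w, h, class_id = NULL, confidence = NULL) {
  b <- data.frame(cx = as.numeric(cx), cy = as.numeric(cy),
                  w = as.numeric(w), h = as.numeric(h))
  validateBoxes(b)
  if (!is.null(class_id)) b$class_id <- as.integer(class_id)
  if (!is.null(confidence)) {
    stopifnot(all(confidence >= 0 & confidence <= 1))
    b$confidence <- as.numeric(confidence)
  }
  b
}

validateBoxes <- function(b) {
  stopifnot(is.data.frame(b), all(c("cx", "cy", "w", "h") %in% names(b)))
  if (any(!is.finite(as.matrix(b[c("cx", "cy", "w", "h")]))))
    stop("box fields must be finite")
  if (any(b$w <= 0) || any(b$h <= 0))
    stop("invalid box: width and height must be strictly positive")
  invisible(b)
}

#' Convert boxes between center/size and corner form
#'
#' @param b Boxes as returned by [axisBox()].
#' @return `boxCorners()` returns a data.frame with `x1`, `y1`, `x2`, `y2`;
#'   `boxFromCorners()` the inverse.
#' @export
boxCorners <- function(b) {
  validateBoxes(b)
  data.frame(x1 = b$cx - b$w / 2, y1 = b$cy - b$h / 2,
             x2 = b$cx + b$w / 2, y2 = b$cy + b$h / 2)
}

#' @rdname boxCorners
#' @param x1,y1,x2,y2 Corner coordinates with `x1 < x2`, `y1 < y2`.
#' @export
boxFromCorners <- function(x1, y1, x2, y2) {
  axisBox((x1 + x2) / 2, (y1 + y2) / 2, x2 - x1, y2 - y1)
}

#' SDIoU hyperparameters
#'
#' `delta` is the fixed balance coefficient bounding the size-aware penalty;
#' `smax` is the reference area (squared pixels at network input resolution)
#' of the largest small-object target — 90 x 90 px by default, the largest
#' crown labeled in nadir orthophotos.
#'
#' @param delta Balance coefficient in (0, 1); default 0.5.
#' @param smax Maximum reference area in px^2; default 8100.
#' @return A list with class `sdiouParams`.
#' @export
sdiouParams <- function(delta = 0.5, smax = 90 * 90) {
  stopifnot(delta > 0, delta < 1, smax > 0)
  structure(list(delta = delta, smax = smax), class = "sdiouParams")
}

#' Intersection-over-union of box pairs
#'
#' @param b1,b2 Boxes (recycled row-wise to a common length).
#' @return Numeric vector of IoU values in `[0, 1]`; 0 for disjoint pairs.
#' @examples
#' boxIoU(axisBox(50, 50, 20, 40), axisBox(55, 50, 20, 20)) # 1/3
#' @export
boxIoU <- function(b1, b2) {
  validateBoxes(b1); validateBoxes(b2)
  c1 <- boxCorners(b1); c2 <- boxCorners(b2)
  iw <- pmax(0, pmin(c1$x2, c2$x2) - pmax(c1$x1, c2$x1))
  ih <- pmax(0, pmin(c1$y2, c2$y2) - pmax(c1$y1, c2$y1))
  inter <- iw * ih
  inter / (b1$w * b1$h + b2$w * b2$h - inter)
}

#' Aspect-ratio shape penalty
#'
#' `v = (4 / pi^2) (atan(w2/h2) - atan(w1/h1))^2`, zero iff the two aspect
#' ratios agree and bounded above by 1.
#'
#' @inheritParams boxIoU
#' @return Numeric vector in `[0, 1]`.
#' @export
shapePenalty <- function(b1, b2) {
  validateBoxes(b1); validateBoxes(b2)
  (4 / pi^2) * (atan(b2$w / b2$h) - atan(b1$w / b1$h))^2
}

#' Aspect-ratio alignment factor
#'
#' `alpha = v / (1 - IoU + v)`. At the degenerate point `v = 0`, `IoU = 1`
#' the downstream product `alpha * v` is defined as 0, so `alpha` itself is
#' returned as 0 whenever `v = 0`.
#'
#' @param v Shape penalty from [shapePenalty()].
#' @param iou IoU of the same pair.
#' @return Numeric vector.
#' @export
sdiouAlpha <- function(v, iou) {
  stopifnot(all(v >= 0), all(iou >= -1e-12 & iou <= 1 + 1e-12))
  ifelse(v == 0, 0, v / (1 - iou + v))
}

#' Size-aware penalty coefficient
#'
#' `beta = delta * (1 - log(1 + area) / log(1 + smax))` (natural logarithm),
#' monotone decreasing in the target area, equal to `delta` in the
#' zero-area limit and clamped to `[0, delta]` for areas above `smax`.
#'
#' @param target_area Area of the target (ground-truth) box in px^2.
#' @param params An [sdiouParams()] object.
#' @return Numeric vector in `[0, delta]`.
#' @export
sdiouBeta <- function(target_area, params = sdiouParams()) {
  if (any(target_area <= 0)) stop("invalid box: target area must be positive")
  b <- params$delta * (1 - log1p(target_area) / log1p(params$smax))
  pmin(pmax(b, 0), params$delta)
}

#' SDIoU similarity of predicted and target boxes
#'
#' `SDIoU = (delta - beta) + (1 - delta + beta) IoU - alpha v
#'  - (1 + delta - beta) rho^2 / c^2`, where `rho^2` is the squared center
#' distance and `c^2` the squared diagonal of the smallest enclosing box.
#' Equals 1 exactly when the boxes coincide; can go negative for distant
#' pairs (the center-distance term dominates).
#'
#' @param b1 Predicted boxes. @param b2 Target boxes.
#' @param params An [sdiouParams()] object.
#' @return Numeric vector of similarities.
#' @examples
#' p <- sdiouParams()
#' sdiou(axisBox(50, 50, 20, 40), axisBox(50, 50, 20, 40), p) # 1
#' @export
sdiou <- function(b1, b2, params = sdiouParams()) {
  validateBoxes(b1); validateBoxes(b2)
  iou <- boxIoU(b1, b2)
  v <- shapePenalty(b1, b2)
  alpha <- sdiouAlpha(v, iou)
  beta <- sdiouBeta(b2$w * b2$h, params)
  rho2 <- (b1$cx - b2$cx)^2 + (b1$cy - b2$cy)^2
  c1 <- boxCorners(b1); c2 <- boxCorners(b2)
  ew <- pmax(c1$x2, c2$x2) - pmin(c1$x1, c2$x1)
  eh <- pmax(c1$y2, c2$y2) - pmin(c1$y1, c2$y1)
  d <- params$delta
  (d - beta) + (1 - d + beta) * iou - alpha * v -
    (1 + d - beta) * rho2 / (ew^2 + eh^2)
}

#' SDIoU regression loss
#'
#' `1 - sdiou(b1, b2)`: zero at a perfect match, growing with center offset,
#' size and aspect mismatch, with penalties strengthened for small targets.
#'
#' @inheritParams sdiou
#' @return Numeric vector of losses.
#' @export
sdiouLoss <- function(b1, b2, params = sdiouParams()) {
  1 - sdiou(b1, b2, params)
}

#' Gradient of the SDIoU loss with respect to the predicted box
#'
#' Central finite differences in each of `cx, cy, w, h` with a step scaled
#' to the box size; the loss surface is smooth almost everywhere, so the
#' approximation error is far below optimizer noise.
#'
#' @inheritParams sdiou
#' @param eps Relative step size.
#' @return A numeric matrix `n x 4` with columns `cx, cy, w, h`.
#' @export
sdiouGrad <- function(b1, b2, params = sdiouParams(), eps = 1e-4) {
  validateBoxes(b1); validateBoxes(b2)
  n <- nrow(b1)
  g <- matrix(0, n, 4, dimnames = list(NULL, c("cx", "cy", "w", "h")))
  scale <- pmax(b1$w, b1$h)
  for (j in 1:4) {
    h <- eps * pmax(scale, 1)
    up <- b1; dn <- b1
    up[[j]] <- up[[j]] + h
    dn[[j]] <- dn[[j]] - h
    if (j >= 3) dn[[j]] <- pmax(dn[[j]], 1e-6)  # keep size positive
    g[, j] <- (sdiouLoss(up, b2, params) - sdiouLoss(dn, b2, params)) /
      (up[[j]] - dn[[j]])
  }
  g
}
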