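# Detection evaluation: greedy confidence-ordered matching, precision /
# recall / F1, average precision as the area under the all-points
# interpolated precision-recall envelope, and mAP at IoU 0.5.

#' Match detections to ground truth
#'
#' Per class, detections are sorted by descending confidence (ties by
#' original index) and each is greedily matched to the unmatched same-class
#' ground-truth box with the highest IoU at or above the threshold. Each
#' ground truth is matched at most once.
#'
#' @param dets Detections (`cx, cy, w, h, class_id, confidence`).
#' @param truths Ground truth (`cx, cy, w, h, class_id`).
#' @param iou_thr IoU matching threshold (default 0.5).
#' @return List: `flags` (detections in descending-confidence order with a
#'   logical `tp`), and `counts` (per-class data.frame `TP, FP, FN`).
#' @export
matchDetections <- function(dets, truths, iou_thr = 0.5) {
  classes <- sort(unique(c(dets$class_id, truths$class_id)))
  flags <- list()
  counts <- list()
  for (cl in classes) {
    d <- dets[dets$class_id == cl, , drop = FALSE]
    t_ <- truths[truths$class_id == cl, , drop = FALSE]
    d <- d[order(-d$confidence, seq_len(nrow(d))), , drop = FALSE]
    matched <- rep(FALSE, nrow(t_))
    tp <- logical(nrow(d))
    for (i in seq_len(nrow(d))) {
      if (nrow(t_) == 0) break
      ious <- boxIoU(d[rep(i, nrow(t_)), , drop = FALSE], t_)
      ious[matched] <- -1
      j <- which.max(ious)
      if (length(j) && ious[j] >= iou_thr) {
        matched[j] <- TRUE
        tp[i] <- TRUE
      }
    }
    d$tp <- tp
    flags[[as.character(cl)]] <- d
    counts[[as.character(cl)]] <-
      data.frame(class_id = cl, TP = sum(tp), FP = sum(!tp),
                 FN = nrow(t_) - sum(tp))
  }
  list(flags = flags, counts = do.call(rbind, counts))
}

#' Precision, recall and F1 from match counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`, with the 0/0
#' convention mapping to 0.
#'
#' @param TP,FP,FN Non-negative counts.
#' @return Named list `P, R, F1`.
#' @examples
#' precisionRecallF1(8, 2, 2) # all three 0.8
#' @export
precisionRecallF1 <- function(TP, FP, FN) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0)
  P <- if (TP + FP > 0) TP / (TP + FP) else 0
  R <- if (TP + FN > 0) TP / (TP + FN) else 0
  F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  list(P = P, R = R, F1 = F1)
}

#' Average precision from PR points
#'
#' All-points interpolation: the area under the precision envelope
#' `p_interp(r) = max_{r' >= r} p(r')` accumulated over the recall steps.
#' Points must come from a descending-confidence sweep (recall
#' non-decreasing).
#'
#' @param recall,precision PR points from the confidence sweep.
#' @return Scalar AP in `[0, 1]`.
#' @examples
#' # detection sequence TP, FP, TP over two truths
#' averagePrecision(c(.5, .5, 1), c(1, .5, 2/3)) # 0.8333
#' @export
averagePrecision <- function(recall, precision) {
  stopifnot(length(recall) == length(precision))
  if (length(recall) == 0) return(0)
  env <- rev(cummax(rev(precision)))
  sum(diff(c(0, recall)) * env)
}

# AP and PR curve from descending-confidence tp flags
apFromFlags <- function(tp, n_truth, confidence = NULL) {
  if (length(tp) == 0 || n_truth == 0)
    return(list(ap = 0, curve = data.frame(recall = numeric(),
                                           precision = numeric(),
                                           confidence = numeric())))
  cum_tp <- cumsum(tp)
  rec <- cum_tp / n_truth
  prec <- cum_tp / seq_along(tp)
  list(ap = averagePrecision(rec, prec),
       curve = data.frame(recall = rec, precision = prec,
                          confidence = confidence %||% rep(NA_real_, length(tp))))
}

#' Mean average precision over classes
#'
#' @param per_class_ap Numeric vector, one AP per class.
#' @return Arithmetic mean.
#' @export
meanAP <- function(per_class_ap) {
  if (length(per_class_ap) == 0) stop("no classes: mAP undefined")
  mean(per_class_ap)
}

#' Evaluate detections over an image set
#'
#' Matches per image, pools detections per class across images, computes
#' per-class AP/P/R/F1 (the point metrics at the F1-maximizing confidence),
#' mAP, and a pooled class-agnostic row (all detections and truths merged
#' into one matching problem).
#'
#' @param det_list List (per image) of detection data.frames.
#' @param truth_list List (per image) of ground-truth data.frames.
#' @param n_classes Number of classes.
#' @param iou_thr IoU matching threshold.
#' @param class_names Optional class labels for the report.
#' @return An [EvalReport-class] object.
#' @export
evaluateDetections <- function(det_list, truth_list, n_classes = 2L,
                               iou_thr = 0.5,
                               class_names = c("Weak", "Dead")) {
  stopifnot(length(det_list) == length(truth_list))
  if (length(class_names) < n_classes)
    class_names <- paste0("class", seq_len(n_classes) - 1L)
  gather <- function(pool_classes) {
    per_img <- lapply(seq_along(det_list), function(i) {
      d <- det_list[[i]]; t_ <- truth_list[[i]]
      if (is.null(d)) d <- emptyDetections()
      if (is.null(t_)) t_ <- emptyDetections()
      if (pool_classes) {
        if (nrow(d)) d$class_id <- 0L
        if (nrow(t_)) t_$class_id <- 0L
      }
      m <- matchDetections(d, t_, iou_thr)
      flg <- do.call(rbind, m$flags)
      if (!is.null(flg) && nrow(flg)) flg$image <- i
      list(flags = flg, truths = t_)
    })
    flags <- do.call(rbind, lapply(per_img, `[[`, "flags"))
    truths <- do.call(rbind, lapply(per_img, `[[`, "truths"))
    list(flags = flags, truths = truths)
  }
  byc <- gather(FALSE)
  per_class <- list()
  curves <- list()
  for (cl in seq_len(n_classes) - 1L) {
    fl <- byc$flags[byc$flags$class_id == cl, , drop = FALSE]
    fl <- fl[order(-fl$confidence), , drop = FALSE]
    n_truth <- sum(byc$truths$class_id == cl)
    res <- apFromFlags(fl$tp, n_truth, fl$confidence)
    bm <- bestF1Point(fl$tp, n_truth)
    per_class[[length(per_class) + 1L]] <-
      data.frame(class_id = cl, class = class_names[cl + 1L],
                 n_truth = n_truth, n_det = nrow(fl),
                 P = bm$P, R = bm$R, F1 = bm$F1, AP = res$ap)
    curves[[class_names[cl + 1L]]] <- res$curve
  }
  per_class <- do.call(rbind, per_class)
  pooled_in <- gather(TRUE)
  fl <- pooled_in$flags
  fl <- fl[order(-fl$confidence), , drop = FALSE]
  n_truth <- nrow(pooled_in$truths)
  pr <- apFromFlags(fl$tp, n_truth, fl$confidence)
  bm <- bestF1Point(fl$tp, n_truth)
  curves[["All"]] <- pr$curve
  methods::new("EvalReport", perClass = per_class,
               pooled = list(AP = pr$ap, P = bm$P, R = bm$R, F1 = bm$F1),
               map = meanAP(per_class$AP), prCurves = curves,
               iouThreshold = iou_thr)
}

bestF1Point <- function(tp, n_truth) {
  if (length(tp) == 0 || n_truth == 0) return(list(P = 0, R = 0, F1 = 0))
  cum_tp <- cumsum(tp)
  P <- cum_tp / seq_along(tp)
  R <- cum_tp / n_truth
  F1 <- ifelse(P + R > 0, 2 * P * R / (P + R), 0)
  k <- which.max(F1)
  list(P = P[k], R = R[k], F1 = F1[k])
}

emptyDetections <- function() {
  data.frame(cx = numeric(), cy = numeric(), w = numeric(), h = numeric(),
             class_id = integer(), confidence = numeric())
}

#' Evaluate a detector on scenes
#'
#' Runs [predictBoxes()] on every scene and scores against the scene truths.
#'
#' @param net Detector network.
#' @param scenes List of scenes (`image` + `truths`) or `ForestScene`s.
#' @param iou_thr IoU threshold.
#' @param conf_threshold Decode confidence threshold (low by default so the
#'   PR sweep covers the full recall range).
#' @return List with `map`, the full `report` ([EvalReport-class]).
#' @export
evaluateScenes <- function(net, scenes, iou_thr = 0.5, conf_threshold = 0.05) {
  det_list <- lapply(scenes, function(sc) {
    img <- if (methods::is(sc, "ForestScene")) sceneImage(sc) else sc$image
    predictBoxes(net, img, conf_threshold = conf_threshold)
  })
  truth_list <- lapply(scenes, function(sc)
    if (methods::is(sc, "ForestScene")) sceneTruths(sc) else sc$truths)
  rep <- evaluateDetections(det_list, truth_list, net$cfg$n_classes, iou_thr)
  list(map = mAP(rep), report = rep)
}

# report serialization ----------------------------------------------------

#' Write / read an evaluation report as structured text
#'
#' Key/value header plus a comma-separated PR point table per curve.
#'
#' @param report An [EvalReport-class].
#' @param path Output file.
#' @export
writeEvalReport <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("iou_threshold,%.6g", report@iouThreshold), con)
  writeLines(sprintf("mAP,%.10g", report@map), con)
  writeLines(sprintf("pooled_AP,%.10g", report@pooled$AP), con)
  writeLines(sprintf("pooled_P,%.10g", report@pooled$P), con)
  writeLines(sprintf("pooled_R,%.10g", report@pooled$R), con)
  writeLines(sprintf("pooled_F1,%.10g", report@pooled$F1), con)
  writeLines("[per_class]", con)
  utils::write.csv(report@perClass, con, row.names = FALSE)
  for (nm in names(report@prCurves)) {
    writeLines(sprintf("[pr_curve %s]", nm), con)
    utils::write.csv(report@prCurves[[nm]], con, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname writeEvalReport
#' @return `readEvalReport()` returns the reconstructed
#'   [EvalReport-class].
#' @export
readEvalReport <- function(path) {
  lines <- readLines(path)
  secs <- grep("^\\[", lines)
  hdr <- lines[seq_len(secs[1] - 1)]
  kv <- do.call(rbind, strsplit(hdr, ","))
  vals <- stats::setNames(as.numeric(kv[, 2]), kv[, 1])
  readBlock <- function(tag) {
    at <- grep(paste0("^\\[", tag), lines)
    if (!length(at)) return(NULL)
    nxt <- c(secs[secs > at[1]], length(lines) + 1L)[1]
    utils::read.csv(text = paste(lines[(at[1] + 1L):(nxt - 1L)],
                                 collapse = "\n"))
  }
  per_class <- readBlock("per_class")
  curve_tags <- sub("^\\[pr_curve (.*)\\]$", "\\1",
                    grep("^\\[pr_curve ", lines, value = TRUE))
  curves <- lapply(curve_tags, function(tag) readBlock(paste0("pr_curve ", tag)))
  names(curves) <- curve_tags
  methods::new("EvalReport", perClass = per_class,
               pooled = list(AP = vals[["pooled_AP"]], P = vals[["pooled_P"]],
                             R = vals[["pooled_R"]], F1 = vals[["pooled_F1"]]),
               map = vals[["mAP"]], prCurves = curves,
               iouThreshold = vals[["iou_threshold"]])
}
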