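#' @import methods
NULL

#' ForestScene: a rendered synthetic UAV forest scene
#'
#' Holds the rendered RGB image, the ground-truth annotations (Weak/Dead
#' crowns only; healthy crowns are rendered but unannotated background) and
#' the generation metadata.
#'
#' @slot image Numeric array (H, W, 3) in `[0, 1]`.
#' @slot truths data.frame of annotated boxes (`cx, cy, w, h, class_id`).
#' @slot metadata List: seed, view mode, per-tree render parameters.
#' @export
setClass("ForestScene",
         representation(image = "array", truths = "data.frame",
                        metadata = "list"),
         validity = function(object) {
           d <- dim(object@image)
           if (length(d) != 3 || d[3] != 3)
             return("image must be an (H, W, 3) array")
           if (min(object@image) < 0 || max(object@image) > 1)
             return("image values must lie in [0, 1]")
           if (nrow(object@truths) > 0) {
             co <- boxCorners(object@truths)
             if (any(co$x1 < -0.51) || any(co$y1 < -0.51) ||
                 any(co$x2 > d[2] + 0.51) || any(co$y2 > d[1] + 0.51))
               return("annotated boxes must lie within image bounds")
           }
           TRUE
         })

#' @describeIn ForestScene Rendered image array.
#' @param object,x A `ForestScene`.
#' @export
setGeneric("sceneImage", function(x) standardGeneric("sceneImage"))

#' @export
setMethod("sceneImage", "ForestScene", function(x) x@image)

#' @describeIn ForestScene Ground-truth annotation data.frame.
#' @export
setGeneric("sceneTruths", function(x) standardGeneric("sceneTruths"))

#' @export
setMethod("sceneTruths", "ForestScene", function(x) x@truths)

#' @describeIn ForestScene Generation metadata list.
#' @export
setGeneric("sceneMetadata", function(x) standardGeneric("sceneMetadata"))

#' @export
setMethod("sceneMetadata", "ForestScene", function(x) x@metadata)

setMethod("show", "ForestScene", function(object) {
  d <- dim(object@image)
  cat(sprintf("ForestScene %dx%d px, %s view, %d annotated crown(s)\n",
              d[2], d[1],
              object@metadata$view_mode %||% "?", nrow(object@truths)))
  if (nrow(object@truths) > 0) {
    tab <- table(factor(object@truths$class_id, levels = 0:1,
                        labels = c("Weak", "Dead")))
    cat("  ", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
  }
})

#' EvalReport: detection evaluation summary
#'
#' Per-class precision/recall/F1 (at the F1-maximizing confidence), average
#' precision from the all-points precision-recall envelope, their mean
#' (mAP), a pooled all-classes row, and the PR curve points.
#'
#' @slot perClass data.frame with one row per class.
#' @slot pooled Named list: metrics of the pooled (class-agnostic) problem.
#' @slot map Mean of the per-class APs.
#' @slot prCurves Named list of PR-point data.frames.
#' @slot iouThreshold IoU matching threshold.
#' @export
setClass("EvalReport",
         representation(perClass = "data.frame", pooled = "list",
                        map = "numeric", prCurves = "list",
                        iouThreshold = "numeric"),
         validity = function(object) {
           v <- c(object@perClass$AP, object@map)
           if (any(v < -1e-9 | v > 1 + 1e-9)) return("AP/mAP must be in [0, 1]")
           if (abs(object@map - mean(object@perClass$AP)) > 1e-9)
             return("mAP must equal the mean of per-class APs")
           TRUE
         })

#' @describeIn EvalReport Mean average precision.
#' @param x An `EvalReport`.
#' @export
setGeneric("mAP", function(x) standardGeneric("mAP"))

#' @export
setMethod("mAP", "EvalReport", function(x) x@map)

#' @describeIn EvalReport Per-class metric table.
#' @export
setGeneric("classMetrics", function(x) standardGeneric("classMetrics"))

#' @export
setMethod("classMetrics", "EvalReport", function(x) x@perClass)

#' @describeIn EvalReport PR curve point list.
#' @export
setGeneric("prCurves", function(x) standardGeneric("prCurves"))

#' @export
setMethod("prCurves", "EvalReport", function(x) x@prCurves)

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport (IoU %.2f): mAP %.4f\n",
              object@iouThreshold, object@map))
  print(object@perClass, row.names = FALSE)
  cat(sprintf("pooled: AP %.4f  P %.4f  R %.4f  F1 %.4f\n",
              object@pooled$AP, object@pooled$P, object@pooled$R,
              object@pooled$F1))
})

#' SurveyReport: ground-survey validation summary
#'
#' Per damage category: surveyed damaged trees (DT), successfully detected
#' (SD) and the accuracy rate AR = 100 SD / DT, plus the overall rate and
#' the counts of retained Weak/Dead detections.
#'
#' @slot categories data.frame with `category, DT, SD, AR`.
#' @slot overall Named list `DT, SD, AR`.
#' @slot detections Named list with retained `weak` and `dead` box counts.
#' @slot confThreshold Confidence filter applied to the detections.
#' @export
setClass("SurveyReport",
         representation(categories = "data.frame", overall = "list",
                        detections = "list", confThreshold = "numeric"),
         validity = function(object) {
           if (any(object@categories$SD > object@categories$DT))
             return("SD cannot exceed DT")
           if (any(object@categories$SD < 0 | object@categories$DT < 0))
             return("counts must be non-negative")
           TRUE
         })

#' @describeIn SurveyReport Accuracy-rate table per category.
#' @param x A `SurveyReport`.
#' @export
setGeneric("surveyRates", function(x) standardGeneric("surveyRates"))

#' @export
setMethod("surveyRates", "SurveyReport", function(x) x@categories)

#' @describeIn SurveyReport Overall DT/SD/AR list.
#' @export
setGeneric("surveyOverall", function(x) standardGeneric("surveyOverall"))

#' @export
setMethod("surveyOverall", "SurveyReport", function(x) x@overall)

setMethod("show", "SurveyReport", function(object) {
  cat(renderSurveyTable(object))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
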