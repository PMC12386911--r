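# Annotation I/O: LabelImg-dialect Pascal VOC XML, YOLO plain-text labels,
# the 7:3 split utility and the class-name mapping.
#
# VOC corner semantics follow LabelImg: xmin/ymin/xmax/ymax are 1-based
# inclusive pixel indices, so a box spanning columns 1..100 has width 99 in
# the continuous center/size convention (center 50.0). The off-by-one is
# applied symmetrically on write, making the round trip exact.

#' Default class vocabulary
#'
#' Weak maps to id 0 and Dead to id 1; extendable for multi-disease setups
#' (e.g. adding PWD classes).
#'
#' @return Named integer vector.
#' @export
defaultClassMap <- function() c(Weak = 0L, Dead = 1L)

#' Read a LabelImg Pascal VOC XML annotation
#'
#' @param path XML file.
#' @param class_map Named id vector; names outside it are kept but flagged.
#' @return List with `path`, `width`, `height`, `boxes` (data.frame `cx, cy,
#'   w, h, class`, plus `class_id` where known and a logical `known`).
#' @export
readVocXml <- function(path, class_map = defaultClassMap()) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed VOC XML at ", path, ": ",
                                           conditionMessage(e)))
  size <- xml2::xml_find_first(doc, ".//size")
  if (inherits(size, "xml_missing"))
    stop("VOC XML missing <size> element: ", path)
  width <- as.numeric(xml2::xml_text(xml2::xml_find_first(size, "./width")))
  height <- as.numeric(xml2::xml_text(xml2::xml_find_first(size, "./height")))
  objs <- xml2::xml_find_all(doc, ".//object")
  boxes <- lapply(objs, function(o) {
    nm <- xml2::xml_text(xml2::xml_find_first(o, "./name"))
    bb <- xml2::xml_find_first(o, "./bndbox")
    cr <- vapply(c("xmin", "ymin", "xmax", "ymax"), function(tag)
      as.numeric(xml2::xml_text(xml2::xml_find_first(bb, paste0("./", tag)))),
      numeric(1))
    data.frame(cx = (cr["xmin"] + cr["xmax"]) / 2 - 0.5,
               cy = (cr["ymin"] + cr["ymax"]) / 2 - 0.5,
               w = cr["xmax"] - cr["xmin"],
               h = cr["ymax"] - cr["ymin"],
               class = nm)
  })
  boxes <- if (length(boxes)) do.call(rbind, boxes) else
    data.frame(cx = numeric(), cy = numeric(), w = numeric(), h = numeric(),
               class = character())
  rownames(boxes) <- NULL
  boxes$known <- boxes$class %in% names(class_map)
  boxes$class_id <- unname(class_map[boxes$class])
  list(path = path, width = width, height = height, boxes = boxes)
}

#' Write a LabelImg Pascal VOC XML annotation
#'
#' @param ann Annotation list as from [readVocXml()] (uses `width`,
#'   `height`, `boxes` with `cx, cy, w, h, class`).
#' @param path Output file.
#' @export
writeVocXml <- function(ann, path) {
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", basename(ann$path %||% path))
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(ann$width))
  xml2::xml_add_child(size, "height", as.character(ann$height))
  xml2::xml_add_child(size, "depth", "3")
  b <- ann$boxes
  for (i in seq_len(nrow(b))) {
    o <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(o, "name", b$class[i])
    bb <- xml2::xml_add_child(o, "bndbox")
    xml2::xml_add_child(bb, "xmin", fmtNum(b$cx[i] - b$w[i] / 2 + 0.5))
    xml2::xml_add_child(bb, "ymin", fmtNum(b$cy[i] - b$h[i] / 2 + 0.5))
    xml2::xml_add_child(bb, "xmax", fmtNum(b$cx[i] + b$w[i] / 2 + 0.5))
    xml2::xml_add_child(bb, "ymax", fmtNum(b$cy[i] + b$h[i] / 2 + 0.5))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

fmtNum <- function(x) {
  ifelse(abs(x - round(x)) < 1e-9, sprintf("%d", as.integer(round(x))),
         sprintf("%.6f", x))
}

#' Read YOLO plain-text labels
#'
#' Five whitespace-separated columns per line: class id, then normalized
#' center x/y and width/height in `[0, 1]`.
#'
#' @param path Label file (may be absent or empty: zero boxes).
#' @return data.frame `class_id, cx, cy, w, h` (normalized).
#' @export
readYoloLabels <- function(path) {
  empty <- data.frame(class_id = integer(), cx = numeric(), cy = numeric(),
                      w = numeric(), h = numeric())
  if (!file.exists(path)) return(empty)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty)
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(parts, length, integer(1)) != 5L)
  if (length(bad))
    stop("malformed YOLO label lines ", paste(bad, collapse = ", "),
         " in ", path)
  m <- do.call(rbind, lapply(parts, as.numeric))
  out <- data.frame(class_id = as.integer(m[, 1]), cx = m[, 2], cy = m[, 3],
                    w = m[, 4], h = m[, 5])
  oob <- which(out$cx < 0 | out$cx > 1 | out$cy < 0 | out$cy > 1 |
               out$w < 0 | out$w > 1 | out$h < 0 | out$h > 1)
  if (length(oob))
    stop("YOLO label values out of [0, 1] on line(s) ",
         paste(oob, collapse = ", "), " in ", path)
  out
}

#' Write YOLO plain-text labels
#'
#' @param labels data.frame `class_id, cx, cy, w, h` (normalized).
#' @param path Output file.
#' @export
writeYoloLabels <- function(labels, path) {
  oob <- which(labels$cx < 0 | labels$cx > 1 | labels$cy < 0 | labels$cy > 1 |
               labels$w < 0 | labels$w > 1 | labels$h < 0 | labels$h > 1)
  if (length(oob))
    stop("normalized label values out of [0, 1] in row(s) ",
         paste(oob, collapse = ", "))
  lines <- sprintf("%d %s %s %s %s", labels$class_id,
                   trimNum(labels$cx), trimNum(labels$cy),
                   trimNum(labels$w), trimNum(labels$h))
  writeLines(lines, path)
  invisible(path)
}

trimNum <- function(x) sub("0+$", "", sprintf("%.8f", x))

#' Convert YOLO normalized labels to pixel boxes and back
#'
#' @param labels Normalized labels as from [readYoloLabels()].
#' @param width,height Image size in px.
#' @return `yoloToPixels()` returns a pixel-frame box data.frame with
#'   `class_id`; `pixelsToYolo()` the inverse.
#' @export
yoloToPixels <- function(labels, width, height) {
  data.frame(cx = labels$cx * width, cy = labels$cy * height,
             w = labels$w * width, h = labels$h * height,
             class_id = labels$class_id)
}

#' @rdname yoloToPixels
#' @param boxes Pixel-frame boxes with `class_id`.
#' @export
pixelsToYolo <- function(boxes, width, height) {
  data.frame(class_id = boxes$class_id, cx = boxes$cx / width,
             cy = boxes$cy / height, w = boxes$w / width,
             h = boxes$h / height)
}

#' Split image stems into train and validation sets
#'
#' Seeded shuffle; the training set takes `round(ratio * n)` stems. The
#' split is per image and is a partition of the input.
#'
#' @param stems Character vector of image stems.
#' @param ratio Training fraction (default 0.7).
#' @param seed Integer seed.
#' @return List with `train` and `val` character vectors.
#' @export
splitDataset <- function(stems, ratio = 0.7, seed = 1L) {
  stopifnot(length(stems) > 0, ratio > 0, ratio < 1)
  set.seed(seed)
  shuffled <- sample(stems)
  n_train <- round(ratio * length(stems))
  list(train = shuffled[seq_len(n_train)],
       val = shuffled[setdiff(seq_along(stems), seq_len(n_train))])
}

#' Write / read a class map as two-column text
#'
#' @param class_map Named integer vector.
#' @param path File path.
#' @export
writeClassMap <- function(class_map, path) {
  writeLines(sprintf("%s %d", names(class_map), class_map), path)
  invisible(path)
}

#' @rdname writeClassMap
#' @export
readClassMap <- function(path) {
  parts <- strsplit(trimws(readLines(path)), "\\s+")
  stats::setNames(vapply(parts, function(p) as.integer(p[2]), integer(1)),
                  vapply(parts, `[[`, character(1), 1))
}

# PNG image helpers ---------------------------------------------------------

#' Read / write RGB images as PNG
#'
#' @param path PNG file.
#' @return `readImagePNG()` returns an (H, W, 3) array in `[0, 1]`.
#' @export
readImagePNG <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE]
  img
}

#' @rdname readImagePNG
#' @param img (H, W, 3) array in `[0, 1]`.
#' @export
writeImagePNG <- function(img, path) {
  png::writePNG(img, path)
  invisible(path)
}

# study bookkeeping ----------------------------------------------------------

#' Per-plot image counts of the woodwasp UAV survey
#'
#' The image inventory of the four surveyed plots: originals collected and
#' images retained after quality preprocessing (excluding frames without
#' damaged trees, broadleaf-dominated or blurred frames).
#'
#' @return data.frame with `plot`, `original`, `preprocessed`.
#' @export
plotImageCounts <- function() {
  utils::read.csv(system.file("extdata", "sw_plot_image_counts.csv",
                              package = "crownwatch"),
                  stringsAsFactors = FALSE)
}

#' @rdname plotImageCounts
#' @return `retainedImageTotal()`: the summed preprocessed column.
#' @export
retainedImageTotal <- function() sum(plotImageCounts()$preprocessed)
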