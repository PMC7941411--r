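## Central S4 containers.
##
## Coordinate conventions used throughout the package:
##   * masks are logical matrices indexed [row, col], row-major semantics,
##     origin at the top-left pixel, 0-based pixel coordinates at the API
##     level (pixel (r, c) lives at matrix cell [r + 1, c + 1]);
##   * the center of pixel (r, c) is the continuous point (x = c + 0.5,
##     y = r + 0.5), with x growing rightwards and y downwards;
##   * bounding boxes are half-open integer vectors c(r0, c0, r1, c1),
##     covering rows [r0, r1) and columns [c0, c1);
##   * polygons are n x 2 matrices of (x, y) vertices in pixel units, the
##     order used by the VIA annotation tool.

#' Class labels understood by the pipeline
#'
#' Approach 1 labels ears as `whole_corn` plus `bare_cob` parts; Approach 2
#' labels `corn_kernel` clusters plus `bare_cob` parts (the whole ear being
#' their union).
#'
#' @param approach 1 or 2.
#' @return Character vector of legal class labels.
#' @export
approachClasses <- function(approach) {
  switch(as.character(approach),
    "1" = c("whole_corn", "bare_cob"),
    "2" = c("corn_kernel", "bare_cob"),
    stop("approach must be 1 or 2")
  )
}

CQ_CLASSES <- c("whole_corn", "bare_cob", "corn_kernel")

#' @rdname Detection-class
#' @export
setClass("Detection", representation(
  label = "character",
  mask = "matrix",
  box = "integer",
  score = "numeric"
))

setValidity("Detection", function(object) {
  msg <- character()
  if (!object@label %in% CQ_CLASSES) {
    msg <- c(msg, paste0("unknown class label '", object@label, "'"))
  }
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be a logical matrix")
  if (is.logical(object@mask) && !any(object@mask)) {
    msg <- c(msg, "mask must have positive area")
  }
  if (length(object@box) != 4L) msg <- c(msg, "box must have length 4")
  if (length(object@score) != 1L || object@score < 0 || object@score > 1) {
    msg <- c(msg, "score must be a single value in [0, 1]")
  }
  if (is.logical(object@mask) && any(object@mask) &&
    length(object@box) == 4L && !identical(object@box, tightBox(object@mask))) {
    msg <- c(msg, "box must be the tight bounding box of the mask")
  }
  if (length(msg)) msg else TRUE
})

#' One segmented instance
#'
#' A `Detection` couples a class label with a binary pixel mask, its tight
#' half-open bounding box and a confidence score in \[0, 1\]. Ground-truth
#' passthroughs carry score 1.
#'
#' @param label One of `whole_corn`, `bare_cob`, `corn_kernel`.
#' @param mask Logical matrix (rows = image rows).
#' @param score Confidence in \[0, 1\].
#' @param box Optional half-open box `c(r0, c0, r1, c1)`; computed from the
#'   mask when missing.
#' @return A `Detection` object.
#' @examples
#' m <- matrix(FALSE, 4, 4); m[2:3, 2:3] <- TRUE
#' Detection("bare_cob", m, score = 0.9)
#' @export
Detection <- function(label, mask, score = 1, box = NULL) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  new("Detection",
    label = label, mask = mask,
    box = if (is.null(box)) tightBox(mask) else as.integer(box),
    score = as.numeric(score)
  )
}

#' @rdname DetectionSet-class
#' @export
setClass("DetectionSet", representation(
  imageId = "character",
  detections = "list",
  source = "character"
))

setValidity("DetectionSet", function(object) {
  msg <- character()
  if (!object@source %in% c("ground_truth", "external_model", "builtin_backend")) {
    msg <- c(msg, "source must be ground_truth, external_model or builtin_backend")
  }
  if (!all(vapply(object@detections, is, logical(1), class2 = "Detection"))) {
    msg <- c(msg, "detections must be a list of Detection objects")
  } else if (length(object@detections) > 1L) {
    s <- vapply(object@detections, slot, numeric(1), name = "score")
    if (is.unsorted(rev(s))) msg <- c(msg, "detections must be sorted by descending score")
  }
  if (length(msg)) msg else TRUE
})

#' All detections for one image
#'
#' Detections are kept sorted by descending confidence score on construction,
#' the order in which greedy instance matching and precision-recall walks
#' consume them.
#'
#' @param imageId Image identifier.
#' @param detections List of [Detection] objects (sorted on ingest).
#' @param source `"ground_truth"`, `"external_model"` or `"builtin_backend"`.
#' @return A `DetectionSet`.
#' @export
DetectionSet <- function(imageId, detections = list(), source = "ground_truth") {
  if (length(detections)) {
    s <- vapply(detections, slot, numeric(1), name = "score")
    detections <- detections[order(-s)]
  }
  new("DetectionSet", imageId = imageId, detections = detections, source = source)
}

#' @rdname AnnotatedScene-class
#' @export
setClass("AnnotatedScene", representation(
  imageId = "character",
  imageShape = "integer",
  instances = "list",
  approach = "integer"
))

setValidity("AnnotatedScene", function(object) {
  msg <- character()
  if (length(object@imageShape) != 2L || any(object@imageShape < 1L)) {
    msg <- c(msg, "imageShape must be c(height, width), both >= 1")
  }
  if (!object@approach %in% c(1L, 2L)) msg <- c(msg, "approach must be 1 or 2")
  legal <- approachClasses(object@approach)
  for (inst in object@instances) {
    if (is.null(inst$label) || !inst$label %in% legal) {
      msg <- c(msg, paste0(
        "instance label '", inst$label %||% "<missing>",
        "' is not legal for approach ", object@approach
      ))
      break
    }
    if (is.null(inst$polygon) && is.null(inst$mask)) {
      msg <- c(msg, "each instance needs a polygon or a mask")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Labeled instances of one image
#'
#' The annotation-side counterpart of a [DetectionSet]: each instance is a
#' class label plus either a VIA-style polygon (n x 2 matrix of (x, y) pixel
#' vertices) or a binary mask.
#'
#' @param imageId Image identifier, unique within a dataset.
#' @param imageShape `c(height, width)` in pixels.
#' @param instances List of `list(label =, polygon = | mask =)` entries.
#' @param approach Labeling approach, 1 or 2.
#' @return An `AnnotatedScene`.
#' @export
AnnotatedScene <- function(imageId, imageShape, instances = list(), approach = 1) {
  new("AnnotatedScene",
    imageId = imageId, imageShape = as.integer(imageShape),
    instances = instances, approach = as.integer(approach)
  )
}

#' @rdname EarGroup-class
#' @export
setClass("EarGroup", representation(
  earBox = "integer",
  wholeMask = "matrix",
  bareParts = "list",
  kernelParts = "list",
  side = "character"
))

setValidity("EarGroup", function(object) {
  msg <- character()
  if (!any(object@wholeMask)) msg <- c(msg, "whole mask must have positive area")
  if (!object@side %in% c("left", "right", "only", "middle")) {
    msg <- c(msg, "side must be left, right, only or middle")
  }
  if (length(msg)) msg else TRUE
})

#' One physical corn ear after instance grouping
#'
#' Groups a whole-ear region (detected directly in Approach 1, or the union
#' of assigned parts in Approach 2) with its bare-cob and kernel part masks
#' and the ear's side on the feeding stand.
#'
#' @param earBox Half-open box of the ear.
#' @param wholeMask Logical matrix of the whole visible ear.
#' @param bareParts,kernelParts Lists of logical part masks.
#' @param side `"left"`, `"right"`, `"only"` (single ear) or `"middle"`.
#' @return An `EarGroup`.
#' @export
EarGroup <- function(earBox, wholeMask, bareParts = list(),
                     kernelParts = list(), side = "only") {
  new("EarGroup",
    earBox = as.integer(earBox), wholeMask = wholeMask,
    bareParts = bareParts, kernelParts = kernelParts, side = side
  )
}

#' @rdname SyntheticScene-class
#' @export
setClass("SyntheticScene", representation(
  image = "ANY",
  sceneA1 = "AnnotatedScene",
  sceneA2 = "AnnotatedScene",
  truth = "data.frame",
  spec = "list"
))

#' @rdname SyntheticDataset-class
#' @export
setClass("SyntheticDataset", representation(
  scenes = "list",
  truth = "data.frame",
  seed = "integer",
  params = "list"
))

setValidity("SyntheticDataset", function(object) {
  if (!all(vapply(object@scenes, is, logical(1), class2 = "SyntheticScene"))) {
    return("scenes must be a list of SyntheticScene objects")
  }
  TRUE
})

#' @rdname EvalReport-class
#' @export
setClass("EvalReport", representation(
  meanIoU = "numeric",
  mAP = "numeric",
  prCurves = "list",
  r2 = "numeric",
  outlierCount = "integer",
  confusion = "matrix",
  records = "data.frame",
  verdicts = "data.frame",
  params = "list"
))

#' @rdname AblationResult-class
#' @export
setClass("AblationResult", representation(
  summary = "data.frame",
  tests = "data.frame",
  sizes = "integer",
  repeats = "integer",
  seed = "integer"
))
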