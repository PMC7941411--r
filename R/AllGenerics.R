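#' Accessors for CobQuant containers
#'
#' Small generics giving read access to the slots of the S4 containers:
#' `imageId()`, `detections()`, `instances()`, `approach()`, `imageShape()`,
#' `truth()`, `labelOf()`, `maskOf()`, `boxOf()`, `scoreOf()`, `sideOf()`.
#'
#' @param x A CobQuant object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("imageId", function(x) standardGeneric("imageId"))
#' @rdname accessors
#' @export
setGeneric("detections", function(x) standardGeneric("detections"))
#' @rdname accessors
#' @export
setGeneric("instances", function(x) standardGeneric("instances"))
#' @rdname accessors
#' @export
setGeneric("approach", function(x) standardGeneric("approach"))
#' @rdname accessors
#' @export
setGeneric("imageShape", function(x) standardGeneric("imageShape"))
#' @rdname accessors
#' @export
setGeneric("truth", function(x) standardGeneric("truth"))
#' @rdname accessors
#' @export
setGeneric("labelOf", function(x) standardGeneric("labelOf"))
#' @rdname accessors
#' @export
setGeneric("maskOf", function(x) standardGeneric("maskOf"))
#' @rdname accessors
#' @export
setGeneric("boxOf", function(x) standardGeneric("boxOf"))
#' @rdname accessors
#' @export
setGeneric("scoreOf", function(x) standardGeneric("scoreOf"))
#' @rdname accessors
#' @export
setGeneric("sideOf", function(x) standardGeneric("sideOf"))

#' @rdname accessors
setMethod("labelOf", "Detection", function(x) x@label)
#' @rdname accessors
setMethod("maskOf", "Detection", function(x) x@mask)
#' @rdname accessors
setMethod("boxOf", "Detection", function(x) x@box)
#' @rdname accessors
setMethod("scoreOf", "Detection", function(x) x@score)

#' @rdname accessors
setMethod("imageId", "DetectionSet", function(x) x@imageId)
#' @rdname accessors
setMethod("detections", "DetectionSet", function(x) x@detections)

#' @rdname accessors
setMethod("imageId", "AnnotatedScene", function(x) x@imageId)
#' @rdname accessors
setMethod("instances", "AnnotatedScene", function(x) x@instances)
#' @rdname accessors
setMethod("approach", "AnnotatedScene", function(x) x@approach)
#' @rdname accessors
setMethod("imageShape", "AnnotatedScene", function(x) x@imageShape)

#' @rdname accessors
setMethod("maskOf", "EarGroup", function(x) x@wholeMask)
#' @rdname accessors
setMethod("boxOf", "EarGroup", function(x) x@earBox)
#' @rdname accessors
setMethod("sideOf", "EarGroup", function(x) x@side)

#' @rdname accessors
setMethod("truth", "SyntheticScene", function(x) x@truth)
#' @rdname accessors
setMethod("truth", "SyntheticDataset", function(x) x@truth)

#' @rdname accessors
#' @export
setMethod("length", "DetectionSet", function(x) length(x@detections))
#' @rdname accessors
#' @export
setMethod("length", "SyntheticDataset", function(x) length(x@scenes))
#' @rdname accessors
#' @export
setMethod("[[", "SyntheticDataset", function(x, i) x@scenes[[i]])

setMethod("show", "Detection", function(object) {
  cat(sprintf(
    "Detection '%s': area %d px, box [%d,%d)x[%d,%d), score %.3f\n",
    object@label, sum(object@mask),
    object@box[1], object@box[3], object@box[2], object@box[4], object@score
  ))
})

setMethod("show", "DetectionSet", function(object) {
  labs <- vapply(object@detections, slot, character(1), name = "label")
  cat(sprintf(
    "DetectionSet '%s' (%s): %d detections\n",
    object@imageId, object@source, length(object@detections)
  ))
  if (length(labs)) {
    tab <- table(labs)
    cat("  ", paste(names(tab), as.integer(tab), sep = ":", collapse = ", "), "\n")
  }
})

setMethod("show", "AnnotatedScene", function(object) {
  labs <- vapply(object@instances, function(i) i$label, character(1))
  cat(sprintf(
    "AnnotatedScene '%s' (approach %d, %dx%d): %d instances%s\n",
    object@imageId, object@approach,
    object@imageShape[1], object@imageShape[2], length(labs),
    if (length(labs)) paste0(" [", paste(labs, collapse = ", "), "]") else ""
  ))
})

setMethod("show", "EarGroup", function(object) {
  cat(sprintf(
    "EarGroup (%s): whole %d px, %d bare part(s), %d kernel part(s)\n",
    object@side, sum(object@wholeMask),
    length(object@bareParts), length(object@kernelParts)
  ))
})

setMethod("show", "SyntheticScene", function(object) {
  cat(sprintf(
    "SyntheticScene '%s' (%dx%d, %s): %d ear(s), true consumption %s%%\n",
    object@sceneA1@imageId,
    object@sceneA1@imageShape[1], object@sceneA1@imageShape[2],
    if (is.null(object@image)) "masks only" else "rendered",
    nrow(object@truth), paste(round(object@truth$true_pct, 1), collapse = "/")
  ))
})

setMethod("show", "SyntheticDataset", function(object) {
  cat(sprintf(
    "SyntheticDataset: %d scenes, %d ears, seed %d\n",
    length(object@scenes), nrow(object@truth), object@seed
  ))
  if (nrow(object@truth)) {
    cat("  category mix:", paste(
      names(table(object@truth$category)),
      as.integer(table(object@truth$category)),
      sep = "=", collapse = ", "
    ), "\n")
  }
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport\n")
  if (length(object@meanIoU)) {
    cat("  weighted mean IoU:", paste(names(object@meanIoU),
      round(object@meanIoU, 4),
      sep = "=", collapse = ", "
    ), "\n")
  }
  cat(sprintf("  mAP: %.4f\n", object@mAP))
  cat(sprintf(
    "  consumption R^2: %.4f (%d outlier ear(s) excluded)\n",
    object@r2, object@outlierCount
  ))
  if (length(object@confusion)) {
    cat(sprintf(
      "  left-right agreement: %d/%d\n",
      sum(diag(object@confusion)), sum(object@confusion)
    ))
  }
})

setMethod("show", "AblationResult", function(object) {
  cat(sprintf(
    "AblationResult: sizes %s, %d repeats, seed %d\n",
    paste(object@sizes, collapse = "/"), object@repeats, object@seed
  ))
  print(object@summary)
})
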