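## Segmentation backends. The trained network of the original workflow is
## represented only by its output contract (readDetections()); for
## desk-scale end-to-end runs a classical HSV-threshold +
## connected-component backend produces DetectionSets directly from images,
## and a ground-truth passthrough turns annotations into perfect detections.

#' Configure a segmentation backend
#'
#' @param backend `"ground_truth"`, `"color_cc"` or `"external"`.
#' @param kernelHue,bareHue Hue ranges in degrees (0-360) classifying kernel
#'   and bare-cob pixels; defaults match the synthetic palette (yellow
#'   kernels, red-brown cob).
#' @param kernelSat,bareSat Saturation ranges in \[0, 1\].
#' @param kernelVal,bareVal Minimum HSV value.
#' @param minArea Minimum instance area in pixels; smaller components are
#'   discarded as speckle.
#' @param morphRadius Radius of the disc used for morphological
#'   opening/closing (0 disables morphology).
#' @param scoreRule `"area_normalized"` (component area over largest
#'   component area of its class) or `"constant"` (all scores 1).
#' @param minScore Score threshold applied to external-manifest detections
#'   before estimation. It is deliberately not applied to the color
#'   backend, whose area-normalized scores rank instances rather than grade
#'   confidence.
#' @param resizeTo Optional side length: preprocess images through
#'   [resizeWithPad()] at this size and map detections back to original
#'   coordinates.
#' @param manifest Path to a detection manifest (required for
#'   `backend = "external"`).
#' @return A list of class `cq_backend_config`.
#' @export
backendConfig <- function(backend = c("ground_truth", "color_cc", "external"),
                          kernelHue = c(35, 75), kernelSat = c(0.30, 1), kernelVal = 0.12,
                          bareHue = c(0, 32), bareSat = c(0.12, 0.95), bareVal = 0.15,
                          minArea = 50L, morphRadius = 1L,
                          scoreRule = c("area_normalized", "constant"),
                          minScore = 0.5, resizeTo = NULL, manifest = NULL) {
  backend <- match.arg(backend)
  scoreRule <- match.arg(scoreRule)
  stopifnot(minArea >= 1, morphRadius >= 0)
  for (rng in list(kernelHue, bareHue)) {
    if (length(rng) != 2L || rng[1] > rng[2] || rng[1] < 0 || rng[2] > 360) {
      stop("hue ranges must be c(lo, hi) within [0, 360]")
    }
  }
  structure(
    list(
      backend = backend,
      kernelHue = kernelHue, kernelSat = kernelSat, kernelVal = kernelVal,
      bareHue = bareHue, bareSat = bareSat, bareVal = bareVal,
      minArea = as.integer(minArea), morphRadius = as.integer(morphRadius),
      scoreRule = scoreRule, minScore = minScore,
      resizeTo = resizeTo, manifest = manifest
    ),
    class = "cq_backend_config"
  )
}

#' Ground-truth passthrough backend
#'
#' Rasterizes every annotated instance of a scene into a [Detection] with
#' score 1 — the oracle against which the rest of the pipeline is checked.
#'
#' @param scene An [AnnotatedScene-class].
#' @return A [DetectionSet-class] with source `"ground_truth"`.
#' @export
segmentGroundTruth <- function(scene) {
  dets <- lapply(rasterizeInstances(scene), function(inst) {
    Detection(inst$label, inst$mask, score = 1)
  })
  DetectionSet(scene@imageId, dets, source = "ground_truth")
}

## Classify pixels of an RGB array into kernel/bare maps by HSV thresholds.
classifyPixels <- function(image, config) {
  H <- dim(image)[1]
  W <- dim(image)[2]
  rgb <- rbind(
    as.vector(image[, , 1]),
    as.vector(image[, , 2]),
    as.vector(image[, , 3])
  )
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  hue <- hsv[1, ] * 360
  sat <- hsv[2, ]
  val <- hsv[3, ]
  kernel <- hue >= config$kernelHue[1] & hue <= config$kernelHue[2] &
    sat >= config$kernelSat[1] & sat <= config$kernelSat[2] &
    val >= config$kernelVal
  bare <- hue >= config$bareHue[1] & hue <= config$bareHue[2] &
    sat >= config$bareSat[1] & sat <= config$bareSat[2] &
    val >= config$bareVal
  bare <- bare & !kernel
  list(
    kernel = matrix(kernel, H, W),
    bare = matrix(bare, H, W)
  )
}

## Morphological open + close with a disc brush, then connected components
## at or above the minimum area.
cleanComponents <- function(map, config) {
  if (config$morphRadius > 0) {
    brush <- EBImage::makeBrush(2L * config$morphRadius + 1L, shape = "disc")
    map <- EBImage::closing(EBImage::opening(map * 1, brush), brush) > 0.5
  }
  comps <- maskComponents(map)
  Filter(function(m) sum(m) >= config$minArea, comps)
}

#' Classical color/connected-component backend
#'
#' Classifies pixels into kernel, bare-cob and background by HSV ranges,
#' cleans each class map by morphological opening and closing, and turns
#' connected components above the minimum area into detections. For
#' Approach 1 the whole-ear instances are the connected components of the
#' union of the kernel and bare maps (mirroring how the two part classes sum
#' to a whole ear); for Approach 2 kernel and bare components are emitted
#' directly. Scores are component area normalized by the largest component
#' of the same class. Fully deterministic.
#'
#' @param image RGB array (H x W x 3, values in \[0, 1\]).
#' @param config A [backendConfig()].
#' @param approachUsed Labeling approach of the emitted detections (1 or 2).
#' @param imageId Identifier for the resulting set.
#' @return A [DetectionSet-class] with source `"builtin_backend"`; empty when
#'   the image contains no corn-colored pixels.
#' @export
segmentColorCC <- function(image, config = backendConfig("color_cc"),
                           approachUsed = 1, imageId = "image") {
  maps <- classifyPixels(image, config)
  bareComps <- cleanComponents(maps$bare, config)
  dets <- list()
  addClass <- function(dets, comps, label) {
    if (!length(comps)) return(dets)
    areas <- vapply(comps, sum, numeric(1))
    for (i in seq_along(comps)) {
      score <- if (config$scoreRule == "area_normalized") areas[i] / max(areas) else 1
      dets[[length(dets) + 1L]] <- Detection(label, comps[[i]], score = score)
    }
    dets
  }
  if (approachUsed == 1) {
    wholeComps <- cleanComponents(maps$kernel | maps$bare, config)
    dets <- addClass(dets, wholeComps, "whole_corn")
  } else {
    kernelComps <- cleanComponents(maps$kernel, config)
    dets <- addClass(dets, kernelComps, "corn_kernel")
  }
  dets <- addClass(dets, bareComps, "bare_cob")
  DetectionSet(imageId, dets, source = "builtin_backend")
}

#' Run a segmentation backend over a dataset
#'
#' Uniform dispatch over the three backends. With `config$resizeTo` set, the
#' color backend sees the square-padded resize of each image and the
#' resulting masks are mapped back to original resolution, so detections are
#' always returned in original-image coordinates. The external backend reads
#' `config$manifest` and fails with a coverage error naming any image id the
#' manifest does not cover; its detections below `config$minScore` are
#' dropped.
#'
#' @param dataset A [SyntheticDataset-class], or a list of
#'   [SyntheticScene-class] objects, or (for `ground_truth`) a list of
#'   [AnnotatedScene-class] objects.
#' @param config A [backendConfig()].
#' @param approachUsed Labeling approach for ground-truth/color detections.
#' @return List of [DetectionSet-class] objects, one per image.
#' @export
runBackend <- function(dataset, config = backendConfig(), approachUsed = 1) {
  scenes <- if (is(dataset, "SyntheticDataset")) dataset@scenes else dataset
  annotated <- function(s) {
    if (is(s, "SyntheticScene")) {
      if (approachUsed == 1) s@sceneA1 else s@sceneA2
    } else {
      s
    }
  }
  if (config$backend == "ground_truth") {
    return(lapply(scenes, function(s) segmentGroundTruth(annotated(s))))
  }
  if (config$backend == "color_cc") {
    return(lapply(scenes, function(s) {
      img <- if (is(s, "SyntheticScene")) s@image else s$image
      if (is.null(img)) stop("color_cc backend needs rendered images")
      id <- if (is(s, "SyntheticScene")) s@sceneA1@imageId else (s$imageId %||% "image")
      if (is.null(config$resizeTo)) {
        segmentColorCC(img, config, approachUsed, imageId = id)
      } else {
        geom <- resizeWithPad(img, config$resizeTo, kind = "image")
        ds <- segmentColorCC(geom$image, config, approachUsed, imageId = id)
        dets <- lapply(ds@detections, function(d) {
          m <- unpadMask(d@mask, geom)
          if (!any(m)) return(NULL)
          Detection(d@label, m, score = d@score)
        })
        DetectionSet(id, Filter(Negate(is.null), dets), source = "builtin_backend")
      }
    }))
  }
  # external manifest
  if (is.null(config$manifest)) stop("external backend requires config$manifest")
  sets <- readDetections(config$manifest)
  names(sets) <- vapply(sets, imageId, character(1))
  ids <- vapply(scenes, function(s) imageId(annotated(s)), character(1))
  missing <- setdiff(ids, names(sets))
  if (length(missing)) {
    stopCoverage(
      "detection manifest does not cover ", length(missing),
      " image(s): ", paste(missing, collapse = ", ")
    )
  }
  lapply(sets[ids], function(ds) {
    keep <- Filter(function(d) d@score >= config$minScore, ds@detections)
    DetectionSet(ds@imageId, keep, source = ds@source)
  })
}
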