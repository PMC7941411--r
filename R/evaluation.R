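## Segmentation and estimation metrics: greedy instance matching, per-class
## area-weighted mean IoU, COCO-style average precision over an IoU-threshold
## sweep, pooled precision-recall curves, consumption R^2 with outlier
## exclusion, the left-right confusion matrix, and the sample-size ablation
## harness with Welch t-tests.

asDetList <- function(x) if (is(x, "DetectionSet")) x@detections else x

#' Greedy one-to-one instance matching
#'
#' Predictions, taken in descending score order, each claim the unclaimed
#' ground-truth instance of the same class with the highest mask IoU,
#' provided that IoU reaches the threshold — the matching underlying true
#' positives, false positives and false negatives at that threshold.
#'
#' @param preds,gts [DetectionSet-class] objects or lists of [Detection]s.
#' @param threshold IoU threshold `t`.
#' @return `list(pairs = data.frame(pred, gt, iou), unmatchedPreds,
#'   unmatchedGts, threshold)`, indices into the score-sorted prediction
#'   list and the ground-truth list.
#' @export
matchInstances <- function(preds, gts, threshold) {
  preds <- asDetList(preds)
  gts <- asDetList(gts)
  if (length(preds) > 1L) {
    preds <- preds[order(-vapply(preds, slot, numeric(1), name = "score"))]
  }
  gtFree <- rep(TRUE, length(gts))
  pairs <- data.frame(pred = integer(), gt = integer(), iou = numeric())
  for (i in seq_along(preds)) {
    best <- 0
    bestJ <- 0L
    for (j in seq_along(gts)) {
      if (!gtFree[j] || gts[[j]]@label != preds[[i]]@label) next
      iou <- maskIoU(preds[[i]]@mask, gts[[j]]@mask)
      if (iou > best) {
        best <- iou
        bestJ <- j
      }
    }
    if (bestJ > 0L && best >= threshold) {
      gtFree[bestJ] <- FALSE
      pairs <- rbind(pairs, data.frame(pred = i, gt = bestJ, iou = best))
    }
  }
  list(
    pairs = pairs,
    unmatchedPreds = setdiff(seq_along(preds), pairs$pred),
    unmatchedGts = which(gtFree),
    threshold = threshold
  )
}

## Area under a PR walk by all-point interpolation: at each recall step the
## precision envelope to the right is used.
apFromPR <- function(recall, precision) {
  if (!length(recall)) return(0)
  penv <- rev(cummax(rev(precision)))
  sum(diff(c(0, recall)) * penv)
}

#' Average precision for one image
#'
#' Walks predictions in descending score order, accumulating true and false
#' positives under [matchInstances()] at the given IoU threshold (classes
#' pooled, matching class-aware), and integrates the precision-recall walk
#' by all-point interpolation. Defined as 1 for an image with neither ground
#' truth nor predictions and 0 when predictions exist without ground truth.
#'
#' @inheritParams matchInstances
#' @return AP in \[0, 1\].
#' @export
averagePrecision <- function(preds, gts, threshold) {
  preds <- asDetList(preds)
  gts <- asDetList(gts)
  if (!length(gts)) return(if (length(preds)) 0 else 1)
  if (!length(preds)) return(0)
  mr <- matchInstances(preds, gts, threshold)
  tp <- seq_along(preds) %in% mr$pairs$pred
  cumTP <- cumsum(tp)
  recall <- cumTP / length(gts)
  precision <- cumTP / seq_along(preds)
  apFromPR(recall, precision)
}

#' Mean average precision over an IoU-threshold sweep
#'
#' The default sweep is thresholds 0.50 to 0.95 in steps of 0.05. In
#' `"per_image"` mode (default) the AP of each image is averaged over
#' thresholds and then over images; `"pooled"` mode ranks all predictions of
#' the dataset together per threshold before averaging over thresholds.
#'
#' @param predSets,gtSets Parallel lists of [DetectionSet-class] objects.
#' @param thresholds IoU thresholds.
#' @param mode `"per_image"` or `"pooled"`.
#' @return mAP in \[0, 1\].
#' @export
meanAveragePrecision <- function(predSets, gtSets,
                                 thresholds = seq(0.5, 0.95, by = 0.05),
                                 mode = c("per_image", "pooled")) {
  mode <- match.arg(mode)
  if (!length(gtSets)) stop("empty dataset")
  if (mode == "per_image") {
    perImage <- vapply(seq_along(gtSets), function(i) {
      mean(vapply(
        thresholds,
        function(t) averagePrecision(predSets[[i]], gtSets[[i]], t),
        numeric(1)
      ))
    }, numeric(1))
    mean(perImage)
  } else {
    mean(vapply(thresholds, function(t) {
      attr(prCurve(predSets, gtSets, t), "ap")
    }, numeric(1)))
  }
}

#' Pooled precision-recall curve
#'
#' All predictions of the dataset are ranked together by score; each is a
#' true or false positive under per-image greedy matching at the threshold.
#' The `"ap"` attribute holds the all-point interpolated area under the
#' walk, which equals the pooled-dataset AP at that threshold.
#'
#' @inheritParams meanAveragePrecision
#' @param threshold IoU threshold.
#' @return data.frame with `threshold`, `score`, `recall`, `precision`
#'   (recall non-decreasing), and attribute `"ap"`.
#' @export
prCurve <- function(predSets, gtSets, threshold) {
  scores <- numeric()
  isTP <- logical()
  nGT <- 0L
  for (i in seq_along(gtSets)) {
    preds <- asDetList(predSets[[i]])
    gts <- asDetList(gtSets[[i]])
    nGT <- nGT + length(gts)
    if (!length(preds)) next
    ord <- order(-vapply(preds, slot, numeric(1), name = "score"))
    preds <- preds[ord]
    mr <- matchInstances(preds, gts, threshold)
    scores <- c(scores, vapply(preds, slot, numeric(1), name = "score"))
    isTP <- c(isTP, seq_along(preds) %in% mr$pairs$pred)
  }
  ord <- order(-scores)
  scores <- scores[ord]
  isTP <- isTP[ord]
  cumTP <- cumsum(isTP)
  out <- data.frame(
    threshold = threshold,
    score = scores,
    recall = if (nGT > 0) cumTP / nGT else rep(0, length(cumTP)),
    precision = if (length(cumTP)) cumTP / seq_along(cumTP) else numeric()
  )
  attr(out, "ap") <- if (nGT == 0L) {
    if (length(scores)) 0 else 1
  } else {
    apFromPR(out$recall, out$precision)
  }
  out
}

#' @rdname prCurve
#' @param curve A data.frame returned by `prCurve()`.
#' @return `prArea()`: the all-point interpolated area under the curve.
#' @export
prArea <- function(curve) apFromPR(curve$recall, curve$precision)

#' Area-weighted mean IoU for one class
#'
#' Per image containing the class in ground truth: class instances are
#' matched greedily (any positive overlap), each ground-truth instance
#' contributes its matched IoU (0 when missed) weighted by its pixel area,
#' and the weighted mean is taken; images are then averaged unweighted.
#' `weight = "uniform"` drops the area weighting.
#'
#' @inheritParams meanAveragePrecision
#' @param class Class label to evaluate.
#' @param weight `"area"` or `"uniform"`.
#' @return Fraction in \[0, 1\], or `NA` (with a warning) when the class is
#'   absent from the whole dataset.
#' @export
weightedMeanIoU <- function(predSets, gtSets, class, weight = c("area", "uniform")) {
  weight <- match.arg(weight)
  vals <- numeric()
  for (i in seq_along(gtSets)) {
    gts <- Filter(function(d) d@label == class, asDetList(gtSets[[i]]))
    if (!length(gts)) next
    preds <- Filter(function(d) d@label == class, asDetList(predSets[[i]]))
    mr <- matchInstances(preds, gts, threshold = 1e-9)
    ious <- rep(0, length(gts))
    ious[mr$pairs$gt] <- mr$pairs$iou
    w <- if (weight == "area") {
      vapply(gts, function(g) sum(g@mask), numeric(1))
    } else {
      rep(1, length(gts))
    }
    vals <- c(vals, sum(w * ious) / sum(w))
  }
  if (!length(vals)) {
    warning("class '", class, "' absent from the ground truth of every image; IoU undefined")
    return(NA_real_)
  }
  mean(vals)
}

#' Coefficient of determination of estimated vs true consumption
#'
#' R-squared of the least-squares linear fit of predicted on ground-truth
#' consumption, with flagged outlier ears (and missing estimates) excluded
#' before fitting.
#'
#' @param pred,gt Numeric vectors of percentages.
#' @param outlier Logical vector flagging records to exclude (default none).
#' @return R-squared, or `NA` (with a warning) when fewer than two usable
#'   pairs remain.
#' @export
rSquared <- function(pred, gt, outlier = NULL) {
  if (is.null(outlier)) outlier <- rep(FALSE, length(pred))
  keep <- !outlier & !is.na(pred) & !is.na(gt)
  if (sum(keep) < 2L) {
    warning("fewer than two non-outlier pairs; R^2 undefined")
    return(NA_real_)
  }
  fit <- lm(pred[keep] ~ gt[keep])
  ssres <- sum(stats::residuals(fit)^2)
  sstot <- sum((pred[keep] - mean(pred[keep]))^2)
  # a flat prediction vector explains none of its (zero) variance
  if (sstot == 0) return(0)
  r2 <- 1 - ssres / sstot
  if (!is.finite(r2)) NA_real_ else r2
}

#' Left-right confusion matrix
#'
#' Rows are ground-truth verdicts, columns predicted verdicts, both over
#' `{left, equal, right}`; the trace counts agreeing images.
#'
#' @param predVerdicts,gtVerdicts data.frames from [pairVerdicts()] over the
#'   same image set.
#' @return 3 x 3 integer matrix.
#' @export
confusionMatrixLR <- function(predVerdicts, gtVerdicts) {
  if (!setequal(predVerdicts$image_id, gtVerdicts$image_id)) {
    stop(
      "pairing error: verdict image sets differ (",
      length(setdiff(gtVerdicts$image_id, predVerdicts$image_id)), " missing, ",
      length(setdiff(predVerdicts$image_id, gtVerdicts$image_id)), " extra)"
    )
  }
  lv <- c("left", "equal", "right")
  m <- match(gtVerdicts$image_id, predVerdicts$image_id)
  tab <- table(
    factor(gtVerdicts$verdict, levels = lv),
    factor(predVerdicts$verdict[m], levels = lv)
  )
  mat <- matrix(as.integer(tab), 3, 3, dimnames = list(gt = lv, pred = lv))
  mat
}

#' Welch two-sided t-test on repeat-level metrics
#'
#' Unequal-variance t-test comparing the metric values of two ablation
#' groups. When both groups are constant, equal means give `p = 1` by
#' convention (and differing means `p = 0`).
#'
#' @param a,b Numeric vectors, at least two values each.
#' @return Named vector `c(t = , p = )`.
#' @export
ttestCompare <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    return(c(t = NA_real_, p = NA_real_))
  }
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(c(t = 0, p = 1))
    }
    return(c(t = sign(mean(a) - mean(b)) * Inf, p = 0))
  }
  ht <- t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  c(t = unname(ht$statistic), p = ht$p.value)
}

#' Degrade ground-truth detections
#'
#' The pluggable stand-in for segmentation models of varying quality used by
#' the ablation harness: each instance mask is eroded by a radius and
#' translated by Gaussian pixel noise scaled by `severity`, bare-cob
#' instances are dropped with a severity-dependent probability (emulating
#' the missed-segmentation failures seen with small training sets), and
#' scores are drawn in \[0.55, 1\]. Instances degraded to emptiness vanish.
#'
#' @param detSet A ground-truth [DetectionSet-class].
#' @param severity Non-negative degradation level; 0 returns an equivalent
#'   set with shuffled scores.
#' @return A degraded [DetectionSet-class].
#' @export
degradeDetections <- function(detSet, severity) {
  rad <- max(0L, as.integer(round(severity)))
  pDrop <- min(0.2, severity^2 / 40)
  brush <- if (rad > 0) EBImage::makeBrush(2L * rad + 1L, shape = "disc") else NULL
  dets <- list()
  for (d in detSet@detections) {
    if (d@label == "bare_cob" && runif(1) < pDrop) next
    m <- d@mask
    if (!is.null(brush)) m <- EBImage::erode(m * 1, brush) > 0.5
    shift <- round(rnorm(2, 0, severity))
    if (any(shift != 0)) m <- shiftMask(m, shift[1], shift[2])
    if (!any(m)) next
    dets[[length(dets) + 1L]] <- Detection(d@label, m, score = runif(1, 0.55, 1))
  }
  DetectionSet(detSet@imageId, dets, source = "external_model")
}

## Translate a mask by (dr, dc), filling with FALSE.
shiftMask <- function(m, dr, dc) {
  H <- nrow(m)
  W <- ncol(m)
  out <- matrix(FALSE, H, W)
  srcR <- seq_len(H) - dr
  srcC <- seq_len(W) - dc
  okR <- srcR >= 1L & srcR <= H
  okC <- srcC >= 1L & srcC <= W
  out[okR, okC] <- m[srcR[okR], srcC[okC]]
  out
}

## Stratified subsample of scene indices proportional to the dataset's own
## category composition (largest remainder), without replacement.
stratifiedSample <- function(categories, size) {
  cats <- c("0-5%", "5-95%", "95-100%")
  counts <- vapply(cats, function(cc) sum(categories == cc), integer(1))
  if (any(counts == 0L)) {
    stop(
      "stratification error: dataset has no scenes in category ",
      paste(cats[counts == 0L], collapse = ", ")
    )
  }
  alloc <- allocateCounts(size, counts / sum(counts))
  alloc <- pmin(alloc, counts)
  short <- size - sum(alloc)
  while (short > 0L) { # redistribute when a small stratum saturates
    room <- which(alloc < counts)
    alloc[room[1]] <- alloc[room[1]] + 1L
    short <- short - 1L
  }
  unlist(lapply(seq_along(cats), function(k) {
    idx <- which(categories == cats[k])
    idx[sample.int(length(idx), alloc[k])]
  }))
}

#' Sample-size ablation harness
#'
#' Emulates the design of training-set-size experiments at desk scale: for
#' each size, `repeats` stratified random subsamples (proportional to the
#' dataset's category composition) are drawn; a quality model — by default
#' [degradeDetections()] with severity `4 / sqrt(size)`, so quality improves
#' with size — stands in for a model trained on that subsample; and
#' segmentation plus estimation metrics are computed on the subsample.
#' Metrics are aggregated as mean and standard deviation over repeats, with
#' two-sided Welch t-tests between consecutive sizes. Reproducible from
#' `seed`.
#'
#' @param dataset A [SyntheticDataset-class] (images not required).
#' @param sizes Strictly increasing subsample sizes, each at most the
#'   dataset size.
#' @param repeats Repeats per size (>= 2).
#' @param seed Integer seed.
#' @param qualityModel `function(detSet, size)` returning degraded
#'   detections; `NULL` for the default.
#' @param approachUsed Labeling approach to evaluate (default 1).
#' @return An [AblationResult-class] with `summary` (size, metric, mean, sd)
#'   and `tests` (metric, size pair, t, p).
#' @export
runAblation <- function(dataset, sizes, repeats = 5L, seed = 1L,
                        qualityModel = NULL, approachUsed = 1) {
  sizes <- as.integer(sizes)
  stopifnot(
    repeats >= 2L, length(sizes) >= 1L,
    all(diff(sizes) > 0L), max(sizes) <= length(dataset@scenes)
  )
  if (is.null(qualityModel)) {
    qualityModel <- function(detSet, size) {
      degradeDetections(detSet, severity = 4 / sqrt(size))
    }
  }
  categories <- vapply(dataset@scenes, function(s) s@truth$category[1], character(1))
  metricNames <- c("bare_cob_iou", "whole_corn_iou", "map", "r2")
  values <- array(NA_real_,
    dim = c(length(sizes), repeats, length(metricNames)),
    dimnames = list(sizes, NULL, metricNames)
  )
  run <- 0L
  for (si in seq_along(sizes)) {
    for (rp in seq_len(repeats)) {
      run <- run + 1L
      withSeed(deriveSeed(seed, run), {
        idx <- stratifiedSample(categories, sizes[si])
        scenes <- dataset@scenes[idx]
        gtSets <- lapply(scenes, function(s) {
          segmentGroundTruth(if (approachUsed == 1) s@sceneA1 else s@sceneA2)
        })
        predSets <- lapply(gtSets, qualityModel, size = sizes[si])
        classes <- approachClasses(approachUsed)
        values[si, rp, "bare_cob_iou"] <- weightedMeanIoU(predSets, gtSets, "bare_cob")
        values[si, rp, "whole_corn_iou"] <- weightedMeanIoU(predSets, gtSets, classes[1])
        values[si, rp, "map"] <- meanAveragePrecision(predSets, gtSets)
        rec <- estimateConsumption(predSets, approachUsed = approachUsed)
        flagged <- detectOutliers(rec, do.call(rbind, lapply(scenes, truth)))
        values[si, rp, "r2"] <- suppressWarnings(
          rSquared(flagged$consumption_pct, flagged$true_pct, flagged$outlier)
        )
      })
    }
  }
  summary <- do.call(rbind, lapply(seq_along(sizes), function(si) {
    data.frame(
      size = sizes[si],
      metric = metricNames,
      mean = apply(values[si, , , drop = FALSE], 3, mean, na.rm = TRUE),
      sd = apply(values[si, , , drop = FALSE], 3, sd, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  }))
  rownames(summary) <- NULL
  tests <- NULL
  if (length(sizes) >= 2L) {
    tests <- do.call(rbind, lapply(seq_len(length(sizes) - 1L), function(si) {
      do.call(rbind, lapply(metricNames, function(mn) {
        tv <- ttestCompare(values[si, , mn], values[si + 1L, , mn])
        data.frame(
          metric = mn, size_a = sizes[si], size_b = sizes[si + 1L],
          t = tv[["t"]], p = tv[["p"]], stringsAsFactors = FALSE
        )
      }))
    }))
  } else {
    tests <- data.frame(
      metric = character(), size_a = integer(), size_b = integer(),
      t = numeric(), p = numeric(), stringsAsFactors = FALSE
    )
  }
  new("AblationResult",
    summary = summary, tests = tests,
    sizes = sizes, repeats = as.integer(repeats), seed = as.integer(seed)
  )
}

#' Evaluate predictions against a synthetic dataset
#'
#' Bundles the metric suite into one report: per-class area-weighted mean
#' IoU, mAP over the standard threshold sweep, pooled PR curves, per-ear
#' consumption records with outlier flags, R-squared (outliers excluded) and
#' the left-right confusion matrix (over the images for which both
#' ground-truth and predicted verdicts exist).
#'
#' @param predSets List of [DetectionSet-class] objects, one per scene.
#' @param dataset The [SyntheticDataset-class] the predictions refer to.
#' @param approachUsed 1 or 2.
#' @param thresholds IoU sweep for mAP.
#' @param prAt Thresholds at which PR curves are kept.
#' @param tolerance Percentage-point tolerance for left-right verdicts.
#' @return An [EvalReport-class].
#' @export
evaluateDataset <- function(predSets, dataset, approachUsed = 1,
                            thresholds = seq(0.5, 0.95, by = 0.05),
                            prAt = c(0.5, 0.75), tolerance = 0) {
  gtSets <- lapply(dataset@scenes, function(s) {
    segmentGroundTruth(if (approachUsed == 1) s@sceneA1 else s@sceneA2)
  })
  classes <- approachClasses(approachUsed)
  miou <- vapply(classes, function(cl) {
    suppressWarnings(weightedMeanIoU(predSets, gtSets, cl))
  }, numeric(1))
  curves <- lapply(prAt, function(t) prCurve(predSets, gtSets, t))
  names(curves) <- paste0("iou_", prAt)
  rec <- estimateConsumption(predSets, approachUsed = approachUsed)
  flagged <- detectOutliers(rec, dataset@truth)
  r2 <- suppressWarnings(
    rSquared(flagged$consumption_pct, flagged$true_pct, flagged$outlier)
  )
  predV <- pairVerdicts(flagged, tolerance = tolerance)
  gtV <- pairVerdicts(
    data.frame(
      image_id = dataset@truth$image_id, side = dataset@truth$side,
      consumption_pct = dataset@truth$true_pct, stringsAsFactors = FALSE
    ),
    tolerance = tolerance
  )
  common <- intersect(predV$image_id, gtV$image_id)
  conf <- confusionMatrixLR(
    predV[predV$image_id %in% common, ],
    gtV[gtV$image_id %in% common, ]
  )
  new("EvalReport",
    meanIoU = miou,
    mAP = meanAveragePrecision(predSets, gtSets, thresholds),
    prCurves = curves,
    r2 = r2,
    outlierCount = sum(flagged$outlier),
    confusion = conf,
    records = flagged,
    verdicts = predV,
    params = list(
      approach = approachUsed, thresholds = thresholds,
      tolerance = tolerance
    )
  )
}

#' Write an evaluation report to disk
#'
#' Serializes an [EvalReport-class] as `report.json` plus CSV tables
#' (per-ear records, verdicts, PR curves, confusion matrix).
#'
#' @param report An [EvalReport-class].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
writeEvalReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(
      mean_iou = as.list(report@meanIoU),
      map = report@mAP,
      r_squared = report@r2,
      outliers = report@outlierCount,
      confusion = list(
        labels = rownames(report@confusion),
        counts = unname(apply(report@confusion, 1, as.list))
      ),
      params = report@params
    ),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, na = "null"
  )
  rec <- report@records
  rec$consumption_pct <- round(rec$consumption_pct, 1)
  rec$true_pct <- round(rec$true_pct, 1)
  write.csv(rec, file.path(dir, "per_ear.csv"), row.names = FALSE)
  write.csv(report@verdicts, file.path(dir, "pair_verdicts.csv"), row.names = FALSE)
  pr <- do.call(rbind, report@prCurves)
  write.csv(pr, file.path(dir, "pr_curves.csv"), row.names = FALSE)
  cm <- as.data.frame(report@confusion)
  write.csv(cm, file.path(dir, "confusion.csv"), row.names = TRUE)
  invisible(dir)
}
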