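# Independent brute-force oracles and shared fixtures. Oracles deliberately
# re-derive every quantity from first principles (per-pixel tests, explicit
# greedy walks, closed-form algebra) so they share no code path with the
# package implementations they check.

# Even-odd ray-casting point-in-polygon test for a single point.
oraclePointInPolygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py)) {
      xcross <- xi + (py - yi) * (xj - xi) / (yj - yi)
      if (px < xcross) inside <- !inside
    }
    j <- i
  }
  inside
}

# Rasterize by testing every pixel center.
oracleMaskFromPolygon <- function(poly, shape) {
  m <- matrix(FALSE, shape[1], shape[2])
  for (r in seq_len(shape[1]) - 1L) {
    for (cc in seq_len(shape[2]) - 1L) {
      m[r + 1L, cc + 1L] <- oraclePointInPolygon(cc + 0.5, r + 0.5, poly)
    }
  }
  m
}

# IoU from explicit pixel index sets.
oracleIoU <- function(a, b) {
  ia <- which(a)
  ib <- which(b)
  u <- union(ia, ib)
  if (!length(u)) return(0)
  length(intersect(ia, ib)) / length(u)
}

# Greedy matching + PR walk + interpolated area, written independently:
# detections are (label, mask, score) lists.
oracleAveragePrecision <- function(preds, gts, t) {
  if (!length(gts)) return(if (length(preds)) 0 else 1)
  if (!length(preds)) return(0)
  ord <- order(-vapply(preds, function(p) p$score, numeric(1)))
  claimed <- rep(FALSE, length(gts))
  tp <- logical(length(preds))
  for (k in seq_along(ord)) {
    p <- preds[[ord[k]]]
    bestIoU <- -1
    bestJ <- 0
    for (j in seq_along(gts)) {
      if (claimed[j] || gts[[j]]$label != p$label) next
      iou <- oracleIoU(p$mask, gts[[j]]$mask)
      if (iou > bestIoU) {
        bestIoU <- iou
        bestJ <- j
      }
    }
    if (bestJ > 0 && bestIoU >= t) {
      claimed[bestJ] <- TRUE
      tp[k] <- TRUE
    }
  }
  nTP <- cumsum(tp)
  rec <- nTP / length(gts)
  prec <- nTP / seq_along(tp)
  # area under the PR walk, integrating max precision at recall >= r
  ap <- 0
  prevR <- 0
  for (k in seq_along(rec)) {
    if (rec[k] > prevR) {
      ap <- ap + (rec[k] - prevR) * max(prec[k:length(prec)])
      prevR <- rec[k]
    }
  }
  ap
}

# Area-weighted mean IoU for one class of one image, from first principles:
# greedy matching by score with any positive overlap, then the GT-area
# weighted mean of matched IoUs (missed instances contribute 0).
oracleWeightedMeanIoU <- function(preds, gts, class) {
  gts <- Filter(function(d) d$label == class, gts)
  if (!length(gts)) return(NULL)
  preds <- Filter(function(d) d$label == class, preds)
  ord <- if (length(preds)) order(-vapply(preds, function(p) p$score, numeric(1))) else integer()
  ious <- rep(0, length(gts))
  claimed <- rep(FALSE, length(gts))
  for (k in ord) {
    best <- 0
    bestJ <- 0
    for (j in seq_along(gts)) {
      if (claimed[j]) next
      iou <- oracleIoU(preds[[k]]$mask, gts[[j]]$mask)
      if (iou > best) {
        best <- iou
        bestJ <- j
      }
    }
    if (bestJ > 0 && best > 0) {
      claimed[bestJ] <- TRUE
      ious[bestJ] <- best
    }
  }
  w <- vapply(gts, function(g) sum(g$mask), numeric(1))
  sum(w * ious) / sum(w)
}

# Two-parameter least squares in closed form.
oracleRSquared <- function(pred, gt) {
  beta <- sum((gt - mean(gt)) * (pred - mean(pred))) / sum((gt - mean(gt))^2)
  alpha <- mean(pred) - beta * mean(gt)
  ssres <- sum((pred - alpha - beta * gt)^2)
  sstot <- sum((pred - mean(pred))^2)
  1 - ssres / sstot
}

# Random rectangle-mask detections on a small grid.
randomDetections <- function(nPred, nGt, shape = c(24L, 24L),
                             labels = c("whole_corn", "bare_cob")) {
  randMask <- function() {
    m <- matrix(FALSE, shape[1], shape[2])
    r0 <- sample.int(shape[1] - 4L, 1)
    c0 <- sample.int(shape[2] - 4L, 1)
    m[r0:(r0 + sample.int(4, 1)), c0:(c0 + sample.int(4, 1))] <- TRUE
    m
  }
  gts <- lapply(seq_len(nGt), function(i) {
    list(label = sample(labels, 1), mask = randMask(), score = 1)
  })
  preds <- lapply(seq_len(nPred), function(i) {
    base <- if (nGt > 0 && runif(1) < 0.7) gts[[sample.int(nGt, 1)]]$mask else randMask()
    mask <- base
    if (runif(1) < 0.6) { # jitter: drop or add a band of rows
      rows <- which(apply(mask, 1, any))
      if (length(rows) > 2 && runif(1) < 0.5) mask[rows[1], ] <- FALSE
    }
    if (!any(mask)) mask <- randMask()
    list(label = sample(labels, 1), mask = mask, score = runif(1))
  })
  list(preds = preds, gts = gts)
}

asDetectionList <- function(raw) {
  lapply(raw, function(d) Detection(d$label, d$mask, score = d$score))
}

# A tiny deterministic mask helper.
blockMask <- function(shape, rows, cols) {
  m <- matrix(FALSE, shape[1], shape[2])
  m[rows, cols] <- TRUE
  m
}

# ---------------------------------------------------------------------------
# Shared 50-scene synthetic suite (fixed seed, clean scenes, bare fractions
# uniform on [0, 1]). Generated once per test run, streaming scene by scene:
# ground-truth estimates for both approaches, color-backend estimates, and
# left/right verdicts, with the heavyweight masks discarded immediately.
acceptanceSuite <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) {
      return(cache)
    }
    specs <- sceneSpecs(50, categoryMix = NULL, seed = 101)
    truthAll <- list()
    estGt1 <- list()
    estGt2 <- list()
    estColor <- list()
    for (i in seq_along(specs)) {
      sc <- generateScene(specs[[i]], render = TRUE)
      truthAll[[i]] <- truth(sc)
      gt1 <- segmentGroundTruth(sc@sceneA1)
      gt2 <- segmentGroundTruth(sc@sceneA2)
      col1 <- segmentColorCC(sc@image, backendConfig("color_cc"),
        approachUsed = 1, imageId = imageId(sc@sceneA1)
      )
      estGt1[[i]] <- estimateConsumption(list(gt1), approachUsed = 1)
      estGt2[[i]] <- estimateConsumption(list(gt2), approachUsed = 2)
      estColor[[i]] <- estimateConsumption(list(col1), approachUsed = 1)
    }
    cache <<- list(
      truth = do.call(rbind, truthAll),
      gt1 = do.call(rbind, estGt1),
      gt2 = do.call(rbind, estGt2),
      color = do.call(rbind, estColor)
    )
    cache
  }
})
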