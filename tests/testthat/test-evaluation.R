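shape16 <- c(16L, 16L)

test_that("matching is greedy by score, class-aware and one-to-one", {
  gt <- blockMask(shape16, 3:10, 3:10)
  predGood <- blockMask(shape16, 3:10, 4:11) # IoU 7/9 ~ 0.78
  predBetter <- blockMask(shape16, 3:10, 3:10) # IoU 1
  # single pred at IoU ~0.6 matches at t = 0.5 but not t = 0.65
  pred06 <- blockMask(shape16, 3:10, 5:12) # IoU 6/10 = 0.6
  mr <- matchInstances(
    list(Detection("bare_cob", pred06, 0.9)),
    list(Detection("bare_cob", gt, 1)), 0.5
  )
  expect_identical(nrow(mr$pairs), 1L)
  mr2 <- matchInstances(
    list(Detection("bare_cob", pred06, 0.9)),
    list(Detection("bare_cob", gt, 1)), 0.65
  )
  expect_identical(nrow(mr2$pairs), 0L)
  expect_identical(mr2$unmatchedPreds, 1L)
  expect_identical(mr2$unmatchedGts, 1L)
  # two preds on one GT: the higher-scored one claims it even at lower IoU
  mr3 <- matchInstances(
    list(
      Detection("bare_cob", predGood, 0.9), # score order first, IoU 0.78
      Detection("bare_cob", predBetter, 0.8) # IoU 1.0 but scored lower
    ),
    list(Detection("bare_cob", gt, 1)), 0.5
  )
  expect_identical(mr3$pairs$pred, 1L)
  expect_identical(mr3$unmatchedPreds, 2L)
  # disjoint class sets yield an empty matching, not an error
  mr4 <- matchInstances(
    list(Detection("whole_corn", predGood, 0.9)),
    list(Detection("bare_cob", gt, 1)), 0.1
  )
  expect_identical(nrow(mr4$pairs), 0L)
})

test_that("average precision reproduces hand-walked PR areas", {
  gt <- list(Detection("bare_cob", blockMask(shape16, 3:10, 3:10), 1))
  hit <- Detection("bare_cob", blockMask(shape16, 3:10, 3:10), 0.9)
  missMask <- blockMask(shape16, 12:15, 12:15)
  # single correct prediction
  expect_identical(averagePrecision(list(hit), gt, 0.5), 1)
  # higher-scored correct + lower FP: recall 1 reached at precision 1
  fp <- Detection("bare_cob", missMask, 0.8)
  expect_identical(averagePrecision(list(hit, fp), gt, 0.5), 1)
  # FP outscores the hit: recall 1 first reached at precision 0.5
  fpHigh <- Detection("bare_cob", missMask, 0.95)
  hitLow <- Detection("bare_cob", blockMask(shape16, 3:10, 3:10), 0.7)
  expect_identical(averagePrecision(list(fpHigh, hitLow), gt, 0.5), 0.5)
  # edge conventions
  expect_identical(averagePrecision(list(), gt, 0.5), 0)
  expect_identical(averagePrecision(list(hit), list(), 0.5), 0)
  expect_identical(averagePrecision(list(), list(), 0.5), 1)
})

test_that("average precision agrees with the brute-force oracle", {
  set.seed(51)
  for (case in 1:200) {
    raw <- randomDetections(sample(0:6, 1), sample(0:6, 1))
    t <- sample(c(0.3, 0.5, 0.75), 1)
    got <- averagePrecision(asDetectionList(raw$preds), asDetectionList(raw$gts), t)
    expect_equal(got, oracleAveragePrecision(raw$preds, raw$gts, t), tolerance = 1e-12)
  }
})

test_that("weighted mean IoU follows the area-weighted definition", {
  # one image: GT areas 100 and 300 at IoUs 0.8 and 0.6 -> 0.65
  gtA <- blockMask(c(40L, 40L), 1:10, 1:10) # 100 px
  gtB <- blockMask(c(40L, 40L), 21:35, 11:30) # 300 px
  predA <- blockMask(c(40L, 40L), 1:10, 2:11) # IoU 80/120... adjust below
  # construct exact IoUs: predA overlaps 9x10=90, union 110 -> not 0.8;
  # use row trimming for exact fractions: IoU 0.8 = 8/10 rows overlap of a
  # 10x10 with an 8x10 sub-block? IoU = 80/100 = 0.8 with pred inside gt.
  predA <- blockMask(c(40L, 40L), 1:8, 1:10) # IoU 80/100 = 0.8
  predB <- blockMask(c(40L, 40L), 21:29, 11:30) # 180/300 = 0.6
  pred <- list(Detection("bare_cob", predA, 0.9), Detection("bare_cob", predB, 0.8))
  gt <- list(Detection("bare_cob", gtA, 1), Detection("bare_cob", gtB, 1))
  got <- weightedMeanIoU(list(pred), list(gt), "bare_cob")
  expect_equal(got, (100 * 0.8 + 300 * 0.6) / 400)
  expect_equal(weightedMeanIoU(list(pred), list(gt), "bare_cob", weight = "uniform"),
               0.7)
  # perfect predictions give exactly 1
  expect_identical(weightedMeanIoU(list(gt), list(gt), "bare_cob"), 1)
  # a fully missed single-instance image contributes 0
  expect_identical(
    weightedMeanIoU(
      list(list(), list(gt[[1]])),
      list(list(gt[[1]]), list(gt[[1]])), "bare_cob"
    ),
    0.5
  )
  expect_warning(
    expect_identical(weightedMeanIoU(list(pred), list(gt), "corn_kernel"), NA_real_),
    "absent"
  )
})

test_that("mAP endpoints and threshold monotonicity behave", {
  ds <- generateDataset(3, seed = 61, imageSizes = list(c(96L, 128L)), render = FALSE)
  gtSets <- runBackend(ds, backendConfig("ground_truth"))
  expect_identical(meanAveragePrecision(gtSets, gtSets), 1)
  none <- lapply(gtSets, function(s) DetectionSet(imageId(s), list(), "external_model"))
  expect_identical(meanAveragePrecision(none, gtSets), 0)
  # degraded detections: per-threshold AP is non-increasing in the threshold
  set.seed(62)
  pred <- lapply(gtSets, degradeDetections, severity = 1.2)
  aps <- vapply(seq(0.5, 0.95, 0.05), function(t) {
    mean(vapply(seq_along(gtSets), function(i) {
      averagePrecision(pred[[i]], gtSets[[i]], t)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(aps) <= 1e-12))
  # hence a grid shifted upward can never score higher
  expect_lte(
    meanAveragePrecision(pred, gtSets, seq(0.6, 0.95, 0.05)),
    meanAveragePrecision(pred, gtSets, seq(0.5, 0.95, 0.05)) + 1e-12
  )
  expect_error(meanAveragePrecision(list(), list()), "empty")
})

test_that("the pooled PR curve integrates to the pooled AP", {
  ds <- generateDataset(3, seed = 63, imageSizes = list(c(96L, 128L)), render = FALSE)
  gtSets <- runBackend(ds, backendConfig("ground_truth"))
  set.seed(64)
  pred <- lapply(gtSets, degradeDetections, severity = 1)
  for (t in c(0.5, 0.75)) {
    curve <- prCurve(pred, gtSets, t)
    expect_true(all(diff(curve$recall) >= 0))
    expect_true(all(curve$precision >= 0 & curve$precision <= 1))
    expect_equal(prArea(curve), attr(curve, "ap"), tolerance = 1e-9)
  }
  # perfect detector: single plateau at precision 1 up to recall 1
  curvePerfect <- prCurve(gtSets, gtSets, 0.5)
  expect_true(all(curvePerfect$precision == 1))
  expect_identical(max(curvePerfect$recall), 1)
  expect_identical(attr(curvePerfect, "ap"), 1)
  # pooled mAP path uses the same area
  expect_equal(
    meanAveragePrecision(pred, gtSets, 0.5, mode = "pooled"),
    attr(prCurve(pred, gtSets, 0.5), "ap")
  )
})

test_that("R-squared comes from the least-squares fit, outliers excluded", {
  expect_equal(rSquared(c(1, 30, 70, 99), c(1, 30, 70, 99)), 1)
  # exactly collinear but not on y = x: still a perfect fit
  expect_equal(rSquared(c(10, 50, 90), c(0, 50, 100)), 1)
  # constant predictions explain nothing
  expect_lte(rSquared(c(50, 50, 50), c(0, 50, 100)), 0)
  # outlier exclusion changes the fit
  pred <- c(0, 25, 50, 75, 0)
  gt <- c(0, 25, 50, 75, 100)
  expect_equal(rSquared(pred, gt, outlier = c(FALSE, FALSE, FALSE, FALSE, TRUE)), 1)
  expect_lt(rSquared(pred, gt), 1)
  expect_warning(expect_identical(rSquared(1, 1), NA_real_), "fewer than two")
})

test_that("R-squared matches the closed-form solution on random vectors", {
  set.seed(71)
  for (case in 1:60) {
    n <- sample(3:20, 1)
    gt <- runif(n, 0, 100)
    pred <- 0.9 * gt + rnorm(n, 0, 10)
    expect_equal(rSquared(pred, gt), oracleRSquared(pred, gt), tolerance = 1e-10)
  }
})

test_that("the left-right confusion matrix counts verdict agreement", {
  gtV <- data.frame(
    image_id = c("a", "b", "c", "d"),
    verdict = c("left", "equal", "right", "right"), stringsAsFactors = FALSE
  )
  expect_identical(sum(diag(confusionMatrixLR(gtV, gtV))), 4L)
  predV <- gtV
  predV$verdict[2] <- "right" # the 99-vs-98 style miss on an equal pair
  cm <- confusionMatrixLR(predV, gtV)
  expect_identical(sum(cm), 4L)
  expect_identical(cm["equal", "right"], 1L)
  expect_identical(sum(diag(cm)), 3L)
  expect_error(confusionMatrixLR(predV[-1, ], gtV), "pairing error")
})

test_that("the Welch comparison behaves at its conventions", {
  expect_identical(ttestCompare(c(0.5, 0.5), c(0.5, 0.5)), c(t = 0, p = 1))
  set.seed(81)
  a <- 0.1 + rnorm(5, 0, 1e-3)
  b <- 0.9 + rnorm(5, 0, 1e-3)
  res <- ttestCompare(a, b)
  expect_lt(res[["p"]], 0.01)
  swapped <- ttestCompare(b, a)
  expect_equal(swapped[["t"]], -res[["t"]])
  expect_equal(swapped[["p"]], res[["p"]])
  # cross-check against stats::t.test directly
  ht <- t.test(a, b)
  expect_equal(res[["t"]], unname(ht$statistic))
  expect_equal(res[["p"]], ht$p.value)
})

test_that("the ablation harness aggregates, tests and reproduces", {
  ds <- generateDataset(12,
    categoryMix = c(0.4, 0.4, 0.2), seed = 91,
    imageSizes = list(c(96L, 128L)), render = FALSE
  )
  res <- runAblation(ds, sizes = c(4L, 8L), repeats = 2L, seed = 5L)
  expect_s4_class(res, "AblationResult")
  expect_identical(nrow(res@summary), 8L) # 2 sizes x 4 metrics
  expect_true(all(is.finite(res@summary$mean)))
  expect_identical(nrow(res@tests), 4L)
  expect_true(all(res@tests$p >= 0 & res@tests$p <= 1))
  res2 <- runAblation(ds, sizes = c(4L, 8L), repeats = 2L, seed = 5L)
  expect_identical(res@summary, res2@summary)
  # default quality model improves with size: mean mAP is non-decreasing
  res3 <- runAblation(ds, sizes = c(3L, 10L), repeats = 3L, seed = 7L)
  mAPs <- res3@summary$mean[res3@summary$metric == "map"]
  expect_gte(mAPs[2], mAPs[1])
})

test_that("stratified ablation rejects datasets missing a category", {
  ds <- generateDataset(6,
    categoryMix = c(1, 0, 0), seed = 92,
    imageSizes = list(c(96L, 128L)), render = FALSE
  )
  expect_error(runAblation(ds, sizes = 3L, repeats = 2L), "stratification error")
})

test_that("evaluateDataset bundles a perfect ground-truth report", {
  ds <- generateDataset(4, seed = 93, imageSizes = list(c(96L, 128L)), render = FALSE)
  gtSets <- runBackend(ds, backendConfig("ground_truth"))
  report <- evaluateDataset(gtSets, ds)
  expect_s4_class(report, "EvalReport")
  expect_identical(unname(report@meanIoU), c(1, 1))
  expect_identical(report@mAP, 1)
  expect_equal(report@r2, 1)
  expect_identical(report@outlierCount, 0L)
  expect_identical(sum(diag(report@confusion)), 4L)
  # serialization writes the expected artifacts
  out <- withr::local_tempdir()
  writeEvalReport(report, out)
  expect_true(all(file.exists(file.path(
    out, c("report.json", "per_ear.csv", "pair_verdicts.csv", "pr_curves.csv", "confusion.csv")
  ))))
  js <- jsonlite::fromJSON(file.path(out, "report.json"))
  expect_equal(js$map, 1)
  expect_equal(js$r_squared, 1)
})
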