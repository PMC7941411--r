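# Fixture: two ears as rectangles with bare parts fully inside known ears,
# built so overlap assignment is unambiguous and checkable by containment.
twoEarFixture <- function() {
  shape <- c(40L, 60L)
  earL <- blockMask(shape, 5:35, 5:20) # left ear
  earR <- blockMask(shape, 5:35, 35:50) # right ear
  bareL1 <- blockMask(shape, 6:10, 6:12)
  bareL2 <- blockMask(shape, 20:24, 8:14)
  bareR1 <- blockMask(shape, 30:34, 40:46)
  DetectionSet("fix", list(
    Detection("whole_corn", earL, 1),
    Detection("whole_corn", earR, 0.95),
    Detection("bare_cob", bareL1, 0.9),
    Detection("bare_cob", bareL2, 0.85),
    Detection("bare_cob", bareR1, 0.8)
  ))
}

test_that("approach-1 grouping assigns bare parts to their containing ear", {
  groups <- groupInstancesApproach1(twoEarFixture())
  expect_length(groups, 2)
  expect_identical(vapply(groups, sideOf, character(1)), c("left", "right"))
  expect_length(groups[[1]]@bareParts, 2) # both left bare parts
  expect_length(groups[[2]]@bareParts, 1)
  # containment oracle: every assigned part lies inside its ear mask
  for (g in groups) {
    for (b in g@bareParts) expect_identical(sum(b & g@wholeMask), sum(b))
  }
})

test_that("a straddling bare part goes to the majority-overlap ear", {
  shape <- c(30L, 60L)
  earL <- blockMask(shape, 5:25, 5:24)
  earR <- blockMask(shape, 5:25, 27:46)
  # 10-column bare band: 7 columns over the left ear, 2 over the right
  bare <- blockMask(shape, 10:14, 18:27)
  ds <- DetectionSet("straddle", list(
    Detection("whole_corn", earL, 1),
    Detection("whole_corn", earR, 0.9),
    Detection("bare_cob", bare, 0.8)
  ))
  groups <- groupInstancesApproach1(ds)
  expect_length(groups[[1]]@bareParts, 1)
  expect_length(groups[[2]]@bareParts, 0)
})

test_that("bare parts below the assignment threshold are reported, not dropped", {
  shape <- c(30L, 40L)
  ear <- blockMask(shape, 5:25, 5:15)
  stray <- blockMask(shape, 10:14, 25:35) # no overlap with the ear
  ds <- DetectionSet("stray", list(
    Detection("whole_corn", ear, 1),
    Detection("bare_cob", stray, 0.8)
  ))
  expect_message(groups <- groupInstancesApproach1(ds), "unassigned")
  expect_length(groups, 1)
  expect_length(groups[[1]]@bareParts, 0)
  expect_length(attr(groups, "unassigned"), 1)
})

test_that("single-ear images get side 'only'; bare with no ear is an error", {
  ds <- DetectionSet("solo", list(
    Detection("whole_corn", blockMask(c(20, 20), 3:17, 5:14), 1)
  ))
  groups <- groupInstancesApproach1(ds)
  expect_length(groups, 1)
  expect_identical(sideOf(groups[[1]]), "only")
  expect_length(groups[[1]]@bareParts, 0)

  bad <- DetectionSet("lost", list(
    Detection("bare_cob", blockMask(c(20, 20), 3:8, 5:9), 1)
  ))
  expect_error(groupInstancesApproach1(bad), "grouping error")
})

test_that("approach-2 clustering joins nearby parts and separates distant ears", {
  shape <- c(60L, 400L)
  kernelA <- blockMask(shape, 10:50, 20:60)
  bareA <- blockMask(shape, 10:50, 61:80) # adjacent to kernelA
  kernelB <- blockMask(shape, 10:50, 300:340) # far to the right
  ds <- DetectionSet("a2", list(
    Detection("corn_kernel", kernelA, 1),
    Detection("bare_cob", bareA, 0.9),
    Detection("corn_kernel", kernelB, 0.8)
  ))
  groups <- groupInstancesApproach2(ds, margin = 5)
  expect_length(groups, 2)
  left <- groups[[which(vapply(groups, sideOf, character(1)) == "left")]]
  expect_identical(sum(left@wholeMask), sum(kernelA) + sum(bareA)) # disjoint union
  expect_length(left@bareParts, 1)
  # graph-connectivity oracle: dilated boxes of A-parts intersect, B's do not
  expect_true(CobQuant:::boxesIntersect(tightBox(kernelA), tightBox(bareA), 5L))
  expect_false(CobQuant:::boxesIntersect(tightBox(kernelA), tightBox(kernelB), 5L))
  expect_length(groupInstancesApproach2(DetectionSet("empty", list())), 0)
})

test_that("consumption ratio implements the pixel-count rule", {
  shape <- c(50L, 40L)
  whole <- blockMask(shape, 1:40, 1:25) # 1000 px
  bare1 <- blockMask(shape, 1:16, 1:25) # 400 px inside
  bare2 <- blockMask(shape, 17:24, 1:25) # 200 px inside
  g <- EarGroup(tightBox(whole), whole, list(bare1, bare2))
  expect_equal(consumptionRatio(g, 1), 60)
  expect_identical(consumptionRatio(EarGroup(tightBox(whole), whole), 1), 0)
  # noisy bare exceeding the whole is clipped at 100
  noisy <- blockMask(shape, 1:44, 1:25) # 1100 px, 1000 inside
  gNoisy <- EarGroup(tightBox(whole), whole, list(noisy))
  expect_identical(consumptionRatio(gNoisy, 1), 100)
  # overlapping bare detections are unioned, not double counted
  gDup <- EarGroup(tightBox(whole), whole, list(bare1, bare1))
  expect_equal(consumptionRatio(gDup, 1), 40)
})

test_that("approach-2 ratio uses summed part pixels", {
  shape <- c(30L, 30L)
  kernel <- blockMask(shape, 1:10, 1:10) # 100
  bare <- blockMask(shape, 15:24, 1:30) # 300
  g <- EarGroup(c(0L, 0L, 30L, 30L), kernel | bare,
    bareParts = list(bare), kernelParts = list(kernel)
  )
  expect_equal(consumptionRatio(g, 2), 75)
  # sum rule: consumption plus kernel share is exactly 100
  kernelShare <- 100 * sum(kernel) / (sum(kernel) + sum(bare))
  expect_identical(consumptionRatio(g, 2) + kernelShare, 100)
  gEmpty <- EarGroup(c(0L, 0L, 30L, 30L), kernel, list(), list())
  expect_error(consumptionRatio(gEmpty, 2), "undefined")
})

test_that("adding an interior bare part never decreases consumption", {
  set.seed(31)
  shape <- c(40L, 40L)
  whole <- blockMask(shape, 5:35, 5:35)
  parts <- list()
  prev <- 0
  for (k in 1:6) {
    r0 <- sample(5:30, 1)
    c0 <- sample(5:30, 1)
    parts[[k]] <- blockMask(shape, r0:min(35, r0 + 4), c0:min(35, c0 + 4))
    g <- EarGroup(tightBox(whole), whole, parts)
    cur <- consumptionRatio(g, 1)
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("left-right comparison reproduces the marginal 98-vs-99 case", {
  expect_identical(compareLeftRight(98, 99, tolerance = 0), "right")
  expect_identical(compareLeftRight(50, 50), "equal")
  expect_identical(compareLeftRight(60, 40), "left")
  expect_identical(compareLeftRight(98, 99, tolerance = 2), "equal")
  expect_error(compareLeftRight(-1, 50))
})

test_that("pair categorization follows the pre-screening rules", {
  expect_identical(categorizePair(2, 50), "5-95%") # mixed pair
  expect_identical(categorizePair(0, 0), "0-5%")
  expect_identical(categorizePair(100, 96), "95-100%")
  expect_error(categorizePair(-2, 10), "0, 100")
  expect_error(categorizePair(10, 101), "0, 100")
})

test_that("categorization matches a table-lookup oracle on random pairs", {
  oracleCat <- function(c1, c2) {
    lows <- c(c1 <= 5, c2 <= 5)
    highs <- c(c1 >= 95, c2 >= 95)
    if (all(lows)) "0-5%" else if (all(highs)) "95-100%" else "5-95%"
  }
  set.seed(32)
  for (case in 1:200) {
    c1 <- runif(1, 0, 100)
    c2 <- sample(c(runif(1, 0, 100), runif(1, 0, 5), runif(1, 95, 100)), 1)
    expect_identical(categorizePair(c1, c2), oracleCat(c1, c2))
  }
})

test_that("outlier detection flags missed classes and missed ears", {
  gt <- data.frame(
    image_id = c("a", "a", "b"), side = c("left", "right", "only"),
    true_pct = c(100, 40, 0), n_bare_parts = c(1L, 2L, 0L),
    stringsAsFactors = FALSE
  )
  # right ear of 'a' fine; left ear predicted with no bare instance (the
  # fully consumed ear the model saw as whole corn only); 'b' fine with no
  # bare anywhere
  pred <- data.frame(
    image_id = c("a", "a", "b"), side = c("left", "right", "only"),
    consumption_pct = c(0, 38, 0), n_bare_parts = c(0L, 2L, 0L),
    stringsAsFactors = FALSE
  )
  flagged <- detectOutliers(pred, gt)
  expect_identical(flagged$outlier, c(TRUE, FALSE, FALSE))
  expect_match(flagged$reason[1], "no bare instance")

  # an entirely missed ear is an outlier with NA estimate
  predMiss <- pred[-1, ]
  flagged2 <- detectOutliers(predMiss, gt)
  expect_true(flagged2$outlier[1])
  expect_true(is.na(flagged2$consumption_pct[1]))
  expect_match(flagged2$reason[1], "not detected")

  # a predicted ear with no ground-truth counterpart is a pairing error
  predExtra <- rbind(pred, data.frame(
    image_id = "c", side = "only", consumption_pct = 10,
    n_bare_parts = 1L, stringsAsFactors = FALSE
  ))
  expect_error(detectOutliers(predExtra, gt), "pairing error")
})

test_that("pair verdicts pull left and right records per image", {
  rec <- data.frame(
    image_id = c("a", "a", "b", "c", "c"),
    side = c("left", "right", "only", "left", "right"),
    consumption_pct = c(20, 80, 50, 66, 66),
    stringsAsFactors = FALSE
  )
  v <- pairVerdicts(rec)
  expect_identical(nrow(v), 2L) # single-ear image contributes no pair
  expect_identical(v$verdict[v$image_id == "a"], "right")
  expect_identical(v$verdict[v$image_id == "c"], "equal")
})
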