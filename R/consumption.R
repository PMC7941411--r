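## The core estimator: assign segmented part instances to individual corn
## ears, compute the per-ear consumption percentage (bare-cob pixels over
## whole-ear pixels), compare left versus right ears and classify pairs into
## the pre-screening categories.

## Order groups left-to-right by the horizontal center of their boxes and
## attach sides. Ties (vertically stacked ears) break by top-most = left,
## flagged as unusual.
assignSides <- function(groups) {
  if (!length(groups)) return(groups)
  if (length(groups) == 1L) {
    groups[[1]]@side <- "only"
    return(groups)
  }
  xc <- vapply(groups, function(g) (g@earBox[2] + g@earBox[4]) / 2, numeric(1))
  yc <- vapply(groups, function(g) (g@earBox[1] + g@earBox[3]) / 2, numeric(1))
  if (anyDuplicated(xc)) {
    cqMessage("ears share a horizontal center; breaking the left/right tie top-most first")
  }
  ord <- order(xc, yc)
  sides <- rep("middle", length(groups))
  sides[ord[1]] <- "left"
  sides[ord[length(ord)]] <- "right"
  for (i in seq_along(groups)) groups[[i]]@side <- sides[i]
  groups[ord]
}

#' Group Approach-1 detections into ears
#'
#' Every `whole_corn` detection seeds one ear; each `bare_cob` detection is
#' assigned to the ear whose whole-corn mask overlaps the largest fraction
#' of the bare mask, provided that fraction reaches `threshold`. Assignment
#' is by mask overlap rather than raw bounding-box containment: boxes of
#' side-by-side ears frequently intersect, and mask overlap reduces to the
#' box rule whenever boxes are disjoint. Unassigned bare parts are returned
#' in the `"unassigned"` attribute (and messaged), never silently dropped.
#'
#' @param dets A [DetectionSet-class] with classes `whole_corn`/`bare_cob`.
#' @param threshold Minimum overlap fraction of a bare mask with an ear's
#'   whole mask for assignment (default 0.5).
#' @return List of [EarGroup-class] objects ordered left to right, with an
#'   `"unassigned"` attribute listing unassigned bare detections.
#' @export
groupInstancesApproach1 <- function(dets, threshold = 0.5) {
  wholes <- Filter(function(d) d@label == "whole_corn", dets@detections)
  bares <- Filter(function(d) d@label == "bare_cob", dets@detections)
  if (!length(wholes)) {
    if (length(bares)) {
      stop(
        "grouping error: image '", dets@imageId, "' has ", length(bares),
        " bare_cob detection(s) but no whole_corn detection; estimation impossible"
      )
    }
    return(structure(list(), unassigned = list()))
  }
  assigned <- vector("list", length(wholes))
  unassigned <- list()
  for (b in bares) {
    frac <- vapply(wholes, function(w) sum(b@mask & w@mask) / sum(b@mask), numeric(1))
    best <- which.max(frac)
    if (frac[best] >= threshold) {
      assigned[[best]] <- c(assigned[[best]], list(b@mask))
    } else {
      unassigned <- c(unassigned, list(b))
    }
  }
  if (length(unassigned)) {
    cqMessage(
      "image '", dets@imageId, "': ", length(unassigned),
      " bare part(s) overlap no ear above threshold ", threshold, "; left unassigned"
    )
  }
  groups <- lapply(seq_along(wholes), function(i) {
    EarGroup(
      earBox = wholes[[i]]@box, wholeMask = wholes[[i]]@mask,
      bareParts = assigned[[i]] %||% list()
    )
  })
  structure(assignSides(groups), unassigned = unassigned)
}

#' Group Approach-2 detections into ears
#'
#' Kernel and bare parts carry no whole-ear detection, so parts are
#' clustered into ears by single linkage on the box-overlap graph: two parts
#' are linked iff their bounding boxes, dilated by `margin` pixels,
#' intersect. Each cluster becomes one ear whose whole mask is the union of
#' its member masks.
#'
#' @param dets A [DetectionSet-class] with classes `corn_kernel`/`bare_cob`.
#' @param margin Box dilation in pixels before testing intersection
#'   (default 5).
#' @return List of [EarGroup-class] objects ordered left to right.
#' @export
groupInstancesApproach2 <- function(dets, margin = 5L) {
  parts <- dets@detections
  if (!length(parts)) return(list())
  n <- length(parts)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i && boxesIntersect(parts[[i]]@box, parts[[j]]@box, margin = margin)) {
        adj[i, j] <- adj[j, i] <- TRUE
      }
    }
  }
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  )$membership
  groups <- lapply(seq_len(max(comp)), function(k) {
    members <- parts[comp == k]
    whole <- Reduce(`|`, lapply(members, slot, "mask"))
    box <- Reduce(boxUnion, lapply(members, slot, "box"))
    EarGroup(
      earBox = box, wholeMask = whole,
      bareParts = lapply(Filter(function(d) d@label == "bare_cob", members), slot, "mask"),
      kernelParts = lapply(Filter(function(d) d@label == "corn_kernel", members), slot, "mask")
    )
  })
  assignSides(groups)
}

#' Per-ear consumption percentage
#'
#' Approach 1: 100 times the pixels of the union of the ear's bare parts
#' (intersected with the whole-ear mask, which clips protruding noise and
#' never double-counts overlapping detections) over the pixels of the whole
#' ear, clipped to \[0, 100\]. Approach 2: 100 times the summed bare-part
#' pixels over the summed bare plus kernel pixels — the whole ear being
#' defined as the sum of its parts.
#'
#' @param group An [EarGroup-class].
#' @param approachUsed 1 or 2.
#' @return Percentage in \[0, 100\].
#' @export
consumptionRatio <- function(group, approachUsed = 1) {
  if (approachUsed == 1) {
    whole <- sum(group@wholeMask)
    if (whole == 0) stop("consumption undefined: whole mask is empty")
    if (!length(group@bareParts)) return(0)
    bare <- sum(Reduce(`|`, group@bareParts) & group@wholeMask)
    min(100, max(0, 100 * bare / whole))
  } else {
    bare <- sum(vapply(group@bareParts, sum, numeric(1)))
    kernel <- sum(vapply(group@kernelParts, sum, numeric(1)))
    if (bare + kernel == 0) {
      stop("consumption undefined: approach-2 ear with zero total part pixels")
    }
    100 * bare / (bare + kernel)
  }
}

#' Compare left and right ear consumption
#'
#' Returns `"equal"` iff the absolute difference is within `tolerance`
#' percentage points, otherwise the side with the larger consumption. The
#' default tolerance of 0 reproduces the strict behavior under which a
#' 99%-vs-98% pair is classified `"right"`.
#'
#' @param leftPct,rightPct Percentages in \[0, 100\].
#' @param tolerance Percentage points treated as a tie.
#' @return `"left"`, `"right"` or `"equal"`.
#' @examples
#' compareLeftRight(98, 99) # "right"
#' @export
compareLeftRight <- function(leftPct, rightPct, tolerance = 0) {
  stopifnot(
    leftPct >= 0, leftPct <= 100,
    rightPct >= 0, rightPct <= 100
  )
  if (abs(leftPct - rightPct) <= tolerance) {
    "equal"
  } else if (leftPct > rightPct) {
    "left"
  } else {
    "right"
  }
}

#' Categorize a pair of consumptions
#'
#' The pre-screening rule used to stratify the image pool: both ears at most
#' 5% consumed is `"0-5%"`, both at least 95% is `"95-100%"`, and everything
#' else — including mixed pairs such as one untouched and one half-eaten ear
#' — is `"5-95%"`.
#'
#' @param c1,c2 Percentages in \[0, 100\].
#' @return One of `"0-5%"`, `"5-95%"`, `"95-100%"`.
#' @export
categorizePair <- function(c1, c2) {
  if (any(c(c1, c2) < 0) || any(c(c1, c2) > 100)) {
    stop("consumption percentages must be in [0, 100]")
  }
  if (c1 <= 5 && c2 <= 5) {
    "0-5%"
  } else if (c1 >= 95 && c2 >= 95) {
    "95-100%"
  } else {
    "5-95%"
  }
}

#' Estimate consumption for a set of detections
#'
#' Runs grouping and the consumption ratio over a list of detection sets,
#' yielding one record per detected ear.
#'
#' @param detSets List of [DetectionSet-class] objects.
#' @param approachUsed 1 or 2.
#' @param threshold Assignment threshold for Approach-1 grouping.
#' @param margin Box-dilation margin for Approach-2 clustering.
#' @return data.frame with columns `image_id`, `side`, `consumption_pct`,
#'   `n_bare_parts`, `n_whole` (or `n_kernel_parts`), `whole_area`,
#'   `outlier`, `reason`. Images where grouping fails (bare parts with no
#'   whole ear) yield zero rows and a message; the outlier pass against
#'   ground truth flags the gap.
#' @export
estimateConsumption <- function(detSets, approachUsed = 1, threshold = 0.5, margin = 5L) {
  rows <- lapply(detSets, function(ds) {
    groups <- tryCatch(
      if (approachUsed == 1) {
        groupInstancesApproach1(ds, threshold = threshold)
      } else {
        groupInstancesApproach2(ds, margin = margin)
      },
      error = function(e) {
        cqMessage("image '", ds@imageId, "': ", conditionMessage(e))
        list()
      }
    )
    if (!length(groups)) return(NULL)
    data.frame(
      image_id = ds@imageId,
      side = vapply(groups, sideOf, character(1)),
      consumption_pct = vapply(groups, consumptionRatio,
        numeric(1),
        approachUsed = approachUsed
      ),
      n_bare_parts = vapply(groups, function(g) length(g@bareParts), integer(1)),
      n_kernel_parts = vapply(groups, function(g) length(g@kernelParts), integer(1)),
      whole_area = vapply(groups, function(g) sum(g@wholeMask), numeric(1)),
      outlier = FALSE,
      reason = "",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) {
    out <- data.frame(
      image_id = character(), side = character(),
      consumption_pct = numeric(), n_bare_parts = integer(),
      n_kernel_parts = integer(), whole_area = numeric(),
      outlier = logical(), reason = character(), stringsAsFactors = FALSE
    )
  }
  out
}

#' Flag estimation outliers against ground truth
#'
#' An ear's estimate is an outlier when segmentation itself failed for a
#' class the ground truth contains: the ear was not detected at all, or the
#' ground truth has bare cob (consumption above zero) while the prediction
#' produced no bare instance for that ear. Outliers are flagged with a
#' reason and retained; downstream R-squared excludes them.
#'
#' @param pred Records from [estimateConsumption()] on predicted detections.
#' @param gt Ground-truth per-ear records: either the generator's truth
#'   table or [estimateConsumption()] on ground-truth detections. Must
#'   contain `image_id`, `side`, a truth percentage column (`true_pct` or
#'   `consumption_pct`) and `n_bare_parts`.
#' @return One row per ground-truth ear: `image_id`, `side`, `true_pct`,
#'   `consumption_pct` (NA when the ear was missed), `outlier`, `reason`.
#' @export
detectOutliers <- function(pred, gt) {
  gtPct <- gt$true_pct %||% gt$consumption_pct
  key <- function(df) paste(df$image_id, df$side)
  pk <- key(pred)
  gk <- key(gt)
  orphan <- setdiff(pk, gk)
  if (length(orphan)) {
    stop(
      "pairing error: predicted ear(s) with no ground-truth counterpart: ",
      paste(orphan, collapse = ", ")
    )
  }
  m <- match(gk, pk)
  out <- data.frame(
    image_id = gt$image_id,
    side = gt$side,
    true_pct = gtPct,
    consumption_pct = ifelse(is.na(m), NA_real_, pred$consumption_pct[m]),
    outlier = FALSE,
    reason = "",
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(out))) {
    if (is.na(m[i])) {
      out$outlier[i] <- TRUE
      out$reason[i] <- "ear not detected (no whole-ear instance)"
    } else if (gt$n_bare_parts[i] > 0 && gtPct[i] > 0 && pred$n_bare_parts[m[i]] == 0) {
      out$outlier[i] <- TRUE
      out$reason[i] <- "ground truth has bare cob but prediction has no bare instance"
    }
  }
  out
}

#' Left-right verdicts from per-ear records
#'
#' For every image carrying both a left and a right record, compares the two
#' consumptions with [compareLeftRight()].
#'
#' @param records data.frame with `image_id`, `side`, `consumption_pct` (or
#'   `true_pct`).
#' @param tolerance Percentage points treated as equal.
#' @return data.frame with `image_id`, `left_pct`, `right_pct`, `verdict`.
#' @export
pairVerdicts <- function(records, tolerance = 0) {
  pct <- records$consumption_pct %||% records$true_pct
  rows <- lapply(split(seq_len(nrow(records)), records$image_id), function(idx) {
    side <- records$side[idx]
    if (!all(c("left", "right") %in% side)) return(NULL)
    l <- pct[idx[side == "left"][1]]
    r <- pct[idx[side == "right"][1]]
    if (is.na(l) || is.na(r)) return(NULL)
    data.frame(
      image_id = records$image_id[idx[1]],
      left_pct = l, right_pct = r,
      verdict = compareLeftRight(l, r, tolerance),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) {
    out <- data.frame(
      image_id = character(), left_pct = numeric(),
      right_pct = numeric(), verdict = character(), stringsAsFactors = FALSE
    )
  }
  rownames(out) <- NULL
  out
}
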