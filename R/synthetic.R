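## Synthetic paired-ear scene generator. Scenes emulate the community-science
## feeding-stand photographs: one or two conical corn ears against a plain,
## textured or cluttered background, each ear partially stripped to bare cob.
## Ground truth is emitted in BOTH labeling approaches over identical pixel
## geometry, and the true consumption of every ear is exact by construction
## (bare pixels / whole pixels), which is what makes the generator usable as
## an oracle for the whole estimation pipeline.

CQ_PALETTE <- list(
  kernel = c(0.85, 0.72, 0.15), # saturated yellow, hue ~49 deg
  bare = c(0.78, 0.52, 0.38), # pale red-brown cob, hue ~21 deg
  background = c(0.53, 0.54, 0.56), # near-neutral gray
  distractors = list(
    c(0.25, 0.35, 0.70), c(0.30, 0.60, 0.25),
    c(0.30, 0.30, 0.32), c(0.60, 0.30, 0.55)
  )
)

#' Specify one synthetic corn ear
#'
#' @param bareFraction Fraction of the visible ear area that is bare cob,
#'   in \[0, 1\].
#' @param center `c(row, col)` of the ear center in pixels.
#' @param length Ear length along its axis, pixels.
#' @param maxWidth Maximum ear width, pixels.
#' @param orientation Degrees away from vertical (tip up at 0).
#' @param barePattern `"top_down"` (eaten from the tip downward) or
#'   `"patchy"` (1-4 bitten-out blobs seeded on the ear outline).
#' @return A list of class `cq_ear_spec`.
#' @export
earSpec <- function(bareFraction, center, length, maxWidth,
                    orientation = 0, barePattern = c("top_down", "patchy")) {
  barePattern <- match.arg(barePattern)
  stopifnot(
    bareFraction >= 0, bareFraction <= 1,
    length > 0, maxWidth > 0
  )
  structure(
    list(
      bareFraction = bareFraction, center = as.numeric(center),
      length = as.numeric(length), maxWidth = as.numeric(maxWidth),
      orientation = as.numeric(orientation), barePattern = barePattern
    ),
    class = "cq_ear_spec"
  )
}

#' Specify one synthetic scene
#'
#' @param ears List of one or two [earSpec()] objects. With two ears their
#'   horizontal centers must differ so left/right is well defined.
#' @param imageShape `c(height, width)` in pixels.
#' @param background `"plain"`, `"textured"` or `"cluttered"`.
#' @param brightness Global brightness multiplier.
#' @param blurSigma Gaussian blur sigma in pixels (0 = none).
#' @param distractors Number of non-corn shapes to scatter.
#' @param seed Integer seed; the scene is deterministic given the spec.
#' @param imageId Image identifier.
#' @param palette Color palette (kernel/bare/background/distractors); the
#'   default is separable in HSV so the built-in color backend works, and can
#'   be degraded on purpose for stress tests.
#' @return A list of class `cq_scene_spec`.
#' @export
sceneSpec <- function(ears, imageShape = c(480L, 640L), background = "plain",
                      brightness = 1, blurSigma = 0, distractors = 0,
                      seed = 1L, imageId = "scene", palette = CQ_PALETTE) {
  if (inherits(ears, "cq_ear_spec")) ears <- list(ears)
  stopifnot(
    length(ears) %in% 1:2,
    background %in% c("plain", "textured", "cluttered")
  )
  if (length(ears) == 2L && ears[[1]]$center[2] == ears[[2]]$center[2]) {
    stop("with two ears the horizontal centers must differ (left/right must be well defined)")
  }
  structure(
    list(
      ears = ears, imageShape = as.integer(imageShape),
      background = background, brightness = brightness,
      blurSigma = blurSigma, distractors = as.integer(distractors),
      seed = as.integer(seed), imageId = imageId, palette = palette
    ),
    class = "cq_scene_spec"
  )
}

## Tapered conical ear outline: linear taper toward the tip with blunted
## ends, rotated by `orientation` about the center. Returns an (x, y) polygon.
earPolygon <- function(ear) {
  u <- seq(0, 1, length.out = 41)
  hw <- 0.5 * ear$maxWidth * (1 - 0.55 * u) * sqrt(pmax(0, 1 - (2 * u - 1)^6))
  along <- (u - 0.5) * ear$length
  th <- ear$orientation * pi / 180
  tipDir <- c(-cos(th), sin(th)) # (row, col) unit vector toward the tip
  acrossDir <- c(sin(th), cos(th))
  right <- cbind(
    ear$center[1] + along * tipDir[1] + hw * acrossDir[1],
    ear$center[2] + along * tipDir[2] + hw * acrossDir[2]
  )
  left <- cbind(
    ear$center[1] + rev(along) * tipDir[1] - rev(hw) * acrossDir[1],
    ear$center[2] + rev(along) * tipDir[2] - rev(hw) * acrossDir[2]
  )
  pts <- rbind(right, left)
  cbind(x = pts[, 2], y = pts[, 1])
}

## Pick the bare-cob pixels of one ear. Returns a logical mask of the same
## shape as `wholeMask` whose area is exactly round(f * area) (at least 1
## when f > 0), so the true consumption is exact by construction.
selectBarePixels <- function(wholeMask, ear) {
  area <- sum(wholeMask)
  f <- ear$bareFraction
  budget <- if (f <= 0) 0L else max(1L, min(area, as.integer(round(f * area))))
  bare <- wholeMask & FALSE
  if (budget == 0L) return(bare)
  idx <- which(wholeMask, arr.ind = TRUE)
  r <- idx[, 1] - 1L
  c <- idx[, 2] - 1L
  th <- ear$orientation * pi / 180
  tipDir <- c(-cos(th), sin(th))
  if (ear$barePattern == "top_down") {
    along <- (r - ear$center[1]) * tipDir[1] + (c - ear$center[2]) * tipDir[2]
    pick <- order(-along, r, c)[seq_len(budget)]
  } else {
    # patchy: blobs grown from seeds ON the ear outline, so consumed regions
    # always touch the ear boundary and the kernel remainder stays hole-free
    pm <- matrix(FALSE, nrow(wholeMask) + 2L, ncol(wholeMask) + 2L)
    pm[2:(nrow(wholeMask) + 1L), 2:(ncol(wholeMask) + 1L)] <- wholeMask
    interior <- pm[cbind(r + 1L, c + 2L)] & pm[cbind(r + 3L, c + 2L)] &
      pm[cbind(r + 2L, c + 1L)] & pm[cbind(r + 2L, c + 3L)]
    boundary <- which(!interior)
    k <- sample(1:4, 1)
    seeds <- boundary[sample.int(length(boundary), min(k, length(boundary)))]
    rate <- runif(length(seeds), 0.7, 1.3)
    val <- rep(Inf, length(r))
    for (s in seq_along(seeds)) {
      d <- sqrt((r - r[seeds[s]])^2 + (c - c[seeds[s]])^2) / rate[s]
      val <- pmin(val, d)
    }
    pick <- order(val, r, c)[seq_len(budget)]
  }
  bare[idx[pick, , drop = FALSE]] <- TRUE
  bare
}

## Split a mask into its 4-connected components, largest first.
maskComponents <- function(mask) {
  if (!any(mask)) return(list())
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  comps <- lapply(seq_len(n), function(i) lab == i)
  comps[order(-vapply(comps, sum, numeric(1)))]
}

#' Generate one synthetic scene
#'
#' Draws the ears of `spec`, selects bare-cob pixels matching each ear's
#' bare fraction exactly, and returns the rendered image together with
#' ground truth in both labeling approaches over identical geometry:
#' Approach 1 carries whole-ear plus bare-part masks, Approach 2 carries
#' kernel plus bare parts with kernel and bare partitioning the whole ear.
#' Deterministic given the spec (which includes its seed).
#'
#' @param spec A [sceneSpec()].
#' @param render Set `FALSE` to skip image rendering (masks and truth only),
#'   which is cheaper when only ground-truth backends are exercised.
#' @return A [SyntheticScene-class] object.
#' @export
generateScene <- function(spec, render = TRUE) {
  stopifnot(inherits(spec, "cq_scene_spec"))
  H <- spec$imageShape[1]
  W <- spec$imageShape[2]
  withSeed(spec$seed, {
    wholeMasks <- lapply(spec$ears, function(e) polygonToMask(earPolygon(e), c(H, W)))
    if (length(wholeMasks) == 2L && any(wholeMasks[[1]] & wholeMasks[[2]])) {
      stop("scene spec error: ear polygons overlap")
    }
    earData <- vector("list", length(spec$ears))
    for (i in seq_along(spec$ears)) {
      whole <- wholeMasks[[i]]
      bare <- selectBarePixels(whole, spec$ears[[i]])
      earData[[i]] <- list(
        whole = whole, bare = bare, kernel = whole & !bare,
        bareComps = maskComponents(bare),
        kernelComps = maskComponents(whole & !bare),
        truePct = 100 * sum(bare) / sum(whole)
      )
    }
    # sides by ascending horizontal center of the whole mask
    ctr <- vapply(earData, function(e) mean(which(e$whole, arr.ind = TRUE)[, 2]), numeric(1))
    ord <- order(ctr)
    sides <- if (length(earData) == 1L) "only" else c("left", "right")[order(ord)]

    instA1 <- list()
    instA2 <- list()
    for (e in earData) {
      instA1[[length(instA1) + 1L]] <- list(label = "whole_corn", mask = e$whole)
      for (b in e$bareComps) {
        instA1[[length(instA1) + 1L]] <- list(label = "bare_cob", mask = b)
      }
      for (k in e$kernelComps) {
        instA2[[length(instA2) + 1L]] <- list(label = "corn_kernel", mask = k)
      }
      for (b in e$bareComps) {
        instA2[[length(instA2) + 1L]] <- list(label = "bare_cob", mask = b)
      }
    }
    truthDf <- data.frame(
      image_id = spec$imageId,
      ear = seq_along(earData),
      side = sides,
      true_pct = vapply(earData, function(e) e$truePct, numeric(1)),
      n_bare_parts = vapply(earData, function(e) length(e$bareComps), integer(1)),
      n_kernel_parts = vapply(earData, function(e) length(e$kernelComps), integer(1)),
      stringsAsFactors = FALSE
    )
    truthDf$category <- categorizePair(
      truthDf$true_pct[1],
      truthDf$true_pct[min(2, nrow(truthDf))]
    )
    img <- if (render) renderScene(spec, earData) else NULL
    new("SyntheticScene",
      image = img,
      sceneA1 = AnnotatedScene(spec$imageId, c(H, W), instA1, 1),
      sceneA2 = AnnotatedScene(spec$imageId, c(H, W), instA2, 2),
      truth = truthDf,
      spec = unclass(spec)
    )
  })
}

## Paint the scene: background, distractor shapes, then the ears (kernel
## texture with a faint row/column grid, bare cob with milder noise). All
## noise is multiplicative on a fixed-hue base color, so HSV hue stays
## inside the class band whatever the brightness.
renderScene <- function(spec, earData) {
  H <- spec$imageShape[1]
  W <- spec$imageShape[2]
  pal <- spec$palette
  img <- array(0, dim = c(H, W, 3))
  lum <- matrix(rnorm(H * W, 0, 0.01), H, W)
  if (spec$background == "plain") {
    for (ch in 1:3) img[, , ch] <- pal$background[ch] + lum
  } else {
    base <- c(0.45, 0.50, 0.60) # cool gray-blue, hue well outside corn bands
    wave <- outer(sin(seq_len(H) / 23), cos(seq_len(W) / 31)) * 0.05
    for (ch in 1:3) img[, , ch] <- base[ch] * (1 + wave) + lum
  }
  nDistract <- if (spec$background == "cluttered") max(spec$distractors, 3L) else spec$distractors
  if (nDistract > 0) {
    rows <- matrix(seq_len(H), H, W) - 0.5
    cols <- matrix(seq_len(W), H, W, byrow = TRUE) - 0.5
    for (d in seq_len(nDistract)) {
      cr <- runif(1, 0.1, 0.9) * H
      cc <- runif(1, 0.1, 0.9) * W
      a <- runif(1, 0.04, 0.15) * min(H, W)
      b <- runif(1, 0.04, 0.15) * min(H, W)
      shape <- ((rows - cr) / a)^2 + ((cols - cc) / b)^2 <= 1
      col <- pal$distractors[[sample.int(length(pal$distractors), 1)]]
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[shape] <- col[ch]
        img[, , ch] <- plane
      }
    }
  }
  for (e in earData) {
    nk <- sum(e$kernel)
    if (nk > 0) {
      idx <- which(e$kernel, arr.ind = TRUE)
      fac <- runif(nk, 0.78, 1.05)
      grid <- (idx[, 1] %% 7L == 0L) | (idx[, 2] %% 5L == 0L)
      fac[grid] <- fac[grid] * 0.62
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[idx] <- pal$kernel[ch] * fac
        img[, , ch] <- plane
      }
    }
    nb <- sum(e$bare)
    if (nb > 0) {
      idx <- which(e$bare, arr.ind = TRUE)
      fac <- runif(nb, 0.88, 1.06)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[idx] <- pal$bare[ch] * fac
        img[, , ch] <- plane
      }
    }
  }
  img <- img * spec$brightness
  if (spec$blurSigma > 0) {
    for (ch in 1:3) img[, , ch] <- EBImage::gblur(img[, , ch], sigma = spec$blurSigma)
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

#' Augment a synthetic scene
#'
#' Applies a sequence of the augmentation operations used when training
#' segmentation networks on this kind of data: geometric ops (`flip_lr`,
#' `flip_ud`, `rot90`, `rot180`, `rot270`) transform the image and every
#' ground-truth mask by the identical pixel permutation (sides in the truth
#' table are recomputed from the transformed geometry); photometric ops
#' (`gaussian_blur` with `sigma`, `color_multiply` with 3 `factors`) touch
#' only the image.
#'
#' @param scene A [SyntheticScene-class].
#' @param ops List whose elements are op names or `list(name, <args>)`, e.g.
#'   `list("flip_lr", list("gaussian_blur", sigma = 2))`.
#' @param seed Optional seed for any stochastic op, for reproducibility.
#' @return The augmented [SyntheticScene-class].
#' @export
augmentScene <- function(scene, ops, seed = NULL) {
  applyOne <- function(scene, op) {
    name <- if (is.list(op)) op[[1]] else op
    if (name %in% CQ_GEOM_OPS) {
      img <- scene@image
      if (!is.null(img)) {
        planes <- lapply(1:3, function(ch) transformMatrix(img[, , ch], name))
        img <- array(0, dim = c(dim(planes[[1]]), 3))
        for (ch in 1:3) img[, , ch] <- planes[[ch]]
      }
      tf <- function(sc) {
        insts <- lapply(sc@instances, function(inst) {
          list(label = inst$label, mask = transformMatrix(inst$mask, name))
        })
        newShape <- if (name %in% c("rot90", "rot270")) rev(sc@imageShape) else sc@imageShape
        AnnotatedScene(sc@imageId, newShape, insts, approach = sc@approach)
      }
      a1 <- tf(scene@sceneA1)
      truth <- scene@truth
      # recompute sides from the transformed whole masks
      wholes <- Filter(function(i) i$label == "whole_corn", a1@instances)
      ctr <- vapply(wholes, function(i) mean(which(i$mask, arr.ind = TRUE)[, 2]), numeric(1))
      truth$side <- if (length(ctr) == 1L) "only" else c("left", "right")[order(order(ctr))]
      methods::initialize(scene,
        image = img, sceneA1 = a1, sceneA2 = tf(scene@sceneA2), truth = truth
      )
    } else if (name == "gaussian_blur") {
      sigma <- (if (is.list(op)) op$sigma else NULL) %||% 1
      img <- scene@image
      if (!is.null(img) && sigma > 0) {
        for (ch in 1:3) img[, , ch] <- EBImage::gblur(img[, , ch], sigma = sigma)
      }
      methods::initialize(scene, image = img)
    } else if (name == "color_multiply") {
      factors <- (if (is.list(op)) op$factors else NULL) %||% c(1, 1, 1)
      img <- scene@image
      if (!is.null(img)) {
        for (ch in 1:3) img[, , ch] <- pmin(1, pmax(0, img[, , ch] * factors[ch]))
      }
      methods::initialize(scene, image = img)
    } else {
      stop("unknown augmentation op '", name, "'")
    }
  }
  run <- function() {
    for (op in ops) scene <<- applyOne(scene, op)
    scene
  }
  if (is.null(seed)) run() else withSeed(seed, run())
}

#' Draw scene specifications for a dataset
#'
#' Samples per-scene specs reproducing the study conditions: two conical
#' ears side by side (ear length 38-55% of the short image side), image
#' sizes drawn from 640x480 / 1280x760 / 2048x1536, and per-ear bare
#' fractions either uniform on \[0, 1\] (`categoryMix = NULL`) or stratified
#' over the pre-screening categories `0-5%`, `5-95%`, `95-100%` by
#' largest-remainder allocation.
#'
#' @param n Number of scenes.
#' @param categoryMix `NULL` for uniform bare fractions, else a numeric
#'   vector of three fractions (summing to 1) over categories
#'   `c("0-5%", "5-95%", "95-100%")`.
#' @param seed Integer seed.
#' @param imageSizes List of `c(height, width)` pairs to sample from.
#' @param nEars Ears per scene (default 2).
#' @param background,blurSigma,distractors,brightness,palette Passed to each
#'   [sceneSpec()]; defaults give the clean-scene configuration.
#' @param idPrefix Prefix for image ids.
#' @return List of [sceneSpec()] objects.
#' @export
sceneSpecs <- function(n, categoryMix = NULL, seed = 1L,
                       imageSizes = list(c(480L, 640L), c(760L, 1280L), c(1536L, 2048L)),
                       nEars = 2L, background = "plain", blurSigma = 0,
                       distractors = 0L, brightness = 1, palette = CQ_PALETTE,
                       idPrefix = "scene") {
  if (n <= 0) stop("n must be positive")
  cats <- c("0-5%", "5-95%", "95-100%")
  if (!is.null(categoryMix)) {
    if (length(categoryMix) != 3L || abs(sum(categoryMix) - 1) > 1e-8) {
      stopValidation("categoryMix must be three fractions summing to 1")
    }
    counts <- allocateCounts(n, categoryMix)
  }
  withSeed(seed, {
    sceneCats <- if (is.null(categoryMix)) {
      rep("uniform", n)
    } else {
      sample(rep(cats, counts))
    }
    lapply(seq_len(n), function(i) {
      shape <- imageSizes[[sample.int(length(imageSizes), 1)]]
      H <- shape[1]; W <- shape[2]
      fs <- drawBareFractions(sceneCats[i], nEars)
      xcenters <- if (nEars == 1L) 0.5 else c(0.28, 0.72)
      ears <- lapply(seq_len(nEars), function(j) {
        len <- runif(1, 0.38, 0.55) * min(H, W)
        earSpec(
          bareFraction = fs[j],
          center = c(
            H * (0.5 + runif(1, -0.05, 0.05)),
            W * (xcenters[j] + runif(1, -0.035, 0.035))
          ),
          length = len,
          maxWidth = len * runif(1, 0.30, 0.38),
          orientation = runif(1, -15, 15),
          barePattern = if (runif(1) < 0.5) "top_down" else "patchy"
        )
      })
      sceneSpec(ears,
        imageShape = shape, background = background,
        brightness = brightness, blurSigma = blurSigma,
        distractors = distractors, seed = deriveSeed(seed, i),
        imageId = sprintf("%s_%04d", idPrefix, i), palette = palette
      )
    })
  })
}

## Per-ear bare fractions for one scene, kept a safe margin inside the
## category bounds so pixel rounding can never flip the realized category.
drawBareFractions <- function(category, nEars) {
  mid <- function() runif(1, 0.08, 0.92)
  lo <- function() runif(1, 0.003, 0.045)
  hi <- function() runif(1, 0.955, 0.997)
  one <- switch(category,
    uniform = function() runif(1),
    `0-5%` = lo,
    `95-100%` = hi,
    `5-95%` = NULL,
    stop("unknown category '", category, "'")
  )
  if (category != "5-95%") {
    return(vapply(seq_len(nEars), function(i) one(), numeric(1)))
  }
  if (nEars == 1L) return(mid())
  if (runif(1) < 0.7) {
    c(mid(), mid())
  } else {
    # mixed pair: one extreme ear, one mid ear, in random order
    pair <- c(if (runif(1) < 0.5) lo() else hi(), mid())
    sample(pair)
  }
}

#' Generate a synthetic dataset
#'
#' Materializes `n` scenes drawn by [sceneSpecs()] with exact per-ear ground
#' truth. For large scene counts or the largest image sizes consider
#' generating scenes one at a time from the specs instead of materializing
#' the whole dataset.
#'
#' @inheritParams sceneSpecs
#' @param render Render RGB images (needed by the color backend) or keep
#'   masks only.
#' @param ... Passed to [sceneSpecs()].
#' @return A [SyntheticDataset-class].
#' @export
generateDataset <- function(n, categoryMix = NULL, seed = 1L, render = TRUE, ...) {
  specs <- sceneSpecs(n, categoryMix = categoryMix, seed = seed, ...)
  scenes <- lapply(specs, generateScene, render = render)
  new("SyntheticDataset",
    scenes = scenes,
    truth = do.call(rbind, lapply(scenes, truth)),
    seed = as.integer(seed),
    params = list(n = n, categoryMix = categoryMix)
  )
}

#' Write a dataset to disk
#'
#' Writes `images/<id>.png`, VIA annotation JSON for both labeling
#' approaches, a `truth.csv` of exact per-ear consumptions and a
#' `manifest.json` recording the seed and generation parameters.
#'
#' @param dataset A [SyntheticDataset-class].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  for (scene in dataset@scenes) {
    if (!is.null(scene@image)) {
      png::writePNG(
        scene@image,
        file.path(dir, "images", paste0(scene@sceneA1@imageId, ".png"))
      )
    }
  }
  writeVia(lapply(dataset@scenes, slot, "sceneA1"), file.path(dir, "via_approach1.json"))
  writeVia(lapply(dataset@scenes, slot, "sceneA2"), file.path(dir, "via_approach2.json"))
  write.csv(dataset@truth, file.path(dir, "truth.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(
      seed = dataset@seed, params = dataset@params,
      n_scenes = length(dataset@scenes),
      package = as.character(utils::packageVersion("CobQuant"))
    ),
    file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
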