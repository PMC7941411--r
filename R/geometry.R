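## Raster/geometry primitives shared by every module: polygon rasterization,
## IoU, tight boxes, run-length coding, the 1024-square resize convention and
## the flip/rotation group used for augmentation.

#' Area of a binary mask
#' @param mask Logical matrix.
#' @return Number of TRUE pixels.
#' @export
maskArea <- function(mask) sum(mask)

#' Tight bounding box of a mask
#'
#' @param mask Logical matrix with at least one TRUE pixel.
#' @return Half-open 0-based box `c(r0, c0, r1, c1)`.
#' @export
tightBox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) stop("tightBox: mask is empty")
  c(
    min(idx[, 1]) - 1L, min(idx[, 2]) - 1L,
    max(idx[, 1]), max(idx[, 2])
  )
}

## Do two half-open boxes, each dilated by `margin` pixels, intersect?
boxesIntersect <- function(a, b, margin = 0L) {
  a[1] - margin < b[3] + margin && b[1] - margin < a[3] + margin &&
    a[2] - margin < b[4] + margin && b[2] - margin < a[4] + margin
}

boxUnion <- function(a, b) {
  c(min(a[1], b[1]), min(a[2], b[2]), max(a[3], b[3]), max(a[4], b[4]))
}

#' Rasterize a polygon to a binary mask
#'
#' A pixel belongs to the mask iff its center (c + 0.5, r + 0.5) lies inside
#' the implicitly closed polygon under the even-odd rule. Centers exactly on
#' an edge are resolved by half-open scanline intervals, so the lower-left of
#' two candidate pixels wins and abutting polygons never double-claim a
#' pixel. Implemented as a scanline fill; tests check it against a per-pixel
#' point-in-polygon oracle.
#'
#' @param points n x 2 matrix of (x, y) vertices in pixel units (VIA order),
#'   n >= 3.
#' @param shape `c(height, width)` of the target grid.
#' @return Logical matrix of dim `shape`.
#' @examples
#' sq <- rbind(c(0, 0), c(0, 2), c(2, 2), c(2, 0))
#' sum(polygonToMask(sq, c(4, 4))) # 4 pixels
#' @export
polygonToMask <- function(points, shape) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) {
    stop("invalid polygon: need at least 3 vertices, got ", nrow(points))
  }
  H <- as.integer(shape[1])
  W <- as.integer(shape[2])
  x <- as.numeric(points[, 1])
  y <- as.numeric(points[, 2])
  x2 <- c(x[-1], x[1])
  y2 <- c(y[-1], y[1])
  keep <- y != y2 # horizontal edges never cross a scanline
  x1 <- x[keep]; y1 <- y[keep]; xe <- x2[keep]; ye <- y2[keep]
  mask <- matrix(FALSE, H, W)
  if (length(x1)) {
    rlo <- max(0L, as.integer(floor(min(y1, ye) - 0.5)))
    rhi <- min(H - 1L, as.integer(ceiling(max(y1, ye))))
    ylo <- pmin(y1, ye)
    yhi <- pmax(y1, ye)
    for (r in seq(rlo, length.out = max(0L, rhi - rlo + 1L))) {
      cy <- r + 0.5
      sel <- ylo <= cy & cy < yhi
      if (!any(sel)) next
      xs <- sort(x1[sel] + (cy - y1[sel]) * (xe[sel] - x1[sel]) / (ye[sel] - y1[sel]))
      for (k in seq(1L, length(xs) - 1L, by = 2L)) {
        c0 <- max(0L, as.integer(ceiling(xs[k] - 0.5)))
        c1 <- min(W - 1L, as.integer(ceiling(xs[k + 1L] - 0.5)) - 1L)
        if (c0 <= c1) mask[r + 1L, (c0 + 1L):(c1 + 1L)] <- TRUE
      }
    }
  }
  if (!any(mask)) {
    stop("empty mask: polygon has zero area on a ", H, "x", W, " grid")
  }
  mask
}

#' Intersection over union of two masks
#'
#' The Jaccard index between two binary masks on the same grid: overlap area
#' divided by union area. Defined as 0 when both masks are empty.
#'
#' @param a,b Logical matrices of identical dimension.
#' @return Fraction in \[0, 1\].
#' @export
maskIoU <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop(
      "grid mismatch: masks have dimensions ",
      paste(dim(a), collapse = "x"), " vs ", paste(dim(b), collapse = "x")
    )
  }
  u <- sum(a | b)
  if (u == 0L) return(0)
  sum(a & b) / u
}

#' Run-length encode a mask
#'
#' Row-major run-length coding: runs are counted along rows (left to right,
#' top row first) and the counts vector always starts with the number of
#' leading FALSE pixels (possibly 0). `sum(counts)` equals `height * width`.
#'
#' @param mask Logical matrix.
#' @return `list(size = c(H, W), counts = integer vector)`.
#' @export
rleEncode <- function(mask) {
  v <- as.vector(t(mask)) # row-major order
  r <- rle(v)
  counts <- r$lengths
  if (length(counts) == 0L) counts <- integer()
  if (length(r$values) && r$values[1]) counts <- c(0L, counts)
  list(size = as.integer(dim(mask)), counts = as.integer(counts))
}

#' @rdname rleEncode
#' @param rle A list as produced by `rleEncode()`.
#' @export
rleDecode <- function(rle) {
  H <- as.integer(rle$size[1])
  W <- as.integer(rle$size[2])
  counts <- as.integer(rle$counts)
  if (sum(counts) != H * W) {
    stop(
      "inconsistent RLE: run counts sum to ", sum(counts),
      " but the grid has ", H * W, " pixels"
    )
  }
  vals <- rep(rep(c(FALSE, TRUE), length.out = length(counts)), counts)
  matrix(vals, nrow = H, ncol = W, byrow = TRUE)
}

#' Resize an image to a padded square
#'
#' Scales the longest side to `targetSide` with bilinear interpolation
#' (preserving aspect ratio), then zero-pads the short side symmetrically to
#' a square — the input convention commonly used when feeding images of
#' arbitrary resolution to a fixed-size segmentation network. Masks must use
#' `kind = "mask"` (nearest-neighbor, so labels stay binary). The returned
#' geometry allows exact inverse mapping of coordinates and masks back to the
#' original resolution.
#'
#' @param image Numeric matrix (H x W) or array (H x W x C), or logical
#'   matrix for masks.
#' @param targetSide Side of the output square in pixels (default 1024).
#' @param kind `"image"` (bilinear) or `"mask"` (nearest-neighbor).
#' @return `list(image, scale, offset = c(top, left), contentShape,
#'   origShape, targetSide)`.
#' @export
resizeWithPad <- function(image, targetSide = 1024, kind = c("image", "mask")) {
  kind <- match.arg(kind)
  if (targetSide <= 0) stop("targetSide must be positive")
  d <- dim(image)
  if (is.null(d) || any(d[1:2] < 1)) stop("image must be a nonempty matrix or array")
  H <- d[1]; W <- d[2]
  scale <- targetSide / max(H, W)
  newH <- if (H >= W) as.integer(targetSide) else as.integer(round(H * scale))
  newW <- if (W > H) as.integer(targetSide) else as.integer(round(W * scale))
  filt <- if (kind == "image") "bilinear" else "none"
  resized <- if (newH == H && newW == W) {
    image * 1 # force numeric copy
  } else {
    EBImage::resize(image * 1, w = newH, h = newW, filter = filt)
  }
  top <- as.integer(floor((targetSide - newH) / 2))
  left <- as.integer(floor((targetSide - newW) / 2))
  out <- if (length(d) == 3L) {
    array(0, dim = c(targetSide, targetSide, d[3]))
  } else {
    matrix(0, targetSide, targetSide)
  }
  idx <- list(top + seq_len(newH), left + seq_len(newW))
  if (length(d) == 3L) {
    out[idx[[1]], idx[[2]], ] <- resized
  } else {
    out[idx[[1]], idx[[2]]] <- resized
  }
  if (kind == "mask") out <- out > 0.5
  list(
    image = out, scale = scale, offset = c(top = top, left = left),
    contentShape = c(newH, newW), origShape = c(H, W),
    targetSide = as.integer(targetSide)
  )
}

#' Map square-frame coordinates back to the original image
#'
#' Inverse of the [resizeWithPad()] geometry for (x, y) points in pixel
#' units.
#'
#' @param points n x 2 matrix of (x, y) points in the padded square frame.
#' @param geom Geometry list returned by [resizeWithPad()].
#' @return n x 2 matrix in original-image pixel units.
#' @export
mapToOriginal <- function(points, geom) {
  points <- as.matrix(points)
  cbind(
    (points[, 1] - geom$offset[["left"]]) / geom$scale,
    (points[, 2] - geom$offset[["top"]]) / geom$scale
  )
}

## Bring a mask predicted in the padded square frame back to original
## resolution (crop the pad, nearest-neighbor resize).
unpadMask <- function(mask, geom) {
  content <- mask[
    geom$offset[["top"]] + seq_len(geom$contentShape[1]),
    geom$offset[["left"]] + seq_len(geom$contentShape[2]),
    drop = FALSE
  ]
  if (all(geom$contentShape == geom$origShape)) {
    return(content)
  }
  EBImage::resize(content * 1,
    w = geom$origShape[1], h = geom$origShape[2],
    filter = "none"
  ) > 0.5
}

CQ_GEOM_OPS <- c("flip_lr", "flip_ud", "rot90", "rot180", "rot270")

#' Apply a flip or rotation to a matrix
#'
#' Exact pixel permutations: `flip_lr`, `flip_ud`, and clockwise rotations
#' `rot90`, `rot180`, `rot270`. Used for both masks and per-channel image
#' planes so geometry stays aligned under augmentation.
#'
#' @param m Matrix.
#' @param op Operation name.
#' @return Transformed matrix.
#' @export
transformMatrix <- function(m, op) {
  switch(op,
    flip_lr = m[, ncol(m):1, drop = FALSE],
    flip_ud = m[nrow(m):1, , drop = FALSE],
    rot90 = t(m[nrow(m):1, , drop = FALSE]),
    rot180 = m[nrow(m):1, ncol(m):1, drop = FALSE],
    rot270 = t(m)[ncol(m):1, , drop = FALSE],
    stop("unknown geometric op '", op, "'")
  )
}
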