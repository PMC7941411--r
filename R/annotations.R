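## VIA (VGG Image Annotator) polygon I/O and the external detection-manifest
## adapter. Both VIA v2 dialects are accepted: a project file carrying
## "_via_img_metadata" and the flat export keyed by "<filename><size>".

viaImageMap <- function(doc) {
  if (!is.null(doc[["_via_img_metadata"]])) {
    doc[["_via_img_metadata"]]
  } else {
    looks <- vapply(doc, function(e) {
      is.list(e) && !is.null(e$filename) && !is.null(e$regions)
    }, logical(1))
    if (!all(looks) || !length(doc)) {
      stop("not a recognizable VIA export: no _via_img_metadata and entries lack filename/regions")
    }
    doc
  }
}

#' Read VIA polygon annotations
#'
#' Parses a VIA v2 JSON export (either dialect) into [AnnotatedScene]
#' objects. Polygon vertices are preserved verbatim; non-polygon regions are
#' skipped with a warning; a region whose class attribute is not legal for
#' the declared labeling approach raises an error naming the offending
#' region.
#'
#' Image dimensions are taken from `file_attributes` entries `height`/`width`
#' (written by [writeVia()]) or, failing that, from the `imageShapes`
#' argument.
#'
#' @param path Path to the VIA JSON file.
#' @param classAttribute Name of the region attribute holding the class
#'   (VIA projects vary; default `"class"`).
#' @param approach Labeling approach the file is expected to follow (1 or 2).
#' @param imageShapes Optional named list of `c(height, width)` keyed by
#'   filename or image id, used when the file carries no size attributes.
#' @return List of [AnnotatedScene] objects.
#' @export
readVia <- function(path, classAttribute = "class", approach = 1,
                    imageShapes = NULL) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("malformed VIA JSON in '", path, "': ", conditionMessage(e))
  )
  imgs <- viaImageMap(doc)
  legal <- approachClasses(approach)
  scenes <- vector("list", length(imgs))
  for (i in seq_along(imgs)) {
    entry <- imgs[[i]]
    fname <- entry$filename %||% names(imgs)[i]
    fa <- entry$file_attributes %||% list()
    id <- fa$image_id %||% sub("\\.[^.]*$", "", fname)
    shape <- if (!is.null(fa$height) && !is.null(fa$width)) {
      c(as.integer(fa$height), as.integer(fa$width))
    } else if (!is.null(imageShapes[[fname]])) {
      as.integer(imageShapes[[fname]])
    } else if (!is.null(imageShapes[[id]])) {
      as.integer(imageShapes[[id]])
    } else {
      stop(
        "image dimensions unavailable for '", fname,
        "': no height/width file_attributes and no imageShapes entry"
      )
    }
    insts <- list()
    for (j in seq_along(entry$regions)) {
      region <- entry$regions[[j]]
      sa <- region$shape_attributes
      if (is.null(sa$name) || sa$name != "polygon") {
        warning(
          "skipping non-polygon region ", j, " (", sa$name %||% "unnamed",
          ") of image '", id, "'"
        )
        next
      }
      cls <- region$region_attributes[[classAttribute]]
      if (is.null(cls) || !cls %in% legal) {
        stop(
          "labeling error: region ", j, " of image '", id, "' has class '",
          cls %||% "<missing>", "', expected one of ",
          paste(legal, collapse = ", ")
        )
      }
      poly <- cbind(
        unlist(sa$all_points_x, use.names = FALSE),
        unlist(sa$all_points_y, use.names = FALSE)
      )
      insts[[length(insts) + 1L]] <- list(label = cls, polygon = poly)
    }
    scenes[[i]] <- AnnotatedScene(id, shape, insts, approach)
  }
  scenes
}

#' Write VIA polygon annotations
#'
#' Serializes scenes to a VIA-loadable project JSON (under
#' `_via_img_metadata`, with image height/width and id stored as file
#' attributes so [readVia()] round-trips without external size information).
#' Mask-only instances are traced to their outer contour polygon; interior
#' holes are dropped with a warning, which loses at most the one-pixel
#' boundary ring of the mask.
#'
#' @param scenes List of [AnnotatedScene] objects.
#' @param path Output path.
#' @param classAttribute Region attribute name to write classes under.
#' @return `path`, invisibly.
#' @export
writeVia <- function(scenes, path, classAttribute = "class") {
  imgs <- list()
  for (scene in scenes) {
    fname <- paste0(scene@imageId, ".png")
    regions <- lapply(scene@instances, function(inst) {
      poly <- inst$polygon %||% maskToPolygon(inst$mask)
      ra <- list()
      ra[[classAttribute]] <- inst$label
      list(
        shape_attributes = list(
          name = "polygon",
          all_points_x = as.numeric(poly[, 1]),
          all_points_y = as.numeric(poly[, 2])
        ),
        region_attributes = ra
      )
    })
    imgs[[paste0(fname, "-1")]] <- list(
      filename = fname, size = -1,
      file_attributes = list(
        image_id = scene@imageId,
        height = scene@imageShape[1], width = scene@imageShape[2]
      ),
      regions = regions
    )
  }
  jsonlite::write_json(list(`_via_img_metadata` = imgs), path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Trace a mask to its outer boundary polygon
#'
#' Walks the outer boundary of the largest connected component along pixel
#' edges, returning a rectilinear polygon with vertices at pixel corners.
#' For a hole-free 4-connected component the traced polygon rasterizes back
#' to the identical mask under the pixel-center even-odd rule, so VIA
#' round-trips of generated ground truth are loss-free. Interior holes are
#' dropped (outer contour only) with a warning.
#'
#' @param mask Logical matrix.
#' @return n x 2 numeric matrix of (x, y) vertices.
#' @export
maskToPolygon <- function(mask) {
  if (!any(mask)) stop("cannot trace an empty mask")
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n > 1L) {
    warning("mask has ", n, " components; tracing the largest outer contour only")
    areas <- tabulate(lab[lab > 0], nbins = n)
    mask <- lab == which.max(areas)
  }
  if (sum(EBImage::fillHull(mask)) > sum(mask)) {
    warning("mask has interior holes; holes are dropped in the traced polygon")
  }
  loops <- traceBoundaryLoops(mask)
  areas <- vapply(loops, function(p) {
    x <- p[, 1]; y <- p[, 2]
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }, numeric(1))
  loops[[which.max(areas)]]
}

## Decompose the boundary of a pixel region into closed rectilinear loops.
## Boundary edges are oriented with the region on their right; at
## checkerboard-ambiguous corners the walk prefers the right turn, which
## keeps loops of diagonally touching regions separate.
traceBoundaryLoops <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pm <- matrix(FALSE, H + 2L, W + 2L)
  pm[2:(H + 1L), 2:(W + 1L)] <- mask
  idx <- which(mask, arr.ind = TRUE)
  r <- idx[, 1] - 1L; c <- idx[, 2] - 1L
  edges <- list() # each: tail x, tail y, dx, dy
  add <- function(sel, tx, ty, dx, dy) {
    if (any(sel)) {
      cbind(tx[sel], ty[sel], dx, dy)
    } else {
      NULL
    }
  }
  e <- rbind(
    add(!pm[cbind(r + 1L, c + 2L)], c, r, 1L, 0L), # top edge, heading +x
    add(!pm[cbind(r + 2L, c + 3L)], c + 1L, r, 0L, 1L), # right edge, +y
    add(!pm[cbind(r + 3L, c + 2L)], c + 1L, r + 1L, -1L, 0L), # bottom, -x
    add(!pm[cbind(r + 2L, c + 1L)], c, r + 1L, 0L, -1L) # left, -y
  )
  byTail <- split(seq_len(nrow(e)), paste(e[, 1], e[, 2]))
  used <- logical(nrow(e))
  loops <- list()
  for (start in seq_len(nrow(e))) {
    if (used[start]) next
    cur <- start
    verts <- list()
    repeat {
      used[cur] <- TRUE
      verts[[length(verts) + 1L]] <- e[cur, 1:2]
      hx <- e[cur, 1] + e[cur, 3]; hy <- e[cur, 2] + e[cur, 4]
      cand <- byTail[[paste(hx, hy)]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      if (length(cand) > 1L) {
        # prefer right turn, then straight, then left
        dx <- e[cur, 3]; dy <- e[cur, 4]
        pref <- rbind(c(-dy, dx), c(dx, dy), c(dy, -dx))
        pick <- NA_integer_
        for (k in 1:3) {
          hit <- cand[e[cand, 3] == pref[k, 1] & e[cand, 4] == pref[k, 2]]
          if (length(hit)) {
            pick <- hit[1]
            break
          }
        }
        cur <- pick
      } else {
        cur <- cand
      }
    }
    v <- do.call(rbind, verts)
    # drop collinear intermediate vertices (rectilinear runs)
    nv <- nrow(v)
    if (nv > 2L) {
      prev <- v[c(nv, seq_len(nv - 1L)), , drop = FALSE]
      nxt <- v[c(seq_len(nv - 1L) + 1L, 1L), , drop = FALSE]
      keep <- (prev[, 1] == v[, 1] & v[, 1] == nxt[, 1]) |
        (prev[, 2] == v[, 2] & v[, 2] == nxt[, 2])
      v <- v[!keep, , drop = FALSE]
    }
    loops[[length(loops) + 1L]] <- cbind(x = v[, 1], y = v[, 2])
  }
  loops
}

## Rasterize the instances of a scene to a list of (label, mask) pairs.
rasterizeInstances <- function(scene) {
  lapply(scene@instances, function(inst) {
    m <- inst$mask %||% polygonToMask(inst$polygon, scene@imageShape)
    list(label = inst$label, mask = m)
  })
}

#' Read an external detection manifest
#'
#' Adapter for externally produced instance-segmentation output (e.g. a
#' trained network run elsewhere). The manifest is JSON of the form
#' `{"images": [{"image_id", "height", "width", "detections":
#' [{"class", "score", "box", "mask"}]}]}` where `mask` is either an inline
#' row-major RLE (`{"size": [H, W], "counts": [...]}`) or
#' `{"png": "relative/path.png"}`. Missing boxes are recomputed from masks;
#' a stated box disagreeing with the tight mask box by more than 1 pixel is
#' a consistency error; missing scores default to 1 (ground-truth
#' passthrough).
#'
#' @param path Manifest path.
#' @param source Source tag for the resulting sets.
#' @return List of [DetectionSet] objects.
#' @export
readDetections <- function(path, source = "external_model") {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("malformed detection manifest '", path, "': ", conditionMessage(e))
  )
  base <- dirname(path)
  lapply(doc$images, function(img) {
    dets <- lapply(img$detections, function(d) {
      m <- if (!is.null(d$mask$counts)) {
        rleDecode(list(
          size = unlist(d$mask$size),
          counts = unlist(d$mask$counts)
        ))
      } else if (!is.null(d$mask$png)) {
        p <- png::readPNG(file.path(base, d$mask$png))
        (if (length(dim(p)) == 3L) p[, , 1] else p) > 0.5
      } else {
        stop("detection of image '", img$image_id, "' lacks a mask")
      }
      tb <- tightBox(m)
      if (!is.null(d$box)) {
        stated <- as.integer(unlist(d$box))
        if (any(abs(stated - tb) > 1L)) {
          stop(
            "consistency error: stated box [", paste(stated, collapse = ","),
            "] of a '", d$class, "' detection in image '", img$image_id,
            "' disagrees with its mask box [", paste(tb, collapse = ","),
            "] by more than 1 px"
          )
        }
      }
      Detection(d$class, m, score = d$score %||% 1, box = tb)
    })
    DetectionSet(img$image_id %||% "<unnamed>", dets, source = source)
  })
}

#' Write a detection manifest
#'
#' Inverse of [readDetections()], with masks stored as inline row-major RLE.
#'
#' @param sets List of [DetectionSet] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeDetections <- function(sets, path) {
  images <- lapply(sets, function(ds) {
    shape <- if (length(ds@detections)) dim(ds@detections[[1]]@mask) else c(0L, 0L)
    list(
      image_id = ds@imageId, height = shape[1], width = shape[2],
      source = ds@source,
      detections = lapply(ds@detections, function(d) {
        list(
          class = d@label, score = d@score, box = as.integer(d@box),
          mask = rleEncode(d@mask)
        )
      })
    )
  })
  jsonlite::write_json(list(images = images), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
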