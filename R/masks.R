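# Mask ingestion, filtering, deduplication and per-frame QC.
# Masks arrive from any segmenter as binary grids; everything here is
# segmenter-agnostic.

.pix <- function(x) {
  if (is(x, "LabeledMask")) x@pixels else x
}

#' Label connected components of a binary mask
#'
#' Flood-fill labeling with configurable pixel connectivity. Exists
#' in-package because the analysis requires a 4/8-connectivity switch.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return integer matrix of component labels (0 = background).
#' @export
labelComponents <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  off <- if (connectivity == 4) {
    cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  } else {
    cbind(rep(-1:1, 3L), rep(-1:1, each = 3L))[-5L, , drop = FALSE]
  }
  cur <- 0L
  todo <- which(mask & lab == 0L)
  while (length(todo)) {
    cur <- cur + 1L
    frontier <- todo[1L]
    lab[frontier] <- cur
    while (length(frontier)) {
      r <- (frontier - 1L) %% nr + 1L
      cc <- (frontier - 1L) %/% nr + 1L
      nbr <- integer(0)
      for (k in seq_len(nrow(off))) {
        rr <- r + off[k, 1L]; c2 <- cc + off[k, 2L]
        ok <- rr >= 1L & rr <= nr & c2 >= 1L & c2 <= nc
        nbr <- c(nbr, (c2[ok] - 1L) * nr + rr[ok])
      }
      nbr <- unique(nbr)
      nbr <- nbr[mask[nbr] & lab[nbr] == 0L]
      lab[nbr] <- cur
      frontier <- nbr
    }
    todo <- which(mask & lab == 0L)
  }
  lab
}

#' Exclude masks touching the image border
#'
#' Masks with any true pixel in the first/last row or column are dropped:
#' such objects are partially out of frame and would bias morphometry.
#'
#' @param masks list of \linkS4class{LabeledMask}.
#' @param frameShape integer length-2 (rows, cols) extent all masks share.
#' @return The retained masks (possibly empty list).
#' @export
excludeEdgeMasks <- function(masks, frameShape) {
  keep <- vapply(masks, function(m) {
    p <- .pix(m)
    if (!all(dim(p) == frameShape))
      stop("mask dimensions ", paste(dim(p), collapse = "x"),
           " do not match frame shape ", paste(frameShape, collapse = "x"))
    !(any(p[1L, ]) || any(p[nrow(p), ]) || any(p[, 1L]) || any(p[, ncol(p)]))
  }, logical(1))
  masks[keep]
}

#' Deduplicate overlapping candidate masks
#'
#' Segmenters frequently emit several masks for one worm (sub-parts of the
#' body). Two masks are adjacent iff they share at least one pixel; within
#' each connected component of that overlap graph only the largest-area
#' mask is kept, so each worm is represented exactly once.
#'
#' @param masks list of \linkS4class{LabeledMask} on one frame.
#' @return list with one mask per overlap component.
#' @export
resolveOverlappingMasks <- function(masks) {
  n <- length(masks)
  if (n <= 1L) return(masks)
  areas <- vapply(masks, function(m) sum(.pix(m)), numeric(1))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    adj[i, j] <- adj[j, i] <- any(.pix(masks[[i]]) & .pix(masks[[j]]))
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  keep <- vapply(split(seq_len(n), comp), function(idx) {
    idx[which.max(areas[idx])]
  }, integer(1))
  masks[sort(keep)]
}

#' Remove small particles from a mask
#'
#' Components smaller than \code{minArea} are deleted; the largest
#' component always survives, so a valid (if small) worm is never erased.
#'
#' @param mask \linkS4class{LabeledMask} or logical matrix.
#' @param minArea minimum component area in pixels (>= 1).
#' @param connectivity 4 or 8 (default 8).
#' @return object of the same type as \code{mask}.
#' @export
cleanSmallParticles <- function(mask, minArea, connectivity = 8) {
  stopifnot(minArea >= 1)
  p <- .pix(mask)
  if (!any(p)) {
    warning("cleanSmallParticles: all-false mask returned unchanged")
    return(mask)
  }
  lab <- labelComponents(p, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= minArea)
  if (!length(keep)) keep <- which.max(sizes)
  out <- matrix(lab %in% keep & p, nrow(p), ncol(p))
  if (is(mask, "LabeledMask")) {
    mask@pixels <- out
    mask
  } else out
}

#' Per-frame quality control of a video mask stream
#'
#' Flags the artifact categories seen in propagated video segmentations:
#' empty masks, oversized regions and overlap with a sibling structure's
#' mask on the same frame.
#'
#' @param masksByFrame list of logical matrices (or LabeledMasks), one per
#'   frame, contiguously indexed.
#' @param maxArea area above which a mask counts as oversized. Default
#'   \code{NULL} uses 5x the median non-empty mask area of the stream.
#' @param siblingMasks optional parallel list of masks of another structure;
#'   overlap is tested pixelwise against it.
#' @return data.frame with columns frame, empty, oversized, overlapping.
#' @export
qcMaskStream <- function(masksByFrame, maxArea = NULL, siblingMasks = NULL) {
  areas <- vapply(masksByFrame, function(m) sum(.pix(m)), numeric(1))
  if (is.null(maxArea)) {
    nz <- areas[areas > 0]
    maxArea <- if (length(nz)) 5 * median(nz) else Inf
  }
  ov <- vapply(seq_along(masksByFrame), function(i) {
    if (is.null(siblingMasks)) return(FALSE)
    any(.pix(masksByFrame[[i]]) & .pix(siblingMasks[[i]]))
  }, logical(1))
  data.frame(
    frame = seq_along(masksByFrame) - 1L,
    empty = areas == 0,
    oversized = areas > maxArea,
    overlapping = ov
  )
}

#' Fill sporadic missing masks by temporal interpolation
#'
#' A missing (empty) frame is filled with the pixelwise union of the
#' nearest non-empty preceding and following masks, reduced to its largest
#' connected component. Runs of missing frames longer than \code{maxGap}
#' are refused: long dropouts need re-segmentation, not silent fills.
#'
#' @param masksByFrame list of logical matrices, one per frame.
#' @param maxGap longest run of missing frames that may be filled
#'   (default 3).
#' @param connectivity component connectivity for the cleanup step.
#' @return list of masks with gaps filled; untouched frames bit-identical.
#' @export
interpolateMissingMasks <- function(masksByFrame, maxGap = 3, connectivity = 8) {
  areas <- vapply(masksByFrame, function(m) sum(.pix(m)), numeric(1))
  miss <- which(areas == 0)
  if (!length(miss)) return(masksByFrame)
  n <- length(masksByFrame)
  if (areas[1L] == 0 || areas[n] == 0)
    stop("first and last frames must have non-empty masks")
  runs <- split(miss, cumsum(c(1L, diff(miss) != 1L)))
  for (run in runs) {
    if (length(run) > maxGap)
      stop("gap-too-long: frames ", paste(run - 1L, collapse = ","),
           " exceed the maximum interpolatable gap of ", maxGap)
    prev <- max(which(areas[seq_len(min(run) - 1L)] > 0))
    after <- (max(run) + 1L):n
    nxt <- after[areas[after] > 0][1L]
    filled <- .pix(masksByFrame[[prev]]) | .pix(masksByFrame[[nxt]])
    filled <- cleanSmallParticles(filled, minArea = sum(filled),
                                  connectivity = connectivity)
    for (f in run) masksByFrame[[f]] <- filled
  }
  masksByFrame
}

#' Default shape-heuristic worm classifier
#'
#' Labels a candidate "worm" iff its skeleton elongation (centerline length
#' over mean width) is at least \code{minElongation} and its solidity (area
#' over convex-ish bounding measure, here area over bounding-box area) sits
#' inside \code{solidityBand}. Transparent stand-in usable without trained
#' weights; any learned classifier can be plugged in via
#' \code{\link{classifyCandidates}}.
#'
#' @param minElongation minimum length/mean-width ratio (default 4).
#' @param solidityBand admissible range of mask area over bounding-box area
#'   (default \code{c(0.02, 0.7)}; elongated curved bodies fill little of
#'   their bounding box, solid blobs fill most of it).
#' @return function(mask, crop) -> label character.
#' @export
shapeHeuristicClassifier <- function(minElongation = 4,
                                     solidityBand = c(0.02, 0.7)) {
  function(mask, crop = NULL) {
    p <- .pix(mask)
    if (!any(p)) return("background")
    rr <- range(which(rowSums(p) > 0)); cc <- range(which(colSums(p) > 0))
    solidity <- sum(p) / ((diff(rr) + 1) * (diff(cc) + 1))
    sk <- tryCatch({
      one <- cleanSmallParticles(p, minArea = sum(p))
      maskToSkeleton(one, nPoints = 50L)
    }, error = function(e) NULL)
    if (is.null(sk)) {
      # compact blobs thin to (near) a point and have no usable skeleton;
      # solidity alone settles those
      return(if (solidity < solidityBand[1] || solidity > solidityBand[2])
               "not_worm" else "unclassified")
    }
    elong <- pixelLength(sk) / max(mean(skelWidths(sk)), 1e-9)
    if (elong >= minElongation && solidity >= solidityBand[1] &&
        solidity <= solidityBand[2]) "worm" else "not_worm"
  }
}

#' Attach classifier labels to candidate masks
#'
#' Runs a pluggable classifier over mask cutouts. A classifier failure on
#' one crop labels it \code{"unclassified"} (and logs); crops are never
#' dropped silently.
#'
#' @param masks list of \linkS4class{LabeledMask}.
#' @param crops optional list of image crops passed through to the
#'   classifier.
#' @param classifier function(mask, crop) returning a label; default
#'   \code{\link{shapeHeuristicClassifier}()}.
#' @return the masks with \code{label} slots filled.
#' @export
classifyCandidates <- function(masks, crops = NULL,
                               classifier = shapeHeuristicClassifier()) {
  for (i in seq_along(masks)) {
    lab <- tryCatch(
      classifier(masks[[i]], if (is.null(crops)) NULL else crops[[i]]),
      error = function(e) {
        message("classifier failed on candidate ", i, ": ", conditionMessage(e))
        "unclassified"
      })
    if (!lab %in% .maskLabels) lab <- "unclassified"
    masks[[i]]@label <- lab
  }
  masks
}

# ---- mask stream I/O -------------------------------------------------------

#' Read a mask stream
#'
#' Accepts a multi-page TIFF (values > 0 are true) or a directory of
#' per-frame PNGs (sorted by filename).
#'
#' @param path TIFF file or PNG directory.
#' @return list of logical matrices, one per frame.
#' @export
readMaskStack <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    lapply(files, function(f) {
      img <- png::readPNG(f)
      if (length(dim(img)) == 3L) img <- img[, , 1L]
      img > 0
    })
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    lapply(pages, function(img) {
      if (length(dim(img)) == 3L) img <- img[, , 1L]
      img > 0
    })
  }
}

#' Write a mask stream as multi-page TIFF
#'
#' @param masks list of logical matrices.
#' @param path output .tif path.
#' @export
writeMaskStack <- function(masks, path) {
  imgs <- lapply(masks, function(m) {
    storage.mode(m) <- "numeric"
    m
  })
  tiff::writeTIFF(imgs, path, bits.per.sample = 8L)
  invisible(path)
}

#' Write a QC report CSV (frame,empty,oversized,overlapping)
#'
#' @param report data.frame from \code{\link{qcMaskStream}}.
#' @param path output CSV path.
#' @export
writeQCReport <- function(report, path) {
  write.csv(report, path, row.names = FALSE)
  invisible(path)
}

#' Record a SAM/SAM2 adapter configuration
#'
#' The upstream foundation-model segmenter is outside this package; its
#' documented mask-generation hyperparameters can be recorded alongside an
#' analysis for provenance. Execution of the adapter is out of scope.
#'
#' @param path YAML file to write.
#' @param points_per_side,pred_iou_thresh,stability_score_thresh,min_mask_region_area
#'   mask-generator settings to record.
#' @export
writeSamAdapterConfig <- function(path, points_per_side = 32,
                                  pred_iou_thresh = 0.95,
                                  stability_score_thresh = 0.95,
                                  min_mask_region_area = 1500) {
  yaml::write_yaml(list(
    adapter = "sam",
    executed_by_this_package = FALSE,
    points_per_side = points_per_side,
    pred_iou_thresh = pred_iou_thresh,
    stability_score_thresh = stability_score_thresh,
    min_mask_region_area = min_mask_region_area
  ), path)
  invisible(path)
}
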