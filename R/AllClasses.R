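#' LabeledMask: one candidate object segmentation on one frame
#'
#' Wraps a binary pixel grid together with its provenance and classifier
#' label. The grid uses image coordinates: \code{pixels[row, col]}, row 1 at
#' the top of the frame.
#'
#' @slot pixels logical matrix, the mask.
#' @slot frameIndex integer, 0-based frame index within the recording.
#' @slot label character, one of \code{"worm"}, \code{"not_worm"},
#'   \code{"background"}, \code{"unclassified"}.
#' @slot source character, free-text provenance tag.
#' @export
setClass("LabeledMask",
  representation(
    pixels = "matrix",
    frameIndex = "integer",
    label = "character",
    source = "character"
  ),
  prototype(frameIndex = 0L, label = "unclassified", source = "")
)

.maskLabels <- c("worm", "not_worm", "background", "unclassified")

setValidity("LabeledMask", function(object) {
  msgs <- character(0)
  if (!is.logical(object@pixels))
    msgs <- c(msgs, "pixels must be a logical matrix")
  if (length(object@frameIndex) != 1L || object@frameIndex < 0L)
    msgs <- c(msgs, "frameIndex must be a single non-negative integer")
  if (!(object@label %in% .maskLabels))
    msgs <- c(msgs, sprintf("label must be one of %s",
                            paste(.maskLabels, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Construct a LabeledMask
#'
#' @param pixels logical (or coercible numeric, >0 means true) matrix.
#' @param frameIndex 0-based frame index.
#' @param label classifier label; defaults to \code{"unclassified"}.
#' @param source provenance tag.
#' @return A \linkS4class{LabeledMask}.
#' @examples
#' m <- matrix(FALSE, 20, 20); m[5:10, 5:10] <- TRUE
#' LabeledMask(m, frameIndex = 0)
#' @export
LabeledMask <- function(pixels, frameIndex = 0L, label = "unclassified",
                        source = "") {
  if (!is.logical(pixels)) {
    stopifnot(is.numeric(pixels))
    pixels <- matrix(pixels > 0, nrow(pixels), ncol(pixels))
  }
  new("LabeledMask", pixels = pixels, frameIndex = as.integer(frameIndex),
      label = label, source = source)
}

#' WormSkeleton: ordered fixed-resolution centerline with width profile
#'
#' The centerline is resampled to exactly \code{nPoints} real-valued
#' \code{(row, col)} coordinates, ordered along the body. Orientation
#' (which end is the head) is assigned later by the tracking stage;
#' until then point order is arbitrary but consistent.
#'
#' @slot points numeric matrix nPoints x 2 (row, col).
#' @slot widths numeric vector of per-point body widths (diameter, px).
#' @slot frameIndex integer frame index.
#' @export
setClass("WormSkeleton",
  representation(
    points = "matrix",
    widths = "numeric",
    frameIndex = "integer"
  ),
  prototype(frameIndex = 0L)
)

setValidity("WormSkeleton", function(object) {
  p <- object@points
  msgs <- character(0)
  if (!is.numeric(p) || ncol(p) != 2L)
    msgs <- c(msgs, "points must be a numeric n x 2 matrix")
  if (nrow(p) < 2L)
    msgs <- c(msgs, "skeleton needs at least 2 points")
  else {
    d <- sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
    if (any(d <= 0))
      msgs <- c(msgs, "consecutive skeleton points must be distinct")
  }
  if (length(object@widths) && length(object@widths) != nrow(p))
    msgs <- c(msgs, "widths must have one entry per point")
  if (any(object@widths < 0))
    msgs <- c(msgs, "widths must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Construct a WormSkeleton
#'
#' @param points numeric n x 2 matrix of (row, col) coordinates.
#' @param widths optional per-point width profile (px); defaults to zeros.
#' @param frameIndex frame index.
#' @return A \linkS4class{WormSkeleton}.
#' @export
WormSkeleton <- function(points, widths = numeric(0), frameIndex = 0L) {
  points <- as.matrix(points)
  dimnames(points) <- NULL
  if (!length(widths)) widths <- rep(0, nrow(points))
  new("WormSkeleton", points = points, widths = as.numeric(widths),
      frameIndex = as.integer(frameIndex))
}

#' CompartmentTraces: per-frame brightness for named neuronal compartments
#'
#' Holds raw mean brightness per compartment, the per-frame background
#' estimate, and the background-corrected traces
#' (\code{corrected = raw - background}, elementwise).
#'
#' @slot raw numeric matrix frames x compartments (camera units).
#' @slot background numeric vector, one value per frame.
#' @slot compartments character vector of compartment names.
#' @export
setClass("CompartmentTraces",
  representation(
    raw = "matrix",
    background = "numeric",
    compartments = "character"
  )
)

setValidity("CompartmentTraces", function(object) {
  msgs <- character(0)
  if (ncol(object@raw) != length(object@compartments))
    msgs <- c(msgs, "one raw column per compartment required")
  if (length(object@background) != nrow(object@raw))
    msgs <- c(msgs, "background must have one value per frame")
  if (length(msgs)) msgs else TRUE
})

#' Construct CompartmentTraces
#'
#' @param raw frames x compartments numeric matrix of mean mask brightness.
#' @param background per-frame background estimate (camera units).
#' @param compartments compartment names; default the three RIA axonal
#'   compartments \code{c("nrD", "nrV", "loop")}.
#' @return A \linkS4class{CompartmentTraces}.
#' @export
CompartmentTraces <- function(raw, background,
                              compartments = colnames(raw)) {
  raw <- as.matrix(raw)
  if (is.null(compartments)) compartments <- c("nrD", "nrV", "loop")[seq_len(ncol(raw))]
  colnames(raw) <- compartments
  new("CompartmentTraces", raw = raw, background = as.numeric(background),
      compartments = compartments)
}
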