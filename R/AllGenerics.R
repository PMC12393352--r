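#' @name accessors
#' @title Accessors for nemaquant S4 classes
#' @description Slot access goes through these accessors rather than
#'   \code{@}: \code{maskPixels}/\code{maskArea}/\code{maskLabel} for
#'   \linkS4class{LabeledMask}; \code{skelPoints}/\code{skelWidths}/
#'   \code{nPoints}/\code{pixelLength} for \linkS4class{WormSkeleton};
#'   \code{rawBrightness}/\code{backgroundTrace}/\code{correctedBrightness}
#'   for \linkS4class{CompartmentTraces}. \code{frameIndex} works on masks
#'   and skeletons.
#' @param x an object of the matching class.
#' @return The slot contents (or, for derived quantities such as
#'   \code{maskArea}, \code{pixelLength} and \code{correctedBrightness},
#'   the value computed from them).
NULL

#' @rdname accessors
#' @export
setGeneric("maskPixels", function(x) standardGeneric("maskPixels"))
#' @rdname accessors
#' @export
setGeneric("maskArea", function(x) standardGeneric("maskArea"))
#' @rdname accessors
#' @export
setGeneric("maskLabel", function(x) standardGeneric("maskLabel"))
#' @rdname accessors
#' @export
setGeneric("frameIndex", function(x) standardGeneric("frameIndex"))
#' @rdname accessors
#' @export
setGeneric("skelPoints", function(x) standardGeneric("skelPoints"))
#' @rdname accessors
#' @export
setGeneric("skelWidths", function(x) standardGeneric("skelWidths"))
#' @rdname accessors
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))
#' @rdname accessors
#' @export
setGeneric("pixelLength", function(x) standardGeneric("pixelLength"))
#' @rdname accessors
#' @export
setGeneric("rawBrightness", function(x) standardGeneric("rawBrightness"))
#' @rdname accessors
#' @export
setGeneric("backgroundTrace", function(x) standardGeneric("backgroundTrace"))
#' @rdname accessors
#' @export
setGeneric("correctedBrightness", function(x) standardGeneric("correctedBrightness"))

#' @rdname accessors
setMethod("maskPixels", "LabeledMask", function(x) x@pixels)
#' @rdname accessors
setMethod("maskArea", "LabeledMask", function(x) sum(x@pixels))
#' @rdname accessors
setMethod("maskLabel", "LabeledMask", function(x) x@label)
#' @rdname accessors
setMethod("frameIndex", "LabeledMask", function(x) x@frameIndex)
#' @rdname accessors
setMethod("frameIndex", "WormSkeleton", function(x) x@frameIndex)

#' @rdname accessors
setMethod("skelPoints", "WormSkeleton", function(x) x@points)
#' @rdname accessors
setMethod("skelWidths", "WormSkeleton", function(x) x@widths)
#' @rdname accessors
setMethod("nPoints", "WormSkeleton", function(x) nrow(x@points))
#' @rdname accessors
setMethod("pixelLength", "WormSkeleton", function(x) {
  p <- x@points
  sum(sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
})

#' @rdname accessors
setMethod("rawBrightness", "CompartmentTraces", function(x) x@raw)
#' @rdname accessors
setMethod("backgroundTrace", "CompartmentTraces", function(x) x@background)
#' @rdname accessors
setMethod("correctedBrightness", "CompartmentTraces", function(x) x@raw - x@background)

setMethod("show", "LabeledMask", function(object) {
  cat(sprintf("LabeledMask frame %d: %dx%d grid, area %d px, label '%s'%s\n",
              object@frameIndex, nrow(object@pixels), ncol(object@pixels),
              sum(object@pixels), object@label,
              if (nzchar(object@source)) paste0(" [", object@source, "]") else ""))
})

setMethod("show", "WormSkeleton", function(object) {
  cat(sprintf("WormSkeleton frame %d: %d points, length %.1f px, mean width %.1f px\n",
              object@frameIndex, nrow(object@points), pixelLength(object),
              mean(object@widths)))
})

setMethod("show", "CompartmentTraces", function(object) {
  cat(sprintf("CompartmentTraces: %d frames x %s\n", nrow(object@raw),
              paste(object@compartments, collapse = "/")))
  cat(sprintf("  background: %.1f-%.1f; corrected range: %.1f-%.1f\n",
              min(object@background), max(object@background),
              min(correctedBrightness(object)), max(correctedBrightness(object))))
})
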