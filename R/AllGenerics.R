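## Generics, accessors and show methods.

#' Estimability index accessor
#' @param object an \linkS4class{EstimabilityResult}.
#' @return the scalar e' value.
#' @export
setGeneric("ePrime", function(object) standardGeneric("ePrime"))

#' @rdname ePrime
#' @export
setMethod("ePrime", "EstimabilityResult", function(object) object@ePrime)

#' Stenosis precision accessor (percent SD)
#' @param object an \linkS4class{EstimabilityResult}.
#' @return the ensemble standard deviation expressed in percent stenosis.
#' @export
setGeneric("precisionPct", function(object) standardGeneric("precisionPct"))

#' @rdname precisionPct
#' @export
setMethod("precisionPct", "EstimabilityResult",
          function(object) object@precisionPct)

#' Degeneracy flags accessor
#' @param object an \linkS4class{EstimabilityResult}.
#' @return named logical vector of degeneracy flags.
#' @export
setGeneric("degeneracyFlags",
           function(object) standardGeneric("degeneracyFlags"))

#' @rdname degeneracyFlags
#' @export
setMethod("degeneracyFlags", "EstimabilityResult",
          function(object) object@flags)

#' Per-instance estimates accessor
#' @param object an \linkS4class{EstimateDistribution}.
#' @return numeric vector of estimated stenosis fractions.
#' @export
setGeneric("estimates", function(object) standardGeneric("estimates"))

#' @rdname estimates
#' @export
setMethod("estimates", "EstimateDistribution",
          function(object) object@estimates)

#' Pixel size accessor
#' @param object an image- or kernel-like object.
#' @return pixel size in mm.
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "PhantomImage", function(object) object@pixelSize)
#' @rdname pixelSize
#' @export
setMethod("pixelSize", "MotionKernel", function(object) object@pixelSize)
#' @rdname pixelSize
#' @export
setMethod("pixelSize", "ImageInstance", function(object) object@pixelSize)
#' @rdname pixelSize
#' @export
setMethod("pixelSize", "TemplateBank", function(object) object@pixelSize)

#' @describeIn pixelSize hyper pixel size of a grid
#'   (\code{clinicalPixel / hyperFactor}).
#' @export
setMethod("pixelSize", "GridSpec",
          function(object) object@clinicalPixel / object@hyperFactor)

## Matrix views -------------------------------------------------------------

#' @export
setMethod("as.matrix", "PhantomImage", function(x, ...) x@values)
#' @export
setMethod("as.matrix", "MotionKernel", function(x, ...) x@values)
#' @export
setMethod("as.matrix", "ImageInstance", function(x, ...) x@values)

#' @export
setMethod("dim", "PhantomImage", function(x) dim(x@values))
#' @export
setMethod("dim", "MotionKernel", function(x) dim(x@values))
#' @export
setMethod("dim", "ImageInstance", function(x) dim(x@values))

## show methods --------------------------------------------------------------

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %.3f mm clinical pixel, %dx hyper, FOV %.1f mm (%d x %d hyper px)\n",
              object@clinicalPixel, object@hyperFactor, object@fov,
              gridHyperN(object), gridHyperN(object)))
})

setMethod("show", "VesselSpec", function(object) {
  cat(sprintf("VesselSpec: d_ref %.2f mm, stenosis %.0f%%, %s plaque (%g HU), lumen %g HU\n",
              object@referenceDiameter, 100 * object@stenosisFraction,
              object@material, object@plaqueHu, object@lumenHu))
})

setMethod("show", "PhantomImage", function(object) {
  cat(sprintf("PhantomImage: %d x %d @ %.4f mm, HU range [%.0f, %.0f]\n",
              nrow(object@values), ncol(object@values), object@pixelSize,
              min(object@values), max(object@values)))
})

setMethod("show", "AcquisitionGeometry", function(object) {
  cat(sprintf("AcquisitionGeometry: %.2f s rotation, %d source(s), %d segment(s), span %.0f deg (%s, %s weights)\n",
              object@rotationTime, object@nSources, object@nSegments,
              object@reconSpan * 180 / pi, object@rotationSense,
              object@weighting))
})

setMethod("show", "MotionKernel", function(object) {
  cat(sprintf("MotionKernel: %d x %d @ %.4f mm, effective temporal resolution %.1f ms\n",
              nrow(object@values), ncol(object@values), object@pixelSize,
              object@temporalResolutionMs))
})

setMethod("show", "TTFCurve", function(object) {
  cat(sprintf("TTFCurve: f50 %.3f /mm, %d samples to %.2f /mm\n",
              object@f50, length(object@freq), max(object@freq)))
})

setMethod("show", "NPSCurve", function(object) {
  cat(sprintf("NPSCurve: sigma %.1f HU, %d radial samples to %.2f /mm\n",
              object@sigma, length(object@freq), max(object@freq)))
})

setMethod("show", "ImageInstance", function(object) {
  cat(sprintf("ImageInstance: %d x %d @ %.3f mm (case %s)\n",
              nrow(object@values), ncol(object@values), object@pixelSize,
              if (is.null(object@provenance$case_id)) "?" else
                object@provenance$case_id))
})

setMethod("show", "TemplateBank", function(object) {
  cat(sprintf("TemplateBank: %d templates (%d x %d px), stenosis [%.2f, %.2f], motion mode '%s'\n",
              ncol(object@templates), object@dim[1], object@dim[2],
              min(object@stenosis), max(object@stenosis), object@mode))
})

setMethod("show", "EstimateDistribution", function(object) {
  cat(sprintf("EstimateDistribution: n = %d, truth %.3f, mean %.3f, sd %.4f (%d clipped)\n",
              length(object@estimates), object@truth,
              mean(object@estimates), sd(object@estimates),
              object@nClipped))
})

setMethod("show", "EstimabilityResult", function(object) {
  fl <- names(object@flags)[object@flags]
  cat(sprintf("EstimabilityResult: e' = %.2f (precision %.2f%%), n = %d%s\n",
              object@ePrime, object@precisionPct, object@n,
              if (length(fl)) paste0(" [", paste(fl, collapse = ", "), "]")
              else ""))
})

setMethod("show", "CaseSpec", function(object) {
  cat(sprintf("CaseSpec '%s': %s, HR %.0f bpm, %s, stenosis %.0f%%, %s plaque, contrast %.0f HU, sigma %.0f HU\n",
              object@id, object@sex, object@heartRate, object@ahaSegment,
              object@stenosisPct, object@material,
              object@lumenEnhancement, object@sigma))
})
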