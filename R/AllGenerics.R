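# Accessor generics and show methods for the central data objects.

#' Lifetime matrix accessor
#' @param x a LifetimeImage or PriorImage.
#' @return numeric matrix of lifetimes (ns).
#' @export
setGeneric("tauMap", function(x) standardGeneric("tauMap"))

#' Validity-mask accessor
#' @param x a LifetimeImage or PriorImage.
#' @return logical matrix.
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' Intensity values accessor
#' @param x an IntensityImage.
#' @return numeric matrix.
#' @export
setGeneric("intensityValues", function(x) standardGeneric("intensityValues"))

#' Photon-count array accessor
#' @param x a FLIMDataCube.
#' @return integer array [m, n, t].
#' @export
setGeneric("photonCounts", function(x) standardGeneric("photonCounts"))

#' Time-bin width accessor
#' @param x a FLIMDataCube.
#' @return bin width in ns.
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' Instrument response function accessor
#' @param x a FLIMDataCube.
#' @return numeric vector (length 0 when absent).
#' @export
setGeneric("instrumentResponse", function(x) standardGeneric("instrumentResponse"))

#' Upsampling factor accessor
#' @param x a SamplingSpec.
#' @return integer factor.
#' @export
setGeneric("upsamplingFactor", function(x) standardGeneric("upsamplingFactor"))

#' Sample offset accessor
#' @param x a SamplingSpec.
#' @return integer length-2 (row, col) offset.
#' @export
setGeneric("sampleOffset", function(x) standardGeneric("sampleOffset"))

#' @rdname tauMap
#' @export
setMethod("tauMap", "LifetimeImage", function(x) x@tau)
#' @rdname tauMap
#' @export
setMethod("tauMap", "PriorImage", function(x) x@tau)
#' @rdname validMask
#' @export
setMethod("validMask", "LifetimeImage", function(x) x@valid)
#' @rdname validMask
#' @export
setMethod("validMask", "PriorImage", function(x) x@valid)
#' @rdname intensityValues
#' @export
setMethod("intensityValues", "IntensityImage", function(x) x@values)
#' @rdname photonCounts
#' @export
setMethod("photonCounts", "FLIMDataCube", function(x) x@counts)
#' @rdname binWidth
#' @export
setMethod("binWidth", "FLIMDataCube", function(x) x@binWidth)
#' @rdname instrumentResponse
#' @export
setMethod("instrumentResponse", "FLIMDataCube", function(x) x@irf)
#' @rdname upsamplingFactor
#' @export
setMethod("upsamplingFactor", "SamplingSpec", function(x) x@factor)
#' @rdname sampleOffset
#' @export
setMethod("sampleOffset", "SamplingSpec", function(x) x@offset)

#' @describeIn LifetimeImage-class image dimensions.
#' @param x object.
#' @export
setMethod("dim", "LifetimeImage", function(x) dim(x@tau))
#' @describeIn IntensityImage-class image dimensions.
#' @param x object.
#' @export
setMethod("dim", "IntensityImage", function(x) dim(x@values))
#' @describeIn PriorImage-class image dimensions.
#' @param x object.
#' @export
setMethod("dim", "PriorImage", function(x) dim(x@tau))
#' @describeIn FLIMDataCube-class cube dimensions [m, n, t].
#' @param x object.
#' @export
setMethod("dim", "FLIMDataCube", function(x) dim(x@counts))

setMethod("show", "SamplingSpec", function(object) {
  cat(sprintf("SamplingSpec: factor %d, offset (%d, %d)\n",
      object@factor, object@offset[1], object@offset[2]))
})

setMethod("show", "LifetimeImage", function(object) {
  d <- dim(object@tau)
  tv <- object@tau[object@valid]
  cat(sprintf("LifetimeImage: %d x %d, %d/%d valid", d[1], d[2],
      sum(object@valid), length(object@valid)))
  if (length(tv))
    cat(sprintf(", tau range [%.3g, %.3g] ns", min(tv), max(tv)))
  cat("\n")
})

setMethod("show", "IntensityImage", function(object) {
  d <- dim(object@values)
  cat(sprintf("IntensityImage: %d x %d, range [%.4g, %.4g]\n",
      d[1], d[2], min(object@values), max(object@values)))
})

setMethod("show", "PriorImage", function(object) {
  d <- dim(object@tau)
  cat(sprintf("PriorImage: %d x %d, %d/%d valid\n", d[1], d[2],
      sum(object@valid), length(object@valid)))
})

setMethod("show", "FLIMDataCube", function(object) {
  d <- dim(object@counts)
  cat(sprintf(
    "FLIMDataCube: %d x %d pixels, %d time bins of %.4g ns, %s photons, %s\n",
    d[1], d[2], d[3], object@binWidth,
    format(sum(object@counts), big.mark = ","),
    if (length(object@irf)) "with IRF" else "no IRF"))
})

setMethod("show", "Homography", function(object) {
  cat("Homography (row, col convention):\n")
  print(round(object@matrix, 6))
})
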