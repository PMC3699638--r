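# Accessor generics and show methods for the S4 containers.

#' @rdname BoldSeries-class
#' @param object,x a package object.
#' @export
setGeneric("boldData", function(x) standardGeneric("boldData"))

#' @rdname BoldSeries-class
#' @export
setGeneric("trSeconds", function(x) standardGeneric("trSeconds"))

#' @rdname BoldSeries-class
#' @export
setGeneric("nVolumes", function(x) standardGeneric("nVolumes"))

#' @rdname BoldSeries-class
#' @export
setGeneric("spatialDim", function(x) standardGeneric("spatialDim"))

#' @rdname BoldSeries-class
#' @export
setGeneric("voxelDims", function(x) standardGeneric("voxelDims"))

#' @rdname TissueMasks-class
#' @export
setGeneric("maskClasses", function(x) standardGeneric("maskClasses"))

#' @rdname TissueMasks-class
#' @param class tissue class name ("GM", "WM", "WMH", "CSF", or "NAWM").
#' @export
setGeneric("getMask", function(x, class) standardGeneric("getMask"))

#' @rdname VoxelMetricMap-class
#' @export
setGeneric("metricValues", function(x) standardGeneric("metricValues"))

#' @rdname VoxelMetricMap-class
#' @export
setGeneric("metricName", function(x) standardGeneric("metricName"))

#' @rdname NoiseDecomposition-class
#' @export
setGeneric("metricMap", function(x) standardGeneric("metricMap"))

#' @rdname NoiseDecomposition-class
#' @export
setGeneric("clippedCount", function(x) standardGeneric("clippedCount"))

#' @rdname CardiacFrequency-class
#' @export
setGeneric("fcHz", function(x) standardGeneric("fcHz"))

#' @rdname BoldSeries-class
#' @export
setMethod("boldData", "BoldSeries", function(x) x@data)

#' @rdname BoldSeries-class
#' @export
setMethod("trSeconds", "BoldSeries", function(x) x@trSeconds)

#' @rdname VoxelMetricMap-class
#' @export
setMethod("trSeconds", "VoxelMetricMap", function(x) x@trSeconds)

#' @rdname BoldSeries-class
#' @export
setMethod("nVolumes", "BoldSeries", function(x) dim(x@data)[4L])

#' @rdname BoldSeries-class
#' @export
setMethod("spatialDim", "BoldSeries", function(x) dim(x@data)[1:3])

#' @rdname TissueMasks-class
#' @export
setMethod("spatialDim", "TissueMasks", function(x) dim(x@masks[[1L]]))

#' @rdname BoldSeries-class
#' @export
setMethod("voxelDims", "BoldSeries", function(x) x@voxelDimsMm)

#' @rdname TissueMasks-class
#' @export
setMethod("maskClasses", "TissueMasks", function(x) names(x@masks))

#' @rdname TissueMasks-class
#' @export
setMethod("getMask", "TissueMasks", function(x, class) {
  if (class == "NAWM") {
    wm <- x@masks[["WM"]]
    if (is.null(wm)) stop("NAWM requested but no WM mask present")
    if (!is.null(x@masks[["WMH"]])) wm <- wm & !x@masks[["WMH"]]
    return(wm)
  }
  m <- x@masks[[class]]
  if (is.null(m)) stop("no mask for tissue class '", class, "'")
  m
})

#' @rdname VoxelMetricMap-class
#' @export
setMethod("metricValues", "VoxelMetricMap", function(x) x@values)

#' @rdname VoxelMetricMap-class
#' @export
setMethod("metricName", "VoxelMetricMap", function(x) x@metricName)

#' @rdname NoiseDecomposition-class
#' @export
setMethod("metricMap", "NoiseDecomposition", function(x) x@map)

#' @rdname NoiseDecomposition-class
#' @export
setMethod("clippedCount", "NoiseDecomposition", function(x) x@clippedCount)

#' @rdname CardiacFrequency-class
#' @export
setMethod("fcHz", "CardiacFrequency", function(x) x@fcHz)

setMethod("show", "BoldSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf("BoldSeries: %d x %d x %d grid, %d volumes, TR %.3g s (Nyquist %.3g Hz)\n",
              d[1], d[2], d[3], d[4], object@trSeconds,
              1 / (2 * object@trSeconds)))
  cat(sprintf("  voxels: %g x %g x %g mm\n", object@voxelDimsMm[1],
              object@voxelDimsMm[2], object@voxelDimsMm[3]))
})

setMethod("show", "TissueMasks", function(object) {
  d <- dim(object@masks[[1L]])
  cat(sprintf("TissueMasks on a %d x %d x %d grid:\n", d[1], d[2], d[3]))
  for (nm in names(object@masks))
    cat(sprintf("  %-4s %d voxels\n", nm, sum(object@masks[[nm]])))
})

setMethod("show", "PulseTrace", function(object) {
  cat(sprintf("PulseTrace: %d samples over %.1f s, mean %.1f bpm\n",
              length(object@bpm), diff(range(object@timesSeconds)),
              mean(object@bpm)))
})

setMethod("show", "VoxelMetricMap", function(object) {
  v <- object@values[!is.na(object@values)]
  cat(sprintf("VoxelMetricMap '%s': %d defined voxels, mean %.4g %% of voxel mean\n",
              object@metricName, length(v),
              if (length(v)) mean(v) else NA_real_))
})

setMethod("show", "NoiseDecomposition", function(object) {
  cat(sprintf("NoiseDecomposition: sigma2_therm = %.4g, %d clipped, %d undefined voxels\n",
              object@sigma2Therm, object@clippedCount, object@undefinedCount))
  show(object@map)
})

setMethod("show", "CardiacFrequency", function(object) {
  cat(sprintf("CardiacFrequency: %.4g Hz (+/- %.3g Hz window, %s)\n",
              object@fcHz, object@halfWindowHz, object@source))
})

setMethod("show", "ThermalRoi", function(object) {
  cat(sprintf("ThermalRoi: corner '%s', %d voxels\n", object@corner,
              sum(object@mask)))
})
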