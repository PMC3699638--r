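#' @import methods
NULL

#' BoldSeries: a 4D BOLD time series
#'
#' Container for an echo-planar BOLD acquisition: a 4D numeric grid
#' (x, y, z, t) in arbitrary scanner units together with its repetition
#' time and voxel dimensions. The temporal variance of each voxel's time
#' course is the raw material for the physiological-noise decomposition.
#'
#' @slot data 4D numeric array (x, y, z, t); all values finite.
#' @slot trSeconds sampling interval (repetition time) in seconds, > 0.
#' @slot voxelDimsMm numeric length-3, positive voxel extents in mm.
#'
#' @seealso [readBold()], [trimVolumes()], [sigmaPhysioMap()]
#' @export
setClass("BoldSeries",
  representation(
    data = "array",
    trSeconds = "numeric",
    voxelDimsMm = "numeric"
  )
)

setValidity("BoldSeries", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 4L)
    msg <- c(msg, sprintf("expected 4D data, got %dD", length(dim(object@data))))
  if (length(object@trSeconds) != 1L || !is.finite(object@trSeconds) ||
      object@trSeconds <= 0)
    msg <- c(msg, "trSeconds must be a single positive number")
  if (length(object@voxelDimsMm) != 3L || any(!is.finite(object@voxelDimsMm)) ||
      any(object@voxelDimsMm <= 0))
    msg <- c(msg, "voxelDimsMm must be three positive values")
  if (anyNA(object@data) || any(!is.finite(object@data)))
    msg <- c(msg, "data contains non-finite values")
  if (length(msg)) msg else TRUE
})

#' Construct a BoldSeries
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param trSeconds repetition time in seconds.
#' @param voxelDimsMm voxel dimensions in mm (default 3 x 3 x 5, the
#'   cardiac-sampled acquisition geometry).
#' @return A [BoldSeries-class] object.
#' @export
BoldSeries <- function(data, trSeconds, voxelDimsMm = c(3, 3, 5)) {
  new("BoldSeries", data = data, trSeconds = as.numeric(trSeconds),
      voxelDimsMm = as.numeric(voxelDimsMm))
}

#' TissueMasks: per-class binary masks in BOLD space
#'
#' Boolean 3D grids, one per tissue class, on the same spatial grid as the
#' BOLD series they annotate. Recognised class names are GM, WM, WMH and
#' CSF. Normal-appearing white matter (NAWM) is derived as WM minus WMH.
#'
#' @slot masks named list of logical 3D arrays with identical dimensions.
#' @export
setClass("TissueMasks", representation(masks = "list"))

.known_classes <- c("GM", "WM", "WMH", "CSF")

setValidity("TissueMasks", function(object) {
  msg <- character()
  if (length(object@masks) == 0L)
    return("at least one tissue mask is required")
  nm <- names(object@masks)
  if (is.null(nm) || any(!nzchar(nm)))
    msg <- c(msg, "masks must be named")
  unknown <- setdiff(nm, .known_classes)
  if (length(unknown))
    msg <- c(msg, paste("unknown tissue classes:", paste(unknown, collapse = ", ")))
  if (!any(c("GM", "WM") %in% nm))
    msg <- c(msg, "at least one of GM, WM must be present")
  dims <- lapply(object@masks, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    msg <- c(msg, "every mask must be a 3D array")
  if (length(dims) > 1L && !all(vapply(dims[-1], identical, TRUE, dims[[1]])))
    msg <- c(msg, "mask dimensions differ between classes")
  if (any(!vapply(object@masks, is.logical, TRUE)))
    msg <- c(msg, "masks must be logical arrays")
  if (length(msg)) msg else TRUE
})

#' Construct TissueMasks
#'
#' @param ... named logical 3D arrays (GM, WM, optionally WMH, CSF), or a
#'   single named list of them.
#' @return A [TissueMasks-class] object.
#' @export
TissueMasks <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1]]) && !is.array(args[[1]]))
    args <- args[[1]]
  new("TissueMasks", masks = args)
}

#' PulseTrace: pulse-oximetry heart-rate samples
#'
#' Time-stamped heart-rate readings recorded during the resting-state scan,
#' from which the cardiac frequency is derived.
#'
#' @slot timesSeconds nondecreasing sample times in seconds.
#' @slot bpm heart rate in beats per minute, all within \[30, 200\].
#' @export
setClass("PulseTrace",
  representation(timesSeconds = "numeric", bpm = "numeric"))

setValidity("PulseTrace", function(object) {
  msg <- character()
  if (length(object@timesSeconds) != length(object@bpm))
    msg <- c(msg, "times and bpm must have equal length")
  if (length(object@bpm) == 0L)
    msg <- c(msg, "trace is empty")
  if (length(object@timesSeconds) > 1L && any(diff(object@timesSeconds) < 0))
    msg <- c(msg, "sample times must be nondecreasing")
  if (length(object@bpm) && (any(object@bpm < 30) || any(object@bpm > 200)))
    msg <- c(msg, "bpm outside plausibility band [30, 200]")
  if (length(msg)) msg else TRUE
})

#' Construct a PulseTrace
#' @param timesSeconds sample times (s), nondecreasing.
#' @param bpm heart-rate samples (beats/min) within \[30, 200\].
#' @return A [PulseTrace-class] object.
#' @export
PulseTrace <- function(timesSeconds, bpm) {
  new("PulseTrace", timesSeconds = as.numeric(timesSeconds),
      bpm = as.numeric(bpm))
}

#' ThermalRoi: out-of-brain region for thermal-noise estimation
#'
#' A corner region of the imaging grid, excluding all tissue voxels, over
#' which the thermal (scanner/electronic) variance is averaged. Corner
#' placement avoids the EPI ghosting artifact.
#'
#' @slot corner one of "x0y0", "x1y0", "x0y1", "x1y1", or "all" for the
#'   union of the four corners.
#' @slot extentVoxels in-plane extent of each corner block (voxels).
#' @slot mask logical 3D array marking the ROI voxels.
#' @export
setClass("ThermalRoi",
  representation(corner = "character", extentVoxels = "integer",
                 mask = "array"))

setValidity("ThermalRoi", function(object) {
  msg <- character()
  if (length(dim(object@mask)) != 3L || !is.logical(object@mask))
    msg <- c(msg, "mask must be a logical 3D array")
  if (!any(object@mask))
    msg <- c(msg, "thermal ROI is empty")
  if (length(msg)) msg else TRUE
})

#' VoxelMetricMap: a voxelwise percent-of-mean metric
#'
#' A 3D grid of nonnegative values expressed as percent of each voxel's
#' temporal mean signal; voxels outside the evaluated mask (or with
#' nonpositive mean) are NA.
#'
#' @slot values 3D numeric array; NA marks undefined voxels.
#' @slot metricName "sigma_physio" or "cardiac_pulsatility".
#' @slot trSeconds repetition time of the originating series.
#' @export
setClass("VoxelMetricMap",
  representation(values = "array", metricName = "character",
                 trSeconds = "numeric"))

setValidity("VoxelMetricMap", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3D array")
  if (!object@metricName %in% c("sigma_physio", "cardiac_pulsatility"))
    msg <- c(msg, "metricName must be sigma_physio or cardiac_pulsatility")
  v <- object@values[!is.na(object@values)]
  if (length(v) && any(v < 0))
    msg <- c(msg, "defined metric values must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' NoiseDecomposition: thermal/physiological variance split
#'
#' Result of applying the square summation law
#' \eqn{\sigma^2_{EPI} = \sigma^2_{physio} + \sigma^2_{therm}} voxelwise:
#' the total temporal variance, the scalar thermal variance subtracted from
#' it, the resulting percent sigma_physio map, and the number of voxels
#' whose total variance fell below the thermal estimate (clamped to zero).
#'
#' @slot sigma2Epi 3D array of total temporal variances (NA outside mask).
#' @slot sigma2Therm scalar thermal variance.
#' @slot map the percent [VoxelMetricMap-class] of sigma_physio.
#' @slot clippedCount voxels where sigma2Epi < sigma2Therm.
#' @slot undefinedCount masked voxels with nonpositive temporal mean.
#' @export
setClass("NoiseDecomposition",
  representation(sigma2Epi = "array", sigma2Therm = "numeric",
                 map = "VoxelMetricMap", clippedCount = "integer",
                 undefinedCount = "integer"))

setValidity("NoiseDecomposition", function(object) {
  msg <- character()
  if (object@sigma2Therm < 0) msg <- c(msg, "sigma2Therm must be >= 0")
  if (object@clippedCount < 0L) msg <- c(msg, "clippedCount must be >= 0")
  if (length(msg)) msg else TRUE
})

#' CardiacFrequency: pulse-derived cardiac frequency and window
#'
#' The cardiac frequency (Hz) identified from the pulse-oximetry trace,
#' with the half-width of the spectral integration window around it.
#'
#' @slot fcHz cardiac frequency in Hz (> 0).
#' @slot halfWindowHz integration half-width in Hz (default 0.02).
#' @slot source "trace_mean" or "trace_median".
#' @export
setClass("CardiacFrequency",
  representation(fcHz = "numeric", halfWindowHz = "numeric",
                 source = "character"))

setValidity("CardiacFrequency", function(object) {
  msg <- character()
  if (object@fcHz <= 0) msg <- c(msg, "fcHz must be positive")
  if (object@halfWindowHz <= 0) msg <- c(msg, "halfWindowHz must be positive")
  if (!object@source %in% c("trace_mean", "trace_median"))
    msg <- c(msg, "source must be trace_mean or trace_median")
  if (length(msg)) msg else TRUE
})
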