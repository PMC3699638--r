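# Voxelwise metrics: total-variance decomposition into thermal and
# physiological parts (square summation law), one-sided amplitude spectra,
# and the cardiac pulsatility metric (windowed spectral integration at the
# pulse-derived cardiac frequency). All maps are percent of voxel mean.

#' Nyquist frequency of a sampling interval
#'
#' Half the sampling rate: fluctuations above it alias. At TR = 0.25 s
#' cardiac frequencies up to 2 Hz are sampled unaliased; at TR = 2 s the
#' sampling rate is 0.5 Hz and the cardiac band cannot be isolated.
#'
#' @param trSeconds sampling interval in seconds.
#' @return Nyquist frequency in Hz.
#' @export
nyquistHz <- function(trSeconds) {
  if (trSeconds <= 0) stop("trSeconds must be positive")
  1 / (2 * trSeconds)
}

# time-by-voxel matrix of the masked time courses
.voxelMatrix <- function(series, mask) {
  d <- dim(series@data)
  m <- matrix(series@data, nrow = prod(d[1:3]), ncol = d[4])
  t(m[as.vector(mask), , drop = FALSE])
}

# unbiased (n-1) temporal variance per column of a time-by-voxel matrix
.colVarsMat <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  (colSums(m * m) - n * mu * mu) / (n - 1)
}

#' Thermal variance from an out-of-brain ROI
#'
#' The mean over ROI voxels of each voxel's temporal variance (denominator
#' n - 1). This scalar is subtracted, in variance units, from every
#' voxel's total variance by [sigmaPhysioMap()].
#'
#' @param series a [BoldSeries-class].
#' @param roi a [ThermalRoi-class].
#' @return scalar thermal variance in squared signal units.
#' @export
thermalVariance <- function(series, roi) {
  if (!any(roi@mask)) stop("thermal ROI is empty")
  if (!identical(dim(roi@mask), dim(series@data)[1:3]))
    stop("ROI grid does not match series grid")
  mean(.colVarsMat(.voxelMatrix(series, roi@mask)))
}

#' Voxelwise physiological-noise map (square summation law)
#'
#' Decomposes each masked voxel's total temporal variance as
#' \eqn{\sigma^2_{EPI} = \sigma^2_{physio} + \sigma^2_{therm}}:
#' the physiological standard deviation is
#' \eqn{\sqrt{\max(\sigma^2_{EPI} - \sigma^2_{therm}, 0)}}, normalised to
#' the voxel's temporal mean and expressed as a percentage. Voxels whose
#' total variance falls below the thermal estimate (possible by sampling
#' error) are clamped to zero and counted; masked voxels with nonpositive
#' mean signal are marked undefined and counted. No detrending is applied:
#' variance is computed over the full retained time course, so slow drift
#' contributes to the physiological component.
#'
#' @param series a [BoldSeries-class] with at least 2 volumes.
#' @param sigma2Therm scalar thermal variance from [thermalVariance()].
#' @param mask logical 3D array of voxels to evaluate.
#' @return A [NoiseDecomposition-class].
#' @export
sigmaPhysioMap <- function(series, sigma2Therm, mask) {
  if (nVolumes(series) < 2L) stop("need at least 2 volumes")
  if (!any(mask)) stop("mask is empty")
  if (sigma2Therm < 0) stop("sigma2Therm must be >= 0")
  m <- .voxelMatrix(series, mask)
  v <- .colVarsMat(m)
  mu <- colMeans(m)
  sigmaPhysio <- sqrt(pmax(v - sigma2Therm, 0))
  pct <- 100 * sigmaPhysio / mu
  bad <- mu <= 0
  pct[bad] <- NA_real_
  if (all(bad)) stop("all masked voxels have nonpositive mean signal")

  dims <- dim(series@data)[1:3]
  vArr <- array(NA_real_, dims)
  vArr[mask] <- v
  pArr <- array(NA_real_, dims)
  pArr[mask] <- pct
  map <- new("VoxelMetricMap", values = pArr, metricName = "sigma_physio",
             trSeconds = series@trSeconds)
  new("NoiseDecomposition", sigma2Epi = vArr,
      sigma2Therm = as.numeric(sigma2Therm), map = map,
      clippedCount = sum(v < sigma2Therm & !bad),
      undefinedCount = sum(bad))
}

#' Cardiac frequency from a pulse-oximetry trace
#'
#' The cardiac frequency is the mean (or median) heart rate over the scan
#' window, converted to Hz. In cardiac-sampled ("cs") mode the full
#' integration window must lie below the Nyquist frequency:
#' `fc + halfWindowHz < 1/(2 tr)`; a violation is a hard error advising
#' the cardiac-aliased ("wb") mode, where the pulsatility metric is not
#' computed.
#'
#' @param trace a [PulseTrace-class].
#' @param scanWindow optional c(start, end) seconds; samples outside it
#'   are ignored (the whole trace is used, with a warning, if no sample
#'   falls inside).
#' @param trSeconds repetition time, required in cs mode for the Nyquist
#'   margin check.
#' @param mode "cs" (cardiac-sampled) or "wb" (conventional TR).
#' @param halfWindowHz spectral half-window around the cardiac frequency
#'   (default 0.02 Hz, matched to the width of the cardiac peak).
#' @param source "trace_mean" (default) or "trace_median" (robust to
#'   oximeter dropouts).
#' @return A [CardiacFrequency-class].
#' @export
cardiacFrequency <- function(trace, scanWindow = NULL, trSeconds = NULL,
                             mode = c("cs", "wb"), halfWindowHz = 0.02,
                             source = c("trace_mean", "trace_median")) {
  mode <- match.arg(mode)
  source <- match.arg(source)
  bpm <- trace@bpm
  if (!is.null(scanWindow)) {
    inWin <- trace@timesSeconds >= scanWindow[1] &
      trace@timesSeconds <= scanWindow[2]
    if (!any(inWin)) {
      warning("no pulse samples inside the scan window; using whole trace")
    } else bpm <- bpm[inWin]
  }
  fc <- if (source == "trace_mean") mean(bpm) / 60 else
    stats::median(bpm) / 60
  if (mode == "cs") {
    if (is.null(trSeconds))
      stop("trSeconds is required for the cs-mode Nyquist check")
    nyq <- nyquistHz(trSeconds)
    if (fc + halfWindowHz >= nyq)
      stop(sprintf(paste0("cardiac frequency %.3g Hz + window %.3g Hz reaches ",
                          "the Nyquist frequency %.3g Hz; the cardiac band is ",
                          "aliased at this TR - use wb mode (sigma_physio only)"),
                   fc, halfWindowHz, nyq))
  }
  new("CardiacFrequency", fcHz = fc, halfWindowHz = halfWindowHz,
      source = source)
}

#' One-sided amplitude spectrum of a time course
#'
#' Returns amplitudes on the frequency grid 0, 1/(n tr), ..., 1/(2 tr),
#' scaled so that a pure sinusoid of amplitude A centred on a bin reads A
#' at that bin: |DFT|/n at f = 0 (and at Nyquist for even n), 2|DFT|/n in
#' between. With this scaling Parseval's identity reads
#' \eqn{a_0^2 + \sum_{interior} a_k^2/2 + a_{Nyq}^2 = \mathrm{mean}(x^2)}.
#'
#' @param course numeric vector, length >= 4.
#' @param trSeconds sampling interval in seconds.
#' @return data.frame with columns `freq_hz` and `amplitude`.
#' @export
amplitudeSpectrum <- function(course, trSeconds) {
  n <- length(course)
  if (n < 4L) stop("need at least 4 samples")
  if (trSeconds <= 0) stop("trSeconds must be positive")
  X <- stats::fft(course)
  nHalf <- floor(n / 2)
  amp <- Mod(X[1:(nHalf + 1L)]) / n
  scale <- rep(2, nHalf + 1L)
  scale[1L] <- 1
  if (n %% 2L == 0L) scale[nHalf + 1L] <- 1
  data.frame(freq_hz = (0:nHalf) / (n * trSeconds),
             amplitude = amp * scale)
}

# frequency bins and one-sided amplitude matrix (bin-by-voxel) for a
# time-by-voxel matrix
.amplitudeMatrix <- function(m, trSeconds) {
  n <- nrow(m)
  X <- stats::mvfft(m)
  nHalf <- floor(n / 2)
  amp <- Mod(X[1:(nHalf + 1L), , drop = FALSE]) / n
  scale <- rep(2, nHalf + 1L)
  scale[1L] <- 1
  if (n %% 2L == 0L) scale[nHalf + 1L] <- 1
  list(freqs = (0:nHalf) / (n * trSeconds), amp = amp * scale)
}

#' Voxelwise cardiac pulsatility map
#'
#' For each masked voxel the one-sided amplitude spectrum is integrated
#' over the bins whose centre lies within `halfWindowHz` of the cardiac
#' frequency (closed interval), and divided by the nominal window width
#' 2 x `halfWindowHz` (0.04 Hz by default) to yield an average amplitude;
#' this is normalised to the voxel's temporal mean and expressed as a
#' percentage - the voxelwise percent signal change at the cardiac
#' frequency.
#'
#' @param series a [BoldSeries-class] (cardiac-sampled: the window must
#'   lie below Nyquist).
#' @param fc a [CardiacFrequency-class].
#' @param mask logical 3D array of voxels to evaluate.
#' @return A [VoxelMetricMap-class] (`metricName = "cardiac_pulsatility"`).
#' @export
cardiacPulsatilityMap <- function(series, fc, mask) {
  if (!any(mask)) stop("mask is empty")
  hw <- fc@halfWindowHz
  nyq <- nyquistHz(series@trSeconds)
  if (fc@fcHz + hw >= nyq)
    stop(sprintf(paste0("cardiac window [%.3g, %.3g] Hz reaches Nyquist ",
                        "(%.3g Hz): pulsatility is not computable at this TR ",
                        "(wb mode computes sigma_physio only)"),
                 fc@fcHz - hw, fc@fcHz + hw, nyq))
  m <- .voxelMatrix(series, mask)
  sp <- .amplitudeMatrix(m, series@trSeconds)
  df <- sp$freqs[2L] - sp$freqs[1L]
  inWin <- abs(sp$freqs - fc@fcHz) <= hw + 1e-12
  if (!any(inWin)) stop("no frequency bins inside the cardiac window")
  avgAmp <- colSums(sp$amp[inWin, , drop = FALSE]) * df / (2 * hw)
  mu <- colMeans(m)
  pct <- 100 * avgAmp / mu
  pct[mu <= 0] <- NA_real_

  dims <- dim(series@data)[1:3]
  arr <- array(NA_real_, dims)
  arr[mask] <- pct
  new("VoxelMetricMap", values = arr, metricName = "cardiac_pulsatility",
      trSeconds = series@trSeconds)
}

#' Per-tissue means of a voxel metric map
#'
#' Averages the defined map voxels within each tissue class. NAWM is
#' reported as WM minus WMH when a lesion mask is present (plain WM
#' otherwise); the lesion class itself is reported as WMH. Empty classes
#' are reported as missing (NA), never as zero.
#'
#' @param map a [VoxelMetricMap-class].
#' @param masks a [TissueMasks-class], typically after
#'   [erodeTissueMasks()].
#' @return data.frame with columns `class`, `mean_pct`, `n_voxels`.
#' @export
tissueSummary <- function(map, masks) {
  if (!identical(dim(map@values), spatialDim(masks)))
    stop(sprintf("map grid %s does not match mask grid %s",
                 paste(dim(map@values), collapse = "x"),
                 paste(spatialDim(masks), collapse = "x")))
  present <- maskClasses(masks)
  classes <- c(if ("GM" %in% present) "GM",
               if ("WM" %in% present) "NAWM",
               if ("WMH" %in% present) "WMH",
               if ("CSF" %in% present) "CSF")
  rows <- lapply(classes, function(cl) {
    sel <- getMask(masks, cl)
    vals <- map@values[sel]
    vals <- vals[!is.na(vals)]
    data.frame(class = cl,
               mean_pct = if (length(vals)) mean(vals) else NA_real_,
               n_voxels = length(vals))
  })
  do.call(rbind, rows)
}

#' Cumulative head motion
#'
#' Sum of per-volume root-mean-squared head displacement values (relative
#' to the previous volume), in mm, over the retained time course.
#'
#' @param displacementMm nonnegative per-volume displacements in mm.
#' @return scalar cumulative displacement in mm.
#' @export
cumulativeMotion <- function(displacementMm) {
  if (length(displacementMm) == 0L) stop("displacement sequence is empty")
  if (any(!is.finite(displacementMm)) || any(displacementMm < 0))
    stop("displacements must be finite and nonnegative")
  sum(displacementMm)
}
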