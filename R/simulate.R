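# Synthetic BOLD phantom generator: tissue-dependent cardiac pulsatility,
# broadband (low-pass) physiological noise, respiration, linear drift and
# additive thermal noise on a concentric-ring geometry with an optional
# contiguous white-matter lesion. The same continuous-time signal model is
# rendered at the cardiac-sampled TR (0.25 s, unaliased) or a conventional
# TR (2 s, cardiac-aliased) so that sampling-rate properties of the
# metrics can be tested against generator truth.

#' Voxel signal model
#'
#' Parameters of one voxel's (or one tissue class's) BOLD time course:
#' \deqn{S(t) = S_0 [1 + c(t) + r(t) + b(t) + d(t)] + \epsilon(t)}
#' with cardiac sinusoid (plus optional 2f and 3f harmonics) `c`,
#' respiratory sinusoid `r`, broadband physiological noise `b` (white
#' Gaussian noise low-pass filtered at `broadbandCutoffHz` and rescaled to
#' an exact sample SD), linear drift `d` and white thermal noise
#' \eqn{\epsilon}. All fractional amplitudes are percent of the baseline
#' \eqn{S_0}.
#'
#' @param baseline mean signal S0 (> 0).
#' @param cardiacAmpPct cardiac sinusoid amplitude, % of S0.
#' @param cardiacHarmonics length-2 amplitude fractions (relative to the
#'   fundamental) for the 2f and 3f harmonics. Default c(0, 0): at the
#'   cardiac-sampled TR the harmonics of a resting heart rate lie at or
#'   above the Nyquist frequency and would alias back into the sampled
#'   band, so they are off unless requested.
#' @param respAmpPct respiratory sinusoid amplitude, % of S0.
#' @param respFreqHz respiratory frequency (default 0.3 Hz).
#' @param physioBroadbandPct sample SD of the broadband physiological
#'   process, % of S0.
#' @param broadbandCutoffHz low-pass cutoff of the broadband process
#'   (default 0.15 Hz, below the cardiac window).
#' @param driftPctPerMin linear drift slope, % of S0 per minute.
#' @param thermalSd additive white Gaussian SD in signal units.
#' @return a `VoxelSignalModel` (named list).
#' @export
voxelSignalModel <- function(baseline = 100, cardiacAmpPct = 0,
                             cardiacHarmonics = c(0, 0), respAmpPct = 0,
                             respFreqHz = 0.3, physioBroadbandPct = 0,
                             broadbandCutoffHz = 0.15,
                             driftPctPerMin = 0, thermalSd = 0) {
  stopifnot(baseline > 0, cardiacAmpPct >= 0, respAmpPct >= 0,
            physioBroadbandPct >= 0, thermalSd >= 0,
            length(cardiacHarmonics) == 2L, all(cardiacHarmonics >= 0))
  structure(list(baseline = baseline, cardiacAmpPct = cardiacAmpPct,
                 cardiacHarmonics = cardiacHarmonics,
                 respAmpPct = respAmpPct, respFreqHz = respFreqHz,
                 physioBroadbandPct = physioBroadbandPct,
                 broadbandCutoffHz = broadbandCutoffHz,
                 driftPctPerMin = driftPctPerMin, thermalSd = thermalSd),
            class = "VoxelSignalModel")
}

# low-pass filter the columns of a matrix of white noise via FFT,
# zeroing the DC bin and all bins above cutoffHz, then rescale each
# column to unit sample SD
.lowpassUnitSd <- function(w, dtSeconds, cutoffHz) {
  n <- nrow(w)
  f <- c(0:(floor(n / 2)), -((n - floor(n / 2) - 1L):1)) / (n * dtSeconds)
  keep <- abs(f) <= cutoffHz & abs(f) > 0
  if (!any(keep)) stop("broadband cutoff leaves no frequency bins")
  X <- stats::mvfft(w)
  X[!keep, ] <- 0
  y <- Re(stats::mvfft(X, inverse = TRUE)) / n
  sds <- apply(y, 2L, stats::sd)
  sds[sds == 0] <- 1
  sweep(y, 2L, sds, "/")
}

# deterministic fractional components (cardiac + respiratory + drift) of a
# model evaluated at times t (seconds), as a fraction of baseline
.deterministicFraction <- function(model, fcHz, t, phases) {
  h <- model$cardiacHarmonics
  A <- model$cardiacAmpPct / 100
  card <- A * sin(2 * pi * fcHz * t + phases$cardiac)
  if (h[1] > 0) card <- card + A * h[1] * sin(2 * pi * 2 * fcHz * t + phases$cardiac2)
  if (h[2] > 0) card <- card + A * h[2] * sin(2 * pi * 3 * fcHz * t + phases$cardiac3)
  resp <- (model$respAmpPct / 100) *
    sin(2 * pi * model$respFreqHz * t + phases$resp)
  drift <- (model$driftPctPerMin / 100) * (t - mean(t)) / 60
  card + resp + drift
}

.checkCsFrequencies <- function(model, fcHz, trSeconds) {
  nyq <- nyquistHz(trSeconds)
  if (model$cardiacAmpPct > 0 && fcHz >= nyq)
    stop(sprintf("cardiac frequency %.3g Hz is at/above Nyquist %.3g Hz in cs mode",
                 fcHz, nyq))
  if (model$respAmpPct > 0 && model$respFreqHz >= nyq)
    stop("respiratory frequency at/above Nyquist in cs mode")
  h <- model$cardiacHarmonics
  if ((h[1] > 0 && 2 * fcHz >= nyq) || (h[2] > 0 && 3 * fcHz >= nyq))
    stop("active cardiac harmonic at/above Nyquist in cs mode")
  invisible(TRUE)
}

#' Simulate one voxel time course
#'
#' Renders the signal model at `n` samples of spacing `trSeconds`. In
#' "cs" mode any active oscillatory component at or above the Nyquist
#' frequency is a hard error; in "wb" mode the cardiac component is
#' rendered from the same continuous-time model and aliases naturally.
#' Deterministic for a fixed RNG seed.
#'
#' @param model a [voxelSignalModel()].
#' @param fcHz cardiac frequency in Hz.
#' @param n number of samples (>= 16).
#' @param trSeconds sampling interval.
#' @param mode "cs" or "wb".
#' @param seed optional integer seed (set just before the random draws).
#' @return numeric time course of length `n`.
#' @export
simulateVoxel <- function(model, fcHz, n, trSeconds, mode = c("cs", "wb"),
                          seed = NULL) {
  mode <- match.arg(mode)
  if (n < 16L) stop("need n >= 16")
  if (mode == "cs") .checkCsFrequencies(model, fcHz, trSeconds)
  if (!is.null(seed)) set.seed(seed)
  t <- (0:(n - 1L)) * trSeconds
  phases <- list(cardiac = stats::runif(1, 0, 2 * pi),
                 cardiac2 = stats::runif(1, 0, 2 * pi),
                 cardiac3 = stats::runif(1, 0, 2 * pi),
                 resp = stats::runif(1, 0, 2 * pi))
  frac <- .deterministicFraction(model, fcHz, t, phases)
  if (model$physioBroadbandPct > 0) {
    bb <- .lowpassUnitSd(matrix(stats::rnorm(n), ncol = 1), trSeconds,
                         model$broadbandCutoffHz)[, 1]
    frac <- frac + (model$physioBroadbandPct / 100) * bb
  }
  model$baseline * (1 + frac) + stats::rnorm(n, 0, model$thermalSd)
}

#' Analytic generator truth for the sigma_physio metric
#'
#' The injected physiological SD, percent of baseline, implied by a signal
#' model over a given sampling grid: sinusoid variances A^2/2, the exact
#' broadband sample SD, and the drift contribution computed from the
#' sample variance of the time grid. This is what an ideal pipeline should
#' recover as sigma_physio after thermal subtraction.
#'
#' @param model a [voxelSignalModel()].
#' @param n number of retained samples.
#' @param trSeconds sampling interval.
#' @return injected sigma_physio in percent of baseline.
#' @export
sigmaPhysioTruth <- function(model, n, trSeconds) {
  h <- model$cardiacHarmonics
  t <- (0:(n - 1L)) * trSeconds
  cardVar <- model$cardiacAmpPct^2 * (1 + h[1]^2 + h[2]^2) / 2
  respVar <- model$respAmpPct^2 / 2
  driftVar <- (model$driftPctPerMin / 60)^2 * stats::var(t)
  sqrt(cardVar + respVar + model$physioBroadbandPct^2 + driftVar)
}

# Rice-distribution mean: E|Z| for Z complex Gaussian with mean magnitude
# nu and per-component SD s (used for the analytic pulsatility truth under
# thermal noise). Asymptotic form for large nu/s, Laguerre form otherwise.
.riceMean <- function(nu, s) {
  if (s == 0) return(nu)
  snr <- nu / s
  if (snr > 8) return(nu + s^2 / (2 * nu))
  x <- -nu^2 / (2 * s^2)
  # L_{1/2}(x) via confluent hypergeometric identities
  l12 <- exp(x / 2) * ((1 - x) * besselI(-x / 2, 0) - x * besselI(-x / 2, 1))
  s * sqrt(pi / 2) * l12
}

#' Analytic generator truth for the cardiac pulsatility metric
#'
#' Expected pipeline reading for a sinusoid of amplitude `ampPct` percent
#' of baseline whose frequency sits exactly on a DFT bin, under additive
#' white thermal noise of SD `thermalSd` (signal units): the signal bin
#' contributes a Rice mean, each remaining window bin a Rayleigh mean, and
#' the windowed amplitude integral is divided by the nominal width
#' 2 x `halfWindowHz`. With `thermalSd = 0` this reduces to
#' `ampPct * df / (2 halfWindowHz)` where `df = 1/(n tr)`.
#'
#' @param ampPct cardiac amplitude, % of baseline.
#' @param n retained samples.
#' @param trSeconds sampling interval.
#' @param halfWindowHz window half-width (default 0.02).
#' @param thermalSd white-noise SD in signal units (default 0).
#' @param baseline voxel mean signal (default 100).
#' @return expected pulsatility metric in percent of voxel mean.
#' @export
pulsatilityTruth <- function(ampPct, n, trSeconds, halfWindowHz = 0.02,
                             thermalSd = 0, baseline = 100) {
  df <- 1 / (n * trSeconds)
  nBins <- 2L * floor(halfWindowHz / df + 1e-9) + 1L
  A <- baseline * ampPct / 100
  sigBin <- if (thermalSd > 0)
    (2 / n) * .riceMean(n * A / 2, thermalSd * sqrt(n / 2)) else A
  noiseBin <- if (thermalSd > 0) thermalSd * sqrt(pi / n) else 0
  avgAmp <- (sigBin + (nBins - 1L) * noiseBin) * df / (2 * halfWindowHz)
  100 * avgAmp / baseline
}

# ---------------------------------------------------------------------------
# phantom geometry

#' Concentric-ring phantom tissue masks
#'
#' CSF core, white-matter annulus and grey-matter outer ring centred in
#' the slice plane, replicated across slices, with the image corners left
#' as background for the thermal ROI. An optional contiguous WMH lesion is
#' grown inside the WM annulus to a target fraction of WM voxels (uses the
#' current RNG state to place the lesion seed).
#'
#' @param dims integer length-3 grid dimensions.
#' @param lesionFraction fraction of WM voxels converted to a contiguous
#'   WMH blob, in \[0, 1); 0 omits the WMH mask.
#' @param radiusScale multiplicative jitter on the ring radii, emulating
#'   between-subject anatomical size variation (so WM volume is a
#'   genuinely varying covariate).
#' @return A [TissueMasks-class].
#' @export
phantomMasks <- function(dims, lesionFraction = 0, radiusScale = 1) {
  if (lesionFraction < 0 || lesionFraction >= 1)
    stop("lesionFraction must be in [0, 1)")
  if (radiusScale <= 0 || radiusScale > 1.15)
    stop("radiusScale must be in (0, 1.15] to keep corners clear")
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  r2d <- sqrt(outer((1:nx - cx)^2, (1:ny - cy)^2, "+"))
  base <- min(nx, ny) * radiusScale
  rCsf <- 0.08 * base; rWm <- 0.26 * base; rGm <- 0.36 * base
  csf <- array(rep(r2d <= rCsf, nz), dims)
  wm <- array(rep(r2d > rCsf & r2d <= rWm, nz), dims)
  gm <- array(rep(r2d > rWm & r2d <= rGm, nz), dims)
  masks <- list(GM = gm, WM = wm, CSF = csf)
  if (lesionFraction > 0) {
    target <- max(1L, round(lesionFraction * sum(wm)))
    if (target >= sum(wm)) stop("lesion larger than the WM mask")
    masks$WMH <- .growLesion(wm, target)
  }
  TissueMasks(masks)
}

# grow a contiguous blob of `target` voxels inside `wm` by breadth-first
# expansion from a randomly chosen WM seed voxel (6-connectivity)
.growLesion <- function(wm, target) {
  dims <- dim(wm)
  idx <- which(wm)
  seedIdx <- idx[sample.int(length(idx), 1L)]
  lesion <- array(FALSE, dims)
  queue <- seedIdx
  lesion[seedIdx] <- TRUE
  count <- 1L
  offsets <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))
  while (count < target && length(queue)) {
    cur <- queue[1L]
    queue <- queue[-1L]
    co <- arrayInd(cur, dims)
    for (k in 1:6) {
      nb <- co + offsets[k, ]
      if (any(nb < 1L) || any(nb > dims)) next
      lin <- nb[1] + (nb[2] - 1L) * dims[1] + (nb[3] - 1L) * dims[1] * dims[2]
      if (wm[lin] && !lesion[lin]) {
        lesion[lin] <- TRUE
        queue <- c(queue, lin)
        count <- count + 1L
        if (count >= target) break
      }
    }
  }
  lesion
}

# ---------------------------------------------------------------------------
# cohort design

.defaultTissueSignal <- function() {
  # percent-of-baseline amplitudes per tissue; WM is graded across groups
  # (cardiac pulsatility and broadband noise increase YC -> EC -> SVD,
  # lesions fall below NAWM), encoding the direction of effects the
  # analysis is meant to detect. Values chosen so injected WM sigma_physio
  # sits near 0.6 / 1.0 / 1.15 % for the three cohorts.
  list(
    GM = list(baseline = 100, cardiac = c(YC = 1.75, EC = 1.75, SVD = 1.75),
              resp = 0.8, broadband = c(YC = 0.48, EC = 0.48, SVD = 0.48)),
    WM = list(baseline = 90, cardiac = c(YC = 0.50, EC = 0.875, SVD = 1.25),
              resp = 0.3, broadband = c(YC = 0.43, EC = 0.72, SVD = 0.63)),
    WMH = list(baseline = 85, cardiac = c(YC = 0.625, EC = 0.625, SVD = 0.625),
               resp = 0.3, broadband = c(YC = 0.73, EC = 0.73, SVD = 0.73)),
    CSF = list(baseline = 120, cardiac = c(YC = 3, EC = 3, SVD = 3),
               resp = 1.0, broadband = c(YC = 1.0, EC = 1.0, SVD = 1.0))
  )
}

#' Cohort design for the phantom generator
#'
#' Defaults emulate the study conditions: three cohorts of 11 young
#' controls (YC), 10 elderly controls (EC) and 7 small-vessel-disease
#' (SVD) subjects with the published age and sex structure; a
#' cardiac-sampled acquisition of 64 x 64 x 4 voxels (3 x 3 x 5 mm) and
#' 510 volumes at TR 0.25 s; a conventional acquisition of 128 volumes at
#' TR 2 s; heart rates drawn from N(60, 5) bpm and held constant within a
#' subject; a contiguous lesion occupying 25 percent of WM in SVD
#' subjects. WM signal parameters are graded YC < EC < SVD and lesions
#' fall below NAWM, the direction of effects under test.
#'
#' @param nSubjects named vector of per-group subject counts.
#' @param csDims,csVolumes,csTrSeconds,csVoxelDims cardiac-sampled
#'   acquisition geometry (volumes include the `csDiscard` non-steady-state
#'   volumes discarded during analysis).
#' @param wbDims,wbVolumes,wbTrSeconds,wbVoxelDims conventional-TR
#'   acquisition geometry (no volumes discarded).
#' @param csDiscard leading cs volumes the analysis will discard.
#' @param tissueSignal nested list of per-tissue signal parameters (see
#'   the package source for the default).
#' @param subjectCv coefficient of variation of a per-subject global
#'   physiology scale shared by all tissue amplitudes of that subject
#'   (it induces the within-subject correlation between tissue classes
#'   that paired contrasts rely on).
#' @param tissueCv coefficient of variation of the additional
#'   tissue-specific amplitude jitter within a subject.
#' @param hrMeanBpm,hrSdBpm between-subject heart-rate distribution.
#' @param traceJitterBpm SD of the sample-to-sample oximeter reading
#'   noise around the subject's heart rate.
#' @param thermalSd white thermal noise SD (signal units).
#' @param driftPctPerMin linear drift slope, % of baseline per minute.
#' @param lesionFraction fraction of WM turned into WMH in SVD subjects.
#' @param ageMean,ageSd,pMale named per-group demographics (pMale is the
#'   probability of drawing a male subject, defaulting to the published
#'   6/11, 3/10, 4/7 ratios).
#' @param dispMeanMm named per-group mean per-volume head displacement.
#' @param wmPveMean named per-group mean WM partial-volume estimate.
#' @param seed integer seed making the cohort fully reproducible.
#' @return a `CohortDesign` (named list).
#' @export
cohortDesign <- function(nSubjects = c(YC = 11, EC = 10, SVD = 7),
                         csDims = c(64, 64, 4), csVolumes = 510,
                         csTrSeconds = 0.25, csVoxelDims = c(3, 3, 5),
                         wbDims = c(32, 32, 4), wbVolumes = 128,
                         wbTrSeconds = 2, wbVoxelDims = c(4, 4, 5.5),
                         csDiscard = 10,
                         tissueSignal = .defaultTissueSignal(),
                         subjectCv = 0.20, tissueCv = 0.08,
                         hrMeanBpm = 60, hrSdBpm = 5,
                         traceJitterBpm = 0.3,
                         thermalSd = 1, driftPctPerMin = 0.2,
                         lesionFraction = 0.25,
                         ageMean = c(YC = 25.4, EC = 65.8, SVD = 70),
                         ageSd = c(YC = 3.2, EC = 3.1, SVD = 8.6),
                         pMale = c(YC = 6 / 11, EC = 3 / 10, SVD = 4 / 7),
                         dispMeanMm = c(YC = 0.040, EC = 0.046, SVD = 0.058),
                         wmPveMean = c(YC = 0.85, EC = 0.80, SVD = 0.75),
                         seed = 1L) {
  stopifnot(all(nSubjects >= 1), lesionFraction >= 0, lesionFraction < 1)
  structure(list(nSubjects = nSubjects, csDims = csDims,
                 csVolumes = csVolumes, csTrSeconds = csTrSeconds,
                 csVoxelDims = csVoxelDims, wbDims = wbDims,
                 wbVolumes = wbVolumes, wbTrSeconds = wbTrSeconds,
                 wbVoxelDims = wbVoxelDims, csDiscard = csDiscard,
                 tissueSignal = tissueSignal,
                 subjectCv = subjectCv, tissueCv = tissueCv,
                 hrMeanBpm = hrMeanBpm, hrSdBpm = hrSdBpm,
                 traceJitterBpm = traceJitterBpm,
                 thermalSd = thermalSd, driftPctPerMin = driftPctPerMin,
                 lesionFraction = lesionFraction, ageMean = ageMean,
                 ageSd = ageSd, pMale = pMale, dispMeanMm = dispMeanMm,
                 wmPveMean = wmPveMean, seed = as.integer(seed)),
            class = "CohortDesign")
}

# tissue amplitude for one subject: group mean x global subject scale x
# tissue-specific jitter, floored at 5 % of the mean so amplitudes stay
# positive
.drawAmp <- function(mean, subjScale, tissueCv) {
  if (mean == 0) return(0)
  max(0.05 * mean, mean * subjScale * stats::rnorm(1, 1, tissueCv))
}

#' Simulate one phantom subject
#'
#' Renders a full subject: BOLD series, tissue masks (with a WMH lesion
#' for SVD subjects when `lesionFraction > 0`), a pulse trace consistent
#' with the injected cardiac frequency, a covariate record, and the
#' analytic per-tissue ground truth. In "wb" mode the same continuous-time
#' model is sampled at the conventional TR, so the cardiac component is
#' aliased rather than absent. Uses the current RNG state; seed upstream
#' for reproducibility.
#'
#' The cardiac and respiratory phases, drift and heart rate are shared
#' across voxels of a subject; the broadband process and thermal noise are
#' drawn independently per voxel (broadband rescaled to its exact target
#' SD per voxel).
#'
#' @param design a [cohortDesign()].
#' @param group "YC", "EC" or "SVD".
#' @param subjectId subject identifier string.
#' @param mode "cs" or "wb".
#' @param ghostCorner optional corner name ("x0y0", ...) receiving a
#'   ghosting-like artifact (elevated baseline and pulsation) for testing
#'   corner selection.
#' @return list with elements `bold`, `masks`, `trace`, `record` (one-row
#'   data.frame) and `truth` (per-tissue data.frame of injected values).
#' @export
simulateSubject <- function(design, group, subjectId,
                            mode = c("cs", "wb"), ghostCorner = NULL) {
  mode <- match.arg(mode)
  cs <- mode == "cs"
  dims <- if (cs) design$csDims else design$wbDims
  nVol <- if (cs) design$csVolumes else design$wbVolumes
  tr <- if (cs) design$csTrSeconds else design$wbTrSeconds
  voxDims <- if (cs) design$csVoxelDims else design$wbVoxelDims
  nRetained <- if (cs) nVol - design$csDiscard else nVol

  hr <- min(100, max(45, stats::rnorm(1, design$hrMeanBpm, design$hrSdBpm)))
  fc <- hr / 60
  lesion <- if (group == "SVD") design$lesionFraction else 0
  radiusScale <- min(1.1, max(0.9, stats::rnorm(1, 1, 0.04)))
  masks <- phantomMasks(dims, lesion, radiusScale)

  # continuous-time model rendered on a fine grid (<= 0.25 s) and
  # subsampled, so slower TRs alias rather than re-draw the physiology
  dtFine <- min(tr, 0.25)
  step <- round(tr / dtFine)
  nFine <- nVol * step
  tFine <- (0:(nFine - 1L)) * dtFine
  keepIdx <- seq(1L, nFine, by = step)
  t <- tFine[keepIdx]

  phases <- list(cardiac = stats::runif(1, 0, 2 * pi),
                 cardiac2 = stats::runif(1, 0, 2 * pi),
                 cardiac3 = stats::runif(1, 0, 2 * pi),
                 resp = stats::runif(1, 0, 2 * pi))

  # subject-level signal parameters are drawn before any bulky noise
  # arrays, so two renderings of the same seed at different TRs share the
  # same continuous-time model
  subjScale <- max(0.4, stats::rnorm(1, 1, design$subjectCv))
  analysisClasses <- intersect(c("GM", "WM", "WMH", "CSF"),
                               maskClasses(masks))
  wmhMask <- if ("WMH" %in% analysisClasses) getMask(masks, "WMH") else NULL
  models <- list()
  for (cl in analysisClasses) {
    pars <- design$tissueSignal[[cl]]
    amp <- .drawAmp(pars$cardiac[[group]], subjScale, design$tissueCv)
    bb <- .drawAmp(pars$broadband[[group]], subjScale, design$tissueCv)
    models[[cl]] <- voxelSignalModel(baseline = pars$baseline,
                                     cardiacAmpPct = amp,
                                     respAmpPct = pars$resp,
                                     physioBroadbandPct = bb,
                                     driftPctPerMin = design$driftPctPerMin,
                                     thermalSd = design$thermalSd)
  }

  nVox <- prod(dims)
  flat <- matrix(stats::rnorm(nVox * nVol, 0, design$thermalSd),
                 nrow = nVol, ncol = nVox)

  truthRows <- list()
  for (cl in analysisClasses) {
    model <- models[[cl]]
    amp <- model$cardiacAmpPct
    bb <- model$physioBroadbandPct
    if (cs) .checkCsFrequencies(model, fc, tr)
    sel <- getMask(masks, cl)
    if (cl == "WM" && !is.null(wmhMask)) sel <- sel & !wmhMask
    vox <- which(sel)
    if (!length(vox)) next
    det <- .deterministicFraction(model, fc, t, phases)
    bbMat <- .lowpassUnitSd(matrix(stats::rnorm(nFine * length(vox)),
                                   nrow = nFine), dtFine,
                            model$broadbandCutoffHz)[keepIdx, , drop = FALSE]
    sds <- apply(bbMat, 2L, stats::sd)
    sds[sds == 0] <- 1
    bbMat <- sweep(bbMat, 2L, sds, "/") * (bb / 100)
    flat[, vox] <- flat[, vox] +
      model$baseline * (1 + det + bbMat)
    truthRows[[cl]] <- data.frame(
      subject_id = subjectId, group = group,
      class = if (cl == "WM") "NAWM" else cl,
      cardiac_amp_pct = amp, broadband_pct = bb, hr_bpm = hr,
      sigma_physio_truth_pct = sigmaPhysioTruth(model, nRetained, tr),
      pulsatility_truth_pct = if (cs)
        pulsatilityTruth(amp, nRetained, tr, thermalSd = 0,
                         baseline = 100) else NA_real_,
      stringsAsFactors = FALSE)
  }

  if (!is.null(ghostCorner)) {
    gm <- .cornerMask(dims, ghostCorner, max(4L, round(dims[1] / 8)))
    ghost <- 20 * (1 + 0.05 * sin(2 * pi * fc * t + phases$cardiac))
    flat[, which(gm)] <- flat[, which(gm)] + ghost
  }

  data <- array(t(flat), c(dims, nVol))
  bold <- BoldSeries(data, trSeconds = tr, voxelDimsMm = voxDims)

  traceTimes <- seq(0, nVol * tr, by = max(1, tr))
  trace <- PulseTrace(traceTimes,
                      pmin(200, pmax(30, hr + stats::rnorm(length(traceTimes), 0,
                                                           design$traceJitterBpm))))

  # per-subject mean displacement varies widely between subjects (the
  # cohort-level motion comparison should generally be non-significant)
  subjDisp <- max(0.005, stats::rnorm(1, design$dispMeanMm[[group]], 0.017))
  disp <- abs(stats::rnorm(nRetained, subjDisp, 0.005))
  # WM volume as a continuous covariate, as a high-resolution anatomical
  # segmentation would supply it (the coarse BOLD-grid voxel count is
  # quantised and can degenerate on small grids)
  base <- min(dims[1:2]) * radiusScale
  wmVolMm3 <- pi * ((0.26 * base)^2 - (0.08 * base)^2) * dims[3] *
    prod(voxDims)
  record <- data.frame(
    subject_id = subjectId, group = group,
    age_years = max(18, stats::rnorm(1, design$ageMean[[group]],
                                     design$ageSd[[group]])),
    sex = sample(c("M", "F"), 1L,
                 prob = c(design$pMale[[group]], 1 - design$pMale[[group]])),
    hr_bpm = hr,
    wm_volume_mm3 = wmVolMm3,
    wm_volume_voxels = sum(getMask(masks, "WM")),
    wmh_volume_voxels = if (!is.null(wmhMask)) sum(wmhMask) else 0L,
    wm_pve = min(1, max(0, stats::rnorm(1, design$wmPveMean[[group]], 0.03))),
    cumulative_motion_mm = cumulativeMotion(disp),
    stringsAsFactors = FALSE)

  list(bold = bold, masks = masks, trace = trace, record = record,
       displacement_mm = disp, truth = do.call(rbind, truthRows))
}

#' Simulate a phantom cohort
#'
#' Draws every subject of the design (deterministically from the design
#' seed) and returns the subjects together with the table of injected
#' ground-truth parameters for recovery tests. With `outDir` set, each
#' subject's series, masks and pulse trace are also written to
#' `outDir/<subject_id>/` as NIfTI/CSV, plus cohort-level covariate and
#' truth tables.
#'
#' @param design a [cohortDesign()].
#' @param mode "cs" or "wb".
#' @param outDir optional output directory.
#' @return list with `subjects` (list of [simulateSubject()] results),
#'   `records` (covariate data.frame) and `truth` (injected-parameter
#'   data.frame).
#' @export
simulateCohort <- function(design, mode = c("cs", "wb"), outDir = NULL) {
  mode <- match.arg(mode)
  set.seed(design$seed)
  subjects <- list()
  for (g in names(design$nSubjects)) {
    for (i in seq_len(design$nSubjects[[g]])) {
      sid <- sprintf("%s%02d", g, i)
      subjects[[sid]] <- simulateSubject(design, g, sid, mode)
    }
  }
  records <- do.call(rbind, lapply(subjects, `[[`, "record"))
  truth <- do.call(rbind, lapply(subjects, `[[`, "truth"))
  rownames(records) <- rownames(truth) <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    for (sid in names(subjects)) {
      sdir <- file.path(outDir, sid)
      dir.create(sdir, showWarnings = FALSE)
      s <- subjects[[sid]]
      writeBold(s$bold, file.path(sdir, "bold.nii.gz"))
      writeMasks(s$masks, sdir, voxelDimsMm = voxelDims(s$bold))
      writePulseTrace(s$trace, file.path(sdir, "pulse.csv"))
    }
    utils::write.table(records, file.path(outDir, "covariates.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(truth, file.path(outDir, "truth.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(subjects = subjects, records = records, truth = truth)
}
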