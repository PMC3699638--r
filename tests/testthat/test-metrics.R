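# Spectral machinery, the variance decomposition and the pulsatility
# metric, checked against closed forms and a brute-force DFT oracle.

test_that("thermal variance recovers the generator variance and ignores the mean", {
  dims <- c(8, 8, 3)
  roiMask <- array(TRUE, dims)
  roi <- new("ThermalRoi", corner = "x0y0", extentVoxels = 8L,
             mask = roiMask)
  zero <- BoldSeries(array(0, c(dims, 20)), 0.25)
  expect_equal(thermalVariance(zero, roi), 0)

  set.seed(10)
  noise <- array(rnorm(prod(dims) * 500, 0, 5), c(dims, 500))
  s <- BoldSeries(noise, 0.25)
  v <- thermalVariance(s, roi)
  expect_equal(v, 25, tolerance = 0.10)

  # adding a per-voxel constant level leaves the variance untouched
  lifted <- sweep(noise, 1:3, array(runif(prod(dims), 50, 150), dims), "+")
  expect_equal(thermalVariance(BoldSeries(lifted, 0.25), roi), v,
               tolerance = 1e-10)
})

test_that("sigma_physio follows the square summation law closed form", {
  dims <- c(4, 4, 1)
  n <- 100
  mask <- array(TRUE, dims)
  # every voxel: exact temporal mean 100 and exact variance 25
  s <- seriesFromCourses(dims, n, 0.25,
                         function(i) exactMoments(n, 100, 5, seed = i))
  dec <- sigmaPhysioMap(s, sigma2Therm = 9, mask)
  vals <- metricValues(metricMap(dec))
  # sqrt(25 - 9) / 100 * 100 = 4 %
  expect_equal(unname(vals[mask]), rep(4, 16), tolerance = 1e-10)
  expect_equal(clippedCount(dec), 0L)

  # square-summation identity before clamping:
  # sigma2_physio + sigma2_therm = sigma2_EPI
  sigmaPhysio <- vals[mask] / 100 * 100  # percent of mean 100 -> signal units
  expect_equal(sigmaPhysio^2 + 9, dec@sigma2Epi[mask], tolerance = 1e-9)
})

test_that("sigma_physio clamps negative decompositions and counts them", {
  dims <- c(2, 2, 1)
  mask <- array(TRUE, dims)
  s <- seriesFromCourses(dims, 50, 0.25,
                         function(i) exactMoments(50, 100, 1, seed = i))
  dec <- sigmaPhysioMap(s, sigma2Therm = 4, mask)  # thermal exceeds total
  expect_true(all(metricValues(metricMap(dec))[mask] == 0))
  expect_equal(clippedCount(dec), 4L)

  const <- seriesFromCourses(dims, 50, 0.25, function(i) rep(100, 50))
  dec0 <- sigmaPhysioMap(const, 0, mask)
  expect_true(all(metricValues(metricMap(dec0))[mask] == 0))
})

test_that("cardiac frequency converts bpm and enforces the Nyquist margin", {
  expect_equal(fcHz(cardiacFrequency(PulseTrace(0:2, rep(60, 3)),
                                     trSeconds = 0.25)), 1.0)
  expect_equal(fcHz(cardiacFrequency(PulseTrace(0:1, c(55, 65)),
                                     trSeconds = 0.25)), 1.0)
  # 150 bpm -> 2.5 Hz: above the 2 Hz Nyquist of TR 0.25
  expect_error(cardiacFrequency(PulseTrace(0:2, rep(150, 3)),
                                trSeconds = 0.25, mode = "cs"),
               "Nyquist")
  # any resting heart rate is aliased at TR 2 s (Nyquist 0.25 Hz)
  expect_error(cardiacFrequency(PulseTrace(0:2, rep(60, 3)),
                                trSeconds = 2, mode = "cs"),
               "wb mode")
  # wb mode performs no margin check
  expect_s4_class(cardiacFrequency(PulseTrace(0:2, rep(60, 3)), mode = "wb"),
                  "CardiacFrequency")
  # median source resists dropout-like outliers within the band
  tr <- PulseTrace(0:4, c(60, 60, 60, 31, 60))
  expect_equal(fcHz(cardiacFrequency(tr, trSeconds = 0.25,
                                     source = "trace_median")), 1.0)
  expect_warning(cardiacFrequency(PulseTrace(0:2, rep(60, 3)),
                                  scanWindow = c(100, 200),
                                  trSeconds = 0.25), "whole trace")
})

test_that("amplitude spectrum matches the analytic single-bin sinusoid", {
  n <- 500; tr <- 0.25
  t <- (0:(n - 1)) * tr
  x <- 100 + 2 * sin(2 * pi * 1.0 * t)
  sp <- amplitudeSpectrum(x, tr)
  expect_equal(sp$freq_hz[2] - sp$freq_hz[1], 0.008, tolerance = 1e-12)
  i <- which.min(abs(sp$freq_hz - 1.0))
  expect_equal(sp$freq_hz[i], 1.0, tolerance = 1e-9)   # 1.0 Hz is bin 125
  expect_equal(sp$amplitude[i], 2, tolerance = 1e-9)
  expect_equal(sp$amplitude[1], 100, tolerance = 1e-9) # DC carries the mean
  expect_lt(max(sp$amplitude[-c(1, i)]), 1e-9)

  const <- amplitudeSpectrum(rep(7, 64), 0.25)
  expect_lt(max(const$amplitude[-1]), 1e-12)
})

test_that("fast transform matches the brute-force DFT and Parseval holds", {
  set.seed(11)
  for (n in c(16, 33, 64)) {
    x <- rnorm(n, 50, 4)
    sp <- amplitudeSpectrum(x, 0.5)
    oracle <- bruteAmplitudes(x)
    expect_lt(max(abs(sp$amplitude - oracle) / pmax(abs(oracle), 1e-8)),
              1e-10)
    # Parseval with the one-sided scaling unwound:
    # a0^2 + sum interior a^2/2 (+ aNyq^2) = mean(x^2)
    a <- sp$amplitude
    last <- length(a)
    power <- a[1]^2 + sum(a[2:(last - 1)]^2) / 2 +
      if (n %% 2 == 0) a[last]^2 else a[last]^2 / 2
    expect_equal(power, mean(x^2), tolerance = 1e-8)
  }
})

test_that("pulsatility map integrates the cardiac window as specified", {
  dims <- c(3, 3, 1)
  n <- 500; tr <- 0.25
  t <- (0:(n - 1)) * tr
  mask <- array(TRUE, dims)
  fc <- new("CardiacFrequency", fcHz = 1.0, halfWindowHz = 0.02,
            source = "trace_mean")

  # 100 + 2 sin(2 pi t): single bin of amplitude 2 at 1.0 Hz,
  # (2 * 0.008) / 0.04 = 0.4 -> 0.4 % of the mean of 100
  s <- seriesFromCourses(dims, n, tr, function(i) 100 + 2 * sin(2 * pi * t))
  m <- cardiacPulsatilityMap(s, fc, mask)
  expect_equal(unname(metricValues(m)[mask]), rep(0.4, 9), tolerance = 1e-9)

  # constant voxel -> 0; off-window sinusoid (on-bin, 1.504 Hz) -> 0
  s0 <- seriesFromCourses(dims, n, tr, function(i) rep(100, n))
  expect_lt(max(metricValues(cardiacPulsatilityMap(s0, fc, mask))[mask]),
            1e-9)
  s15 <- seriesFromCourses(dims, n, tr,
                           function(i) 100 + 2 * sin(2 * pi * 1.504 * t))
  expect_lt(max(metricValues(cardiacPulsatilityMap(s15, fc, mask))[mask]),
            1e-9)
})

test_that("pulsatility is linear in amplitude and level-invariant in the numerator", {
  dims <- c(2, 2, 1)
  n <- 500; tr <- 0.25
  t <- (0:(n - 1)) * tr
  mask <- array(TRUE, dims)
  fc <- new("CardiacFrequency", fcHz = 1.0, halfWindowHz = 0.02,
            source = "trace_mean")
  mk <- function(amp, level)
    seriesFromCourses(dims, n, tr,
                      function(i) level + amp * sin(2 * pi * t + 0.3))
  v1 <- metricValues(cardiacPulsatilityMap(mk(1, 100), fc, mask))[1]
  v2 <- metricValues(cardiacPulsatilityMap(mk(2, 100), fc, mask))[1]
  expect_equal(v2 / v1, 2, tolerance = 0.01)
  # doubling the level halves the percent value (numerator unchanged)
  v1b <- metricValues(cardiacPulsatilityMap(mk(1, 200), fc, mask))[1]
  expect_equal(v1b / v1, 0.5, tolerance = 1e-6)
})

test_that("pulsatility refuses an aliased cardiac window", {
  s <- BoldSeries(array(rnorm(4 * 4 * 1 * 64, 100), c(4, 4, 1, 64)), 2)
  fc <- new("CardiacFrequency", fcHz = 1.0, halfWindowHz = 0.02,
            source = "trace_mean")
  expect_error(cardiacPulsatilityMap(s, fc, array(TRUE, c(4, 4, 1))),
               "Nyquist")
})

test_that("tissue summaries average per class with NAWM excluding lesions", {
  dims <- c(10, 10, 1)
  gm <- array(FALSE, dims); gm[1:5, , ] <- TRUE
  wm <- array(FALSE, dims); wm[6:10, , ] <- TRUE
  wmh <- array(FALSE, dims); wmh[6:7, 1:5, ] <- TRUE
  tm <- TissueMasks(list(GM = gm, WM = wm, WMH = wmh))
  vals <- array(NA_real_, dims)
  vals[gm] <- 2; vals[wm] <- 1; vals[wmh] <- 5
  m <- new("VoxelMetricMap", values = vals, metricName = "sigma_physio",
           trSeconds = 0.25)
  ts <- tissueSummary(m, tm)
  expect_equal(ts$mean_pct[ts$class == "GM"], 2)
  expect_equal(ts$mean_pct[ts$class == "WMH"], 5)
  # oracle by mask-set arithmetic: NAWM = WM minus WMH
  expect_equal(ts$mean_pct[ts$class == "NAWM"], mean(vals[wm & !wmh]))
  expect_equal(ts$n_voxels[ts$class == "NAWM"], sum(wm) - sum(wmh))

  # uniform map: every class mean identical
  vals2 <- array(1, dims)
  m2 <- new("VoxelMetricMap", values = vals2, metricName = "sigma_physio",
            trSeconds = 0.25)
  expect_true(all(tissueSummary(m2, tm)$mean_pct == 1))

  # empty class reported missing, not zero
  tmEmpty <- TissueMasks(list(GM = gm, WM = wm, WMH = array(FALSE, dims)))
  tsE <- tissueSummary(m, tmEmpty)
  expect_true(is.na(tsE$mean_pct[tsE$class == "WMH"]))
  expect_equal(tsE$n_voxels[tsE$class == "WMH"], 0L)
})

test_that("cumulative motion sums per-volume displacements", {
  expect_equal(cumulativeMotion(rep(0.05, 500)), 25)
  expect_error(cumulativeMotion(numeric(0)), "empty")
  expect_error(cumulativeMotion(c(0.1, -0.1)), "nonnegative")
  # cohort-scale means arise from ~0.046-0.058 mm per volume
  expect_equal(cumulativeMotion(rep(0.046, 500)), 23)
  expect_equal(cumulativeMotion(rep(0.058, 500)), 29)
})

test_that("sigma_physio rises with injected broadband noise (paired sign test)", {
  n <- 200
  dims <- c(3, 3, 1)
  mask <- array(TRUE, dims)
  lowHigher <- logical(20)
  for (r in 1:20) {
    set.seed(100 + r)
    mLow <- voxelSignalModel(cardiacAmpPct = 0.5, physioBroadbandPct = 0.5,
                             thermalSd = 1)
    mHigh <- voxelSignalModel(cardiacAmpPct = 0.5, physioBroadbandPct = 1.0,
                              thermalSd = 1)
    sLow <- seriesFromCourses(dims, n, 0.25,
                              function(i) simulateVoxel(mLow, 1, n, 0.25,
                                                        seed = 1000 * r + i))
    sHigh <- seriesFromCourses(dims, n, 0.25,
                               function(i) simulateVoxel(mHigh, 1, n, 0.25,
                                                         seed = 1000 * r + i))
    vLow <- mean(metricValues(metricMap(sigmaPhysioMap(sLow, 1, mask)))[mask])
    vHigh <- mean(metricValues(metricMap(sigmaPhysioMap(sHigh, 1, mask)))[mask])
    lowHigher[r] <- vHigh > vLow
  }
  # sign test: 20/20 successes under H0 p = 2^-20; require all
  expect_true(all(lowHigher))
})
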