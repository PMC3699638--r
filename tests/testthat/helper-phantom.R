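# Shared fixtures: a reduced phantom profile (20 x 20 x 2 grid, 210
# volumes at TR 0.25 s) keeps simulation cheap while preserving every
# geometric property the pipeline relies on (ring tissue classes,
# background corners, lesion-in-WM).

smallDesign <- function(seed = 1L, ...) {
  cohortDesign(csDims = c(20, 20, 2), csVolumes = 210,
               wbDims = c(20, 20, 2), wbVolumes = 63, seed = seed, ...)
}

smallConfig <- function(mode = "cs", ...) {
  runConfig(mode = mode, thermalExtent = 4, ...)
}

# a deterministic BoldSeries whose voxel time courses are supplied by a
# function(index) -> numeric(n)
seriesFromCourses <- function(dims, n, tr, courseFn, voxelDims = c(3, 3, 5)) {
  arr <- array(0, c(dims, n))
  flat <- matrix(0, nrow = n, ncol = prod(dims))
  for (i in seq_len(prod(dims))) flat[, i] <- courseFn(i)
  BoldSeries(array(t(flat), c(dims, n)), trSeconds = tr,
             voxelDimsMm = voxelDims)
}

# brute-force direct DFT (independent oracle for the fast transform)
bruteDft <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  vapply(k, function(kk)
    sum(x * exp(-2i * pi * kk * (0:(n - 1)) / n)), complex(1))
}

# one-sided amplitudes from the brute-force DFT, same scaling convention
bruteAmplitudes <- function(x) {
  n <- length(x)
  X <- bruteDft(x)
  nHalf <- floor(n / 2)
  amp <- Mod(X[1:(nHalf + 1)]) / n
  scale <- rep(2, nHalf + 1)
  scale[1] <- 1
  if (n %% 2 == 0) scale[nHalf + 1] <- 1
  amp * scale
}

# a vector with exact sample mean `mean` and exact sample SD `sd`
exactMoments <- function(n, mean, sd, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n)
  x <- (x - base::mean(x)) / stats::sd(x)
  mean + sd * x
}
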