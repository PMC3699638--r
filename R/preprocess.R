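# Preprocessing: discarding initial volumes, Gaussian mask erosion to
# reduce partial-volume effects, and placement of the out-of-brain corner
# ROI used for thermal-noise estimation.

#' Discard initial volumes of a BOLD series
#'
#' Removes the first `nDiscard` time points (non-steady-state volumes);
#' the repetition time is unchanged. The cardiac-sampled protocol discards
#' 10 of 510 volumes so that variances are computed over a 500-point time
#' course; conventional-TR data are used as released (0 discarded).
#'
#' @param series a [BoldSeries-class].
#' @param nDiscard number of leading volumes to drop; must be <
#'   `nVolumes(series)`.
#' @return A trimmed [BoldSeries-class].
#' @export
trimVolumes <- function(series, nDiscard) {
  nDiscard <- as.integer(nDiscard)
  n <- nVolumes(series)
  if (nDiscard < 0L) stop("nDiscard must be >= 0")
  if (nDiscard >= n)
    stop(sprintf("cannot discard %d of %d volumes", nDiscard, n))
  if (nDiscard == 0L) return(series)
  BoldSeries(series@data[, , , (nDiscard + 1L):n, drop = FALSE],
             trSeconds = series@trSeconds,
             voxelDimsMm = series@voxelDimsMm)
}

# Separable Gaussian smoothing of a 3D array with zero padding outside the
# grid (outside-grid treated as non-tissue: conservative for erosion).
# fwhm is isotropic in mm and converted per axis to voxel units; axes whose
# kernel collapses to a delta are left untouched.
.gaussianSmooth3d <- function(arr, fwhmMm, voxelDimsMm) {
  sigmaVox <- (fwhmMm / (2 * sqrt(2 * log(2)))) / voxelDimsMm
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigmaVox[ax]
    r <- max(1L, ceiling(3 * s))
    w <- exp(-(seq(-r, r))^2 / (2 * s^2))
    w <- w / sum(w)
    if (length(w) == 1L || max(w) > 1 - 1e-12) next
    perm <- c(ax, setdiff(1:3, ax))
    x <- aperm(arr, perm)
    dp <- dim(x)
    m <- matrix(x, nrow = dp[1])
    npad <- dp[1] + 2L * r
    padded <- matrix(0, nrow = npad, ncol = ncol(m))
    padded[(r + 1L):(r + dp[1]), ] <- m
    out <- matrix(0, nrow = dp[1], ncol = ncol(m))
    for (k in seq_along(w))
      out <- out + w[k] * padded[k:(k + dp[1] - 1L), , drop = FALSE]
    arr <- aperm(array(out, dp), order(perm))
  }
  arr
}

#' Erode a binary mask with a Gaussian kernel
#'
#' The mask indicator is convolved with an isotropic Gaussian of the given
#' full width at half maximum (zero-padded at the grid boundary) and voxels
#' whose smoothed value falls below `keepThreshold` are removed. The output
#' is always a subset of the input, and erosion is monotone in the input
#' mask. Used to trim partial-volume boundary voxels from tissue masks.
#'
#' @param mask logical 3D array.
#' @param fwhmMm Gaussian kernel full width at half maximum in mm
#'   (default 3).
#' @param voxelDimsMm voxel dimensions in mm.
#' @param keepThreshold smoothed-value cutoff in (0, 1\]; voxels with
#'   smoothed indicator >= this are kept (default 0.9).
#' @return logical 3D array, a subset of `mask`.
#' @export
erodeMask <- function(mask, fwhmMm = 3, voxelDimsMm = c(3, 3, 5),
                      keepThreshold = 0.9) {
  if (fwhmMm <= 0) stop("fwhmMm must be positive")
  if (keepThreshold <= 0 || keepThreshold > 1)
    stop("keepThreshold must be in (0, 1]")
  if (!any(mask)) {
    warning("erodeMask: input mask is empty")
    return(mask)
  }
  sm <- .gaussianSmooth3d(array(as.numeric(mask), dim(mask)), fwhmMm,
                          voxelDimsMm)
  mask & (sm >= keepThreshold - 1e-12)
}

#' Erode every mask of a TissueMasks object
#'
#' GM, WM and CSF masks are eroded; the WMH lesion mask, when present, is
#' left as segmented (lesions are small and interior to WM).
#'
#' @inheritParams erodeMask
#' @param masks a [TissueMasks-class].
#' @param classes classes to erode.
#' @return An eroded [TissueMasks-class].
#' @export
erodeTissueMasks <- function(masks, fwhmMm = 3, voxelDimsMm = c(3, 3, 5),
                             keepThreshold = 0.9,
                             classes = c("GM", "WM", "CSF")) {
  out <- masks@masks
  for (cl in intersect(classes, names(out)))
    out[[cl]] <- suppressWarnings(
      erodeMask(out[[cl]], fwhmMm, voxelDimsMm, keepThreshold))
  TissueMasks(out)
}

.cornerNames <- c("x0y0", "x1y0", "x0y1", "x1y1")

.cornerMask <- function(dims, corner, extent) {
  m <- array(FALSE, dims)
  xs <- if (grepl("x0", corner)) 1:extent else (dims[1] - extent + 1L):dims[1]
  ys <- if (grepl("y0", corner)) 1:extent else (dims[2] - extent + 1L):dims[2]
  m[xs, ys, ] <- TRUE
  m
}

#' Place the thermal-noise ROI in an image corner
#'
#' Thermal (scanner/electronic) noise is estimated from a region outside
#' the brain, placed in a corner of the imaging grid to minimise
#' contribution from the EPI ghosting artifact. Any voxel belonging to a
#' tissue mask is excluded from the ROI.
#'
#' Policies: `"fixed"` uses the given corner; `"min-signal"` (default)
#' picks the corner with lowest mean signal, which avoids ghost energy;
#' `"all-corners"` returns the union of the four corner blocks (estimates
#' from one vs four corners differ by well under the between-subject
#' spread on homogeneous noise).
#'
#' @param series a [BoldSeries-class].
#' @param masks optional [TissueMasks-class]; tissue voxels are excluded.
#' @param extentVoxels in-plane size of each corner block (default 8,
#'   spanning all slices).
#' @param policy "min-signal", "fixed" or "all-corners".
#' @param corner corner used when `policy = "fixed"` ("x0y0", "x1y0",
#'   "x0y1" or "x1y1").
#' @return A [ThermalRoi-class].
#' @export
thermalRoi <- function(series, masks = NULL, extentVoxels = 8,
                       policy = c("min-signal", "fixed", "all-corners"),
                       corner = "x0y0") {
  policy <- match.arg(policy)
  extentVoxels <- as.integer(extentVoxels)
  dims <- spatialDim(series)
  if (extentVoxels < 1L || extentVoxels > min(dims[1:2]))
    stop("corner extent does not fit in the grid")
  tissue <- array(FALSE, dims)
  if (!is.null(masks))
    for (cl in maskClasses(masks)) tissue <- tissue | getMask(masks, cl)

  cornerMasks <- lapply(.cornerNames, function(cn)
    .cornerMask(dims, cn, extentVoxels) & !tissue)

  pick <- switch(policy,
    "fixed" = {
      if (!corner %in% .cornerNames)
        stop("corner must be one of ", paste(.cornerNames, collapse = ", "))
      match(corner, .cornerNames)
    },
    "min-signal" = {
      meanImg <- rowMeans(series@data, dims = 3L)
      meanSignal <- vapply(cornerMasks, function(cm) {
        if (!any(cm)) return(Inf)
        mean(meanImg[cm])
      }, numeric(1))
      which.min(meanSignal)
    },
    "all-corners" = 0L)

  roiMask <- if (policy == "all-corners") {
    Reduce(`|`, cornerMasks)
  } else cornerMasks[[pick]]
  roiName <- if (policy == "all-corners") "all" else .cornerNames[pick]
  if (!any(roiMask))
    stop("thermal ROI is empty after excluding tissue voxels")
  new("ThermalRoi", corner = roiName, extentVoxels = extentVoxels,
      mask = roiMask)
}
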