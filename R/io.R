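# Disk I/O: NIfTI volumes for series/masks/maps, delimited text for pulse
# traces and subject summary tables. Masks must already be in BOLD space;
# no registration is performed here.

#' Read a 4D BOLD series from a NIfTI file
#'
#' The repetition time is taken from the NIfTI header (pixdim\[4\]) unless
#' `trOverride` is supplied. An explicit override always wins; if it
#' disagrees with a positive header TR by more than 1 percent a warning is
#' emitted.
#'
#' @param path path to a 4D NIfTI file.
#' @param trOverride optional repetition time in seconds, overriding the
#'   header value.
#' @return A [BoldSeries-class].
#' @export
readBold <- function(path, trOverride = NULL) {
  if (!file.exists(path)) stop("BOLD file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- array(as.vector(img), dim(img))
  if (length(dim(arr)) != 4L)
    stop("expected 4D volume in '", path, "', got ",
         length(dim(arr)), "D")
  pd <- RNifti::pixdim(img)
  trHeader <- if (length(pd) >= 4L) pd[4L] else NA_real_
  tr <- trHeader
  if (!is.null(trOverride)) {
    if (is.finite(trHeader) && trHeader > 0 &&
        abs(trOverride - trHeader) > 0.01 * trHeader)
      warning(sprintf("TR override %.4g s differs from header TR %.4g s in %s",
                      trOverride, trHeader, path))
    tr <- trOverride
  }
  if (!is.finite(tr) || tr <= 0)
    stop("nonpositive or absent repetition time in '", path,
         "'; supply trOverride")
  vd <- pd[1:3]
  if (any(!is.finite(vd)) || any(vd <= 0)) vd <- c(3, 3, 5)
  BoldSeries(arr, trSeconds = tr, voxelDimsMm = vd)
}

#' Write a BoldSeries to NIfTI
#'
#' @param series a [BoldSeries-class].
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
writeBold <- function(series, path) {
  img <- RNifti::asNifti(series@data)
  RNifti::pixdim(img) <- c(series@voxelDimsMm, series@trSeconds)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read tissue masks from NIfTI files
#'
#' Masks are binarised (> 0.5) and checked against the spatial grid of a
#' reference series when one is given; any shape mismatch is a hard error.
#'
#' @param paths named character vector or list of NIfTI paths; names are
#'   tissue classes among GM, WM, WMH, CSF.
#' @param reference optional [BoldSeries-class] whose spatial grid the
#'   masks must match.
#' @return A [TissueMasks-class].
#' @export
readMasks <- function(paths, reference = NULL) {
  paths <- unlist(paths)
  if (is.null(names(paths)) || any(!nzchar(names(paths))))
    stop("mask paths must be named by tissue class")
  masks <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("mask file not found: ", p)
    img <- RNifti::readNifti(p)
    arr <- array(as.vector(img), dim(img))
    if (length(dim(arr)) == 4L && dim(arr)[4L] == 1L)
      arr <- arr[, , , 1L, drop = TRUE]
    if (length(dim(arr)) != 3L)
      stop("expected 3D mask in '", p, "'")
    arr > 0.5
  })
  tm <- TissueMasks(masks)
  if (!is.null(reference)) {
    sd <- spatialDim(reference)
    md <- spatialDim(tm)
    if (!identical(as.integer(md), as.integer(sd)))
      stop(sprintf("mask grid %s does not match series grid %s",
                   paste(md, collapse = "x"), paste(sd, collapse = "x")))
  }
  tm
}

#' Write tissue masks to NIfTI files
#'
#' @param masks a [TissueMasks-class].
#' @param dir output directory.
#' @param voxelDimsMm voxel dimensions recorded in the headers.
#' @return named vector of written paths, invisibly.
#' @export
writeMasks <- function(masks, dir, voxelDimsMm = c(3, 3, 5)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- vapply(maskClasses(masks), function(cl) {
    p <- file.path(dir, paste0("mask_", tolower(cl), ".nii.gz"))
    img <- RNifti::asNifti(array(as.integer(getMask(masks, cl)),
                                 dim = spatialDim(masks)))
    RNifti::pixdim(img) <- voxelDimsMm
    RNifti::writeNifti(img, p)
    p
  }, character(1))
  invisible(out)
}

#' Read a pulse-oximetry trace
#'
#' Expects two-column delimited text (time_seconds, bpm), with or without a
#' header. Rows with heart rate outside the physiologic plausibility band
#' \[30, 200\] bpm are dropped with a message; a file with no valid rows is
#' an error.
#'
#' @param path path to delimited text.
#' @param sep field separator; `""` auto-detects comma/tab/whitespace.
#' @return A [PulseTrace-class].
#' @export
readPulseTrace <- function(path, sep = "") {
  if (!file.exists(path)) stop("pulse trace not found: ", path)
  first <- readLines(path, n = 1L)
  if (sep == "")
    sep <- if (grepl(",", first)) "," else if (grepl("\t", first)) "\t" else ""
  hasHeader <- grepl("[A-Za-z]", first)
  df <- utils::read.table(path, header = hasHeader, sep = sep,
                          strip.white = TRUE)
  if (ncol(df) < 2L) stop("expected two columns (time_seconds, bpm) in ", path)
  times <- as.numeric(df[[1L]])
  bpm <- as.numeric(df[[2L]])
  keep <- is.finite(times) & is.finite(bpm) & bpm >= 30 & bpm <= 200
  nDropped <- sum(!keep)
  if (nDropped > 0L)
    message(nDropped, " pulse sample(s) outside [30, 200] bpm dropped from ",
            basename(path))
  if (!any(keep)) stop("no valid samples in pulse trace ", path)
  ord <- order(times[keep])
  PulseTrace(times[keep][ord], bpm[keep][ord])
}

#' Write a pulse trace as CSV
#'
#' @param trace a [PulseTrace-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePulseTrace <- function(trace, path) {
  utils::write.csv(data.frame(time_seconds = trace@timesSeconds,
                              bpm = trace@bpm),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a voxel metric map to NIfTI
#'
#' Undefined voxels are stored as NaN so the round-trip is lossless.
#'
#' @param map a [VoxelMetricMap-class].
#' @param path output path (.nii or .nii.gz).
#' @param voxelDimsMm voxel dimensions recorded in the header.
#' @return `path`, invisibly.
#' @export
writeMetricMap <- function(map, path, voxelDimsMm = c(3, 3, 5)) {
  img <- RNifti::asNifti(map@values)
  RNifti::pixdim(img) <- c(voxelDimsMm, map@trSeconds)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a voxel metric map written by [writeMetricMap()]
#'
#' @param path NIfTI path.
#' @param metricName metric stored in the file ("sigma_physio" or
#'   "cardiac_pulsatility").
#' @return A [VoxelMetricMap-class].
#' @export
readMetricMap <- function(path, metricName) {
  if (!file.exists(path)) stop("metric map not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- array(as.vector(img), dim(img))
  if (length(dim(arr)) != 3L) stop("expected 3D metric map in ", path)
  arr[is.nan(arr)] <- NA_real_
  pd <- RNifti::pixdim(img)
  tr <- if (length(pd) >= 4L && is.finite(pd[4L]) && pd[4L] > 0) pd[4L] else 1
  new("VoxelMetricMap", values = arr, metricName = metricName,
      trSeconds = tr)
}

#' Write the per-subject summary table
#'
#' One row per subject, tab-separated, with a header. Columns are the
#' subject identifier, group, covariates, per-tissue metric means and
#' bookkeeping counts produced by [runSubject()].
#'
#' @param rows data.frame of subject summaries.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSummaryTable <- function(rows, path) {
  if (!is.data.frame(rows) || nrow(rows) == 0L)
    stop("summary table must be a nonempty data.frame")
  utils::write.table(rows, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a per-subject summary table
#'
#' @param path path to a tab-separated summary written by
#'   [writeSummaryTable()].
#' @return data.frame of subject summaries.
#' @export
readSummaryTable <- function(path) {
  if (!file.exists(path)) stop("summary table not found: ", path)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Read a run configuration from YAML
#'
#' Flat keys override the defaults of [runConfig()].
#'
#' @param path YAML file path.
#' @return a run configuration list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  do.call(runConfig, vals)
}
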