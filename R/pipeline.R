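# Per-subject map computation and cohort-level statistics. The per-subject
# summary table is the sole contract between the map layer and the stats
# layer, so externally computed datasets can enter at either level.

#' Run configuration
#'
#' Collects every preprocessing, metric and statistics parameter with its
#' default. `discardVolumes = NULL` resolves by mode: 10 leading volumes
#' for cardiac-sampled data, 0 for conventional-TR data.
#'
#' @param mode "cs" (cardiac-sampled; both metrics) or "wb"
#'   (conventional TR; sigma_physio only).
#' @param discardVolumes leading volumes to discard (NULL = by mode).
#' @param erodeFwhmMm Gaussian erosion kernel FWHM in mm.
#' @param erodeKeepThreshold smoothed-indicator cutoff kept after erosion.
#' @param thermalCornerPolicy "min-signal", "fixed" or "all-corners".
#' @param thermalExtent in-plane corner ROI extent in voxels.
#' @param thermalCorner corner used under the "fixed" policy.
#' @param halfWindowHz cardiac integration half-window (Hz).
#' @param fcSource "trace_mean" or "trace_median".
#' @param alpha significance level for intra-subject contrasts.
#' @param bonferroniM family size for the post-hoc cohort trio.
#' @return named list of class `RunConfig`.
#' @export
runConfig <- function(mode = c("cs", "wb"), discardVolumes = NULL,
                      erodeFwhmMm = 3, erodeKeepThreshold = 0.9,
                      thermalCornerPolicy = "min-signal",
                      thermalExtent = 8, thermalCorner = "x0y0",
                      halfWindowHz = 0.02, fcSource = "trace_mean",
                      alpha = 0.05, bonferroniM = 3) {
  mode <- match.arg(mode)
  if (is.null(discardVolumes))
    discardVolumes <- if (mode == "cs") 10L else 0L
  structure(list(mode = mode, discardVolumes = as.integer(discardVolumes),
                 erodeFwhmMm = erodeFwhmMm,
                 erodeKeepThreshold = erodeKeepThreshold,
                 thermalCornerPolicy = thermalCornerPolicy,
                 thermalExtent = as.integer(thermalExtent),
                 thermalCorner = thermalCorner,
                 halfWindowHz = halfWindowHz, fcSource = fcSource,
                 alpha = alpha, bonferroniM = bonferroniM),
            class = "RunConfig")
}

.summaryValue <- function(summaryDf, class) {
  i <- match(class, summaryDf$class)
  if (is.na(i)) NA_real_ else summaryDf$mean_pct[i]
}

#' Run the per-subject pipeline
#'
#' Executes trim -> mask erosion -> thermal ROI -> sigma_physio map ->
#' (cs mode) cardiac frequency -> pulsatility map -> tissue summaries ->
#' intra-subject GM-vs-NAWM contrasts, and returns a one-row summary
#' data.frame. The thermal ROI is checked to be disjoint from every tissue
#' mask on every run. With `outDir` set the metric maps are written as
#' NIfTI; outputs are written to a temporary name and renamed, so a failed
#' subject leaves no partial files.
#'
#' @param bold a [BoldSeries-class].
#' @param masks a [TissueMasks-class] in BOLD space.
#' @param trace a [PulseTrace-class] (required in cs mode).
#' @param record optional one-row data.frame of covariates (subject_id,
#'   group, age_years, sex, wm_pve, cumulative_motion_mm, ...); carried
#'   into the summary row.
#' @param config a [runConfig()].
#' @param outDir optional directory for sigma_physio.nii.gz and (cs)
#'   pulsatility.nii.gz.
#' @return one-row data.frame subject summary.
#' @export
runSubject <- function(bold, masks, trace = NULL, record = NULL,
                       config = runConfig(), outDir = NULL) {
  if (!identical(as.integer(spatialDim(masks)),
                 as.integer(spatialDim(bold))))
    stop(sprintf("mask grid %s does not match series grid %s",
                 paste(spatialDim(masks), collapse = "x"),
                 paste(spatialDim(bold), collapse = "x")))
  cs <- config$mode == "cs"
  if (cs && is.null(trace))
    stop("cs mode requires a pulse trace")

  series <- trimVolumes(bold, config$discardVolumes)
  eroded <- erodeTissueMasks(masks, fwhmMm = config$erodeFwhmMm,
                             voxelDimsMm = voxelDims(bold),
                             keepThreshold = config$erodeKeepThreshold)
  roi <- thermalRoi(series, masks, extentVoxels = config$thermalExtent,
                    policy = config$thermalCornerPolicy,
                    corner = config$thermalCorner)
  for (cl in maskClasses(masks))
    if (any(roi@mask & getMask(masks, cl)))
      stop("thermal ROI intersects tissue mask ", cl)

  s2t <- thermalVariance(series, roi)

  evalMask <- Reduce(`|`, lapply(maskClasses(eroded),
                                 function(cl) getMask(eroded, cl)))
  decomp <- sigmaPhysioMap(series, s2t, evalMask)
  sigmaSummary <- tissueSummary(metricMap(decomp), eroded)
  sigmaContrast <- intraSubjectContrast(metricMap(decomp), eroded,
                                        alpha = config$alpha)

  fc <- NULL
  pulsSummary <- NULL
  pulsContrast <- list(classification = NA_character_)
  pulsMap <- NULL
  if (cs) {
    n <- nVolumes(series)
    fc <- cardiacFrequency(trace,
                           scanWindow = c(0, nVolumes(bold) * trSeconds(bold)),
                           trSeconds = trSeconds(series), mode = "cs",
                           halfWindowHz = config$halfWindowHz,
                           source = config$fcSource)
    pulsMap <- cardiacPulsatilityMap(series, fc, evalMask)
    pulsSummary <- tissueSummary(pulsMap, eroded)
    pulsContrast <- intraSubjectContrast(pulsMap, eroded,
                                         alpha = config$alpha)
  }

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    .atomicWrite <- function(map, name) {
      tmp <- file.path(outDir, paste0(".tmp_", name))
      writeMetricMap(map, tmp, voxelDimsMm = voxelDims(bold))
      file.rename(tmp, file.path(outDir, name))
    }
    .atomicWrite(metricMap(decomp), "sigma_physio.nii.gz")
    if (!is.null(pulsMap)) .atomicWrite(pulsMap, "pulsatility.nii.gz")
  }

  row <- data.frame(
    subject_id = if (!is.null(record$subject_id)) record$subject_id else "subject",
    group = if (!is.null(record$group)) record$group else NA_character_,
    mode = config$mode,
    tr_seconds = trSeconds(series),
    n_volumes_retained = nVolumes(series),
    fc_hz = if (cs) fcHz(fc) else NA_real_,
    thermal_variance = s2t,
    clipped_voxels = clippedCount(decomp),
    undefined_voxels = decomp@undefinedCount,
    sigma_physio_gm = .summaryValue(sigmaSummary, "GM"),
    sigma_physio_nawm = .summaryValue(sigmaSummary, "NAWM"),
    sigma_physio_wmh = .summaryValue(sigmaSummary, "WMH"),
    sigma_physio_csf = .summaryValue(sigmaSummary, "CSF"),
    pulsatility_gm = if (cs) .summaryValue(pulsSummary, "GM") else NA_real_,
    pulsatility_nawm = if (cs) .summaryValue(pulsSummary, "NAWM") else NA_real_,
    pulsatility_wmh = if (cs) .summaryValue(pulsSummary, "WMH") else NA_real_,
    pulsatility_csf = if (cs) .summaryValue(pulsSummary, "CSF") else NA_real_,
    contrast_sigma = sigmaContrast$classification,
    contrast_pulsatility = pulsContrast$classification,
    stringsAsFactors = FALSE)

  extras <- setdiff(names(record), names(row))
  if (length(extras)) row <- cbind(row, record[, extras, drop = FALSE])
  rownames(row) <- NULL
  row
}

.addRow <- function(report, res, metric, note = NULL) {
  res$metric <- metric
  if (!is.null(note)) res$note <- note
  rbind(report, res)
}

#' Run the cohort-level statistical battery
#'
#' Reproduces the study's test sequence over a subject summary table:
#' (1, 2) one-way ANOVA of the NAWM sigma_physio and cardiac pulsatility
#' means across groups, with post-hoc pooled-variance t-tests and
#' Bonferroni flags for the three pairwise comparisons; (3) tallies of the
#' per-subject GM-vs-NAWM contrast classifications; (4) ANCOVA with
#' thermal noise, then thermal noise + WM volume + WM partial-volume
#' estimate, as covariates of non-interest; (5) paired NAWM-vs-WMH t-tests
#' with Cohen's d (pooled and paired forms) within the lesion group;
#' (6) group comparison of cumulative head motion and motion-metric
#' correlations; plus Levene and Shapiro-Wilk diagnostics. Tests whose
#' inputs are missing are skipped with a reason.
#'
#' @param summaries data.frame from [runSubject()] (one row per subject).
#' @param config a [runConfig()].
#' @return list with `report` (data.frame of test results), `posthoc`
#'   (pairwise tests with Bonferroni flags), `contrastTable`
#'   (classification tallies) and `skipped` (character reasons).
#' @export
runCohort <- function(summaries, config = runConfig()) {
  skipped <- character()
  report <- NULL
  posthoc <- NULL
  groups <- unique(summaries$group[!is.na(summaries$group)])
  multiGroup <- length(groups) >= 2L

  metrics <- c(sigma_physio = "sigma_physio_nawm",
               pulsatility = "pulsatility_nawm")
  for (mn in names(metrics)) {
    col <- metrics[[mn]]
    vals <- summaries[[col]]
    if (is.null(vals) || all(is.na(vals))) {
      skipped <- c(skipped, paste0(mn, ": no NAWM values (", col, " empty)"))
      next
    }
    if (!multiGroup) {
      skipped <- c(skipped, paste0("ANOVA ", mn, ": fewer than 2 groups"))
    } else {
      report <- .addRow(report, oneWayAnova(vals, summaries$group), mn)
      # post-hoc pairwise trio with Bonferroni
      pairs <- utils::combn(sort(groups), 2L, simplify = FALSE)
      for (pr in pairs) {
        a <- vals[summaries$group == pr[1]]
        b <- vals[summaries$group == pr[2]]
        if (sum(is.finite(a)) < 2L || sum(is.finite(b)) < 2L) next
        res <- unpairedT(a, b)
        res$test <- paste0("posthoc_", pr[1], "_vs_", pr[2])
        res$metric <- mn
        res$bonferroni_significant <- NA
        posthoc <- rbind(posthoc, res)
      }
      if (!is.null(posthoc)) {
        sel <- posthoc$metric == mn
        posthoc$bonferroni_significant[sel] <-
          bonferroniAdjust(posthoc$p_value[sel], m = config$bonferroniM,
                           alpha = config$alpha)
      }
      # ANCOVA: thermal noise, then thermal + WM volume + WM PVE
      cov1 <- data.frame(thermal = summaries$thermal_variance)
      report <- .addRow(report, ancovaGroupTest(vals, summaries$group, cov1),
                        mn, note = "covariate: thermal noise")
      volCol <- intersect(c("wm_volume_mm3", "wm_volume_voxels"),
                          names(summaries))[1]
      if (!is.na(volCol) && "wm_pve" %in% names(summaries)) {
        cov3 <- data.frame(thermal = summaries$thermal_variance,
                           wm_volume = summaries[[volCol]],
                           wm_pve = summaries$wm_pve)
        report <- .addRow(report, ancovaGroupTest(vals, summaries$group, cov3),
                          mn, note = "covariates: thermal + WM volume + WM PVE")
      } else {
        skipped <- c(skipped, paste0("3-covariate ANCOVA ", mn,
                                     ": WM volume/PVE columns missing"))
      }
      # diagnostics
      report <- .addRow(report, varianceHomogeneity(vals, summaries$group), mn)
      for (g in sort(groups)) {
        gv <- vals[summaries$group == g & is.finite(vals)]
        if (length(gv) >= 3L) {
          res <- normalityShapiro(gv)
          res$test <- paste0("shapiro_", g)
          report <- .addRow(report, res, mn)
        }
      }
    }
    # paired NAWM vs WMH within the lesion group
    wmhCol <- sub("nawm", "wmh", col)
    wmh <- summaries[[wmhCol]]
    hasPairs <- !is.null(wmh) & is.finite(vals) & is.finite(wmh)
    if (sum(hasPairs) >= 2L) {
      res <- pairedT(vals[hasPairs], wmh[hasPairs])
      res$test <- "paired_nawm_vs_wmh"
      res$effect_size <- cohensD(vals[hasPairs], wmh[hasPairs])
      res$note <- sprintf("d_pooled = %.3f, d_paired = %.3f",
                          cohensD(vals[hasPairs], wmh[hasPairs]),
                          cohensD(vals[hasPairs], wmh[hasPairs], paired = TRUE))
      report <- .addRow(report, res, mn)
    } else {
      skipped <- c(skipped, paste0("paired NAWM-vs-WMH ", mn,
                                   ": fewer than 2 subjects with WMH"))
    }
  }

  # contrast tallies (GM vs NAWM classification per group per metric)
  contrastTable <- NULL
  for (cc in c("contrast_sigma", "contrast_pulsatility")) {
    if (!cc %in% names(summaries) || all(is.na(summaries[[cc]]))) next
    tab <- table(group = summaries$group, classification = summaries[[cc]])
    contrastTable <- rbind(contrastTable,
                           cbind(data.frame(metric = cc),
                                 as.data.frame(tab)))
  }

  # head motion: EC vs SVD comparison and motion-metric correlations
  if ("cumulative_motion_mm" %in% names(summaries)) {
    mot <- summaries$cumulative_motion_mm
    if (all(c("EC", "SVD") %in% groups)) {
      res <- unpairedT(mot[summaries$group == "EC"],
                       mot[summaries$group == "SVD"])
      res$test <- "motion_EC_vs_SVD"
      report <- .addRow(report, res, "motion")
    }
    for (g in intersect(c("EC", "SVD"), groups)) {
      sel <- summaries$group == g
      if (sum(sel) >= 3L && !all(is.na(summaries$sigma_physio_nawm[sel]))) {
        res <- pearsonCorr(mot[sel], summaries$sigma_physio_nawm[sel])
        res$test <- paste0("motion_corr_sigma_", g)
        report <- .addRow(report, res, "motion")
      }
    }
  } else {
    skipped <- c(skipped, "motion tests: cumulative_motion_mm missing")
  }

  # lesion burden vs metrics within the lesion group
  if (all(c("wmh_volume_voxels") %in% names(summaries)) &&
      "SVD" %in% groups) {
    sel <- summaries$group == "SVD" & summaries$wmh_volume_voxels > 0
    if (sum(sel) >= 3L) {
      res <- pearsonCorr(summaries$wmh_volume_voxels[sel],
                         summaries$sigma_physio_nawm[sel])
      res$test <- "wmh_volume_corr_sigma"
      report <- .addRow(report, res, "sigma_physio")
    }
  }

  rownames(report) <- NULL
  if (!is.null(posthoc)) rownames(posthoc) <- NULL
  list(report = report, posthoc = posthoc, contrastTable = contrastTable,
       skipped = skipped)
}

#' End-to-end demonstration on a small phantom cohort
#'
#' Simulates a reduced cardiac-sampled cohort (20 x 20 x 2 grid, 210
#' volumes), runs the per-subject pipeline and the cohort statistics, and
#' returns everything. Deterministic in `seed`.
#'
#' @param seed integer seed.
#' @param nSubjects per-group subject counts.
#' @param outDir optional directory for maps and tables.
#' @return list with `summaries`, `stats`, `truth` and the `design`.
#' @export
runDemo <- function(seed = 1L, nSubjects = c(YC = 11, EC = 10, SVD = 7),
                    outDir = NULL) {
  design <- cohortDesign(nSubjects = nSubjects, csDims = c(20, 20, 2),
                         csVolumes = 210, seed = seed)
  config <- runConfig(mode = "cs", thermalExtent = 4)
  cohort <- simulateCohort(design, mode = "cs")
  summaries <- do.call(rbind, lapply(cohort$subjects, function(s)
    runSubject(s$bold, s$masks, s$trace, s$record, config,
               outDir = if (!is.null(outDir))
                 file.path(outDir, s$record$subject_id) else NULL)))
  rownames(summaries) <- NULL
  stats <- runCohort(summaries, config)
  if (!is.null(outDir)) {
    writeSummaryTable(summaries, file.path(outDir, "summaries.tsv"))
    utils::write.table(stats$report, file.path(outDir, "report.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(summaries = summaries, stats = stats, truth = cohort$truth,
       design = design)
}
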