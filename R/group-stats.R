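# Cohort-level statistics over per-subject tissue summaries: one-way
# ANOVA and ANCOVA across groups, pooled-variance post-hoc t-tests with
# Bonferroni correction, paired lesion contrasts with Cohen's d,
# Levene/Shapiro-Wilk diagnostics, Pearson correlation and age regression.
# Two-tailed p values throughout.

.testResult <- function(test, statistic = NA_real_, df1 = NA_real_,
                        df2 = NA_real_, p_value = NA_real_,
                        effect_size = NA_real_, note = NA_character_) {
  data.frame(test = test, statistic = statistic, df1 = df1, df2 = df2,
             p_value = p_value, effect_size = effect_size, note = note,
             stringsAsFactors = FALSE)
}

.checkGroups <- function(values, group) {
  if (length(values) != length(group)) stop("values and group lengths differ")
  keep <- is.finite(values) & !is.na(group)
  values <- values[keep]
  group <- droplevels(factor(group[keep]))
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  if (any(table(group) < 2L))
    stop("every group needs at least 2 observations")
  list(values = values, group = group)
}

#' One-way ANOVA across groups
#'
#' Standard between/within variance decomposition; F has (k - 1, N - k)
#' degrees of freedom. With the three study cohorts of 11, 10 and 7
#' subjects the group test carries df (2, 25).
#'
#' @param values numeric outcome per subject.
#' @param group group label per subject.
#' @return one-row data.frame (test, statistic, df1, df2, p_value, ...).
#' @export
oneWayAnova <- function(values, group) {
  g <- .checkGroups(values, group)
  fit <- stats::aov(g$values ~ g$group)
  tab <- summary(fit)[[1L]]
  .testResult("one_way_anova", statistic = tab[["F value"]][1L],
              df1 = tab[["Df"]][1L], df2 = tab[["Df"]][2L],
              p_value = tab[["Pr(>F)"]][1L])
}

#' ANCOVA group test with covariates of non-interest
#'
#' Tests the group factor after adjusting for covariates by model
#' comparison: `value ~ covariates` vs `value ~ covariates + group`
#' (a Type III-style group test). With k groups, N subjects and p
#' covariates the F test has (k - 1, N - k - p) df, e.g. (2, 24) for one
#' covariate and (2, 22) for three on a 28-subject cohort. With no
#' covariates the result equals the one-way ANOVA exactly.
#'
#' @param values numeric outcome per subject.
#' @param group group label per subject.
#' @param covariates data.frame (or NULL) of numeric covariates, e.g.
#'   thermal variance, WM volume, WM partial-volume estimate.
#' @return one-row data.frame.
#' @export
ancovaGroupTest <- function(values, group, covariates = NULL) {
  if (is.null(covariates) || NCOL(covariates) == 0L) {
    res <- oneWayAnova(values, group)
    res$test <- "ancova"
    return(res)
  }
  covariates <- as.data.frame(covariates)
  keep <- is.finite(values) & !is.na(group) &
    stats::complete.cases(covariates)
  values <- values[keep]
  group <- droplevels(factor(group[keep]))
  covariates <- covariates[keep, , drop = FALSE]
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  if (length(values) <= nlevels(group) + ncol(covariates))
    stop("too few observations for the requested model")
  dat <- cbind(data.frame(.y = values, .g = group), covariates)
  covTerms <- paste(colnames(covariates), collapse = " + ")
  reduced <- stats::lm(stats::as.formula(paste(".y ~", covTerms)), data = dat)
  if (any(!is.finite(stats::coef(reduced))) || reduced$rank < ncol(covariates) + 1L)
    stop("covariate matrix is rank deficient")
  full <- stats::lm(stats::as.formula(paste(".y ~", covTerms, "+ .g")),
                    data = dat)
  cmp <- stats::anova(reduced, full)
  .testResult("ancova", statistic = cmp[["F"]][2L],
              df1 = cmp[["Df"]][2L], df2 = cmp[["Res.Df"]][2L],
              p_value = cmp[["Pr(>F)"]][2L])
}

#' Two-sample t-tests (pooled-variance unpaired, and paired)
#'
#' Two-tailed throughout. The unpaired form uses the pooled-variance
#' Student t (Welch available by flag); identical samples (zero variance
#' of differences, or zero pooled variance) yield an undefined statistic
#' flagged in the `note` column rather than an error.
#'
#' @param a,b numeric samples (equal length for the paired test).
#' @param welch use the Welch unequal-variance form (default FALSE).
#' @return one-row data.frame; `effect_size` carries Cohen's d (pooled
#'   form).
#' @name tTests
#' @export
unpairedT <- function(a, b, welch = FALSE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs >= 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    return(.testResult("unpaired_t", note = "zero variance: t undefined"))
  ht <- stats::t.test(a, b, var.equal = !welch)
  .testResult("unpaired_t", statistic = unname(ht$statistic),
              df1 = unname(ht$parameter), p_value = ht$p.value,
              effect_size = cohensD(a, b))
}

#' @rdname tTests
#' @export
pairedT <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2L) stop("need >= 2 complete pairs")
  d <- a - b
  if (stats::var(d) == 0)
    return(.testResult("paired_t",
                       note = "zero variance of differences: t undefined"))
  ht <- stats::t.test(a, b, paired = TRUE)
  .testResult("paired_t", statistic = unname(ht$statistic),
              df1 = unname(ht$parameter), p_value = ht$p.value,
              effect_size = cohensD(a, b))
}

#' Cohen's d effect size
#'
#' Default is the classic pooled-standard-deviation form
#' (mean(a) - mean(b)) / s_pooled, reported even alongside paired tests;
#' `paired = TRUE` gives the alternative mean-difference / SD-of-
#' differences form. Zero denominator yields NA.
#'
#' @param a,b numeric samples.
#' @param paired use the SD-of-differences denominator.
#' @return scalar d (NA when undefined).
#' @export
cohensD <- function(a, b, paired = FALSE) {
  if (paired) {
    if (length(a) != length(b)) stop("paired samples must have equal length")
    d <- a - b
    s <- stats::sd(d)
    return(if (s == 0) NA_real_ else mean(d) / s)
  }
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("each sample needs >= 2 values")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
    (na + nb - 2)
  if (sp2 == 0) return(NA_real_)
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Levene's test of variance homogeneity
#'
#' One-way ANOVA on absolute deviations from the group means (mean
#' centring, the SPSS convention).
#'
#' @param values numeric outcome per subject.
#' @param group group label per subject.
#' @return one-row data.frame.
#' @export
varianceHomogeneity <- function(values, group) {
  g <- .checkGroups(values, group)
  groupMeans <- tapply(g$values, g$group, mean)
  absDev <- abs(g$values - groupMeans[g$group])
  res <- oneWayAnova(absDev, g$group)
  res$test <- "levene"
  res
}

#' Shapiro-Wilk normality test
#'
#' Wraps the published AS R94 approximation (stats::shapiro.test);
#' requires 3 <= n <= 2000.
#'
#' @param values numeric sample.
#' @return one-row data.frame with W as the statistic.
#' @export
normalityShapiro <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3L || length(values) > 2000L)
    stop("Shapiro-Wilk requires 3 <= n <= 2000")
  ht <- stats::shapiro.test(values)
  .testResult("shapiro_wilk", statistic = unname(ht$statistic),
              df1 = length(values), p_value = ht$p.value)
}

#' Pearson correlation with two-tailed p value
#'
#' @param x,y numeric vectors, n >= 3; constant input yields an undefined
#'   (flagged) result.
#' @return one-row data.frame; `effect_size` carries r.
#' @export
pearsonCorr <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(.testResult("pearson_corr", note = "constant input: r undefined"))
  ht <- stats::cor.test(x, y)
  .testResult("pearson_corr", statistic = unname(ht$statistic),
              df1 = unname(ht$parameter), p_value = ht$p.value,
              effect_size = unname(ht$estimate))
}

#' Linear age regression of a metric
#'
#' Regresses the metric on age, reporting slope, Pearson r and the
#' two-tailed p of the age coefficient; when extra covariates (e.g. slice
#' thickness) are supplied the covariate-adjusted age p value is reported
#' alongside. Used for the conventional-TR verification of the white
#' matter aging effect.
#'
#' @param metric numeric outcome per subject.
#' @param age numeric age in years.
#' @param extraCovariates optional data.frame of additional regressors.
#' @return list with `slope`, `r`, `p_value`, `adjusted_p` (NA when no
#'   extras), and the one-row data.frame `result`.
#' @export
ageRegression <- function(metric, age, extraCovariates = NULL) {
  keep <- is.finite(metric) & is.finite(age)
  if (!is.null(extraCovariates))
    keep <- keep & stats::complete.cases(as.data.frame(extraCovariates))
  metric <- metric[keep]; age <- age[keep]
  if (length(metric) < 3L) stop("need at least 3 complete observations")
  if (stats::sd(age) == 0) stop("age is constant")
  fit <- stats::lm(metric ~ age)
  co <- summary(fit)$coefficients
  r <- stats::cor(metric, age)
  adjP <- NA_real_
  if (!is.null(extraCovariates)) {
    dat <- cbind(data.frame(.y = metric, age = age),
                 as.data.frame(extraCovariates)[keep, , drop = FALSE])
    fit2 <- stats::lm(.y ~ ., data = dat)
    adjP <- summary(fit2)$coefficients["age", "Pr(>|t|)"]
  }
  res <- .testResult("age_regression", statistic = co["age", "t value"],
                     df1 = fit$df.residual, p_value = co["age", "Pr(>|t|)"],
                     effect_size = r)
  list(slope = unname(co["age", "Estimate"]), r = r,
       p_value = co["age", "Pr(>|t|)"], adjusted_p = adjP, result = res)
}

#' Intra-subject GM vs NAWM tissue contrast
#'
#' Unpaired two-sample t-test across the voxel values of a subject's
#' metric map in GM vs NAWM, classified at `alpha` into "NAWM<GM"
#' (significantly lower in NAWM), "NAWM=GM" (no significant difference)
#' or "NAWM>GM". Tabulated over a cohort this reproduces the
#' tissue-contrast proportions table.
#'
#' @param map a [VoxelMetricMap-class].
#' @param masks a [TissueMasks-class] (eroded).
#' @param alpha significance level (default 0.05).
#' @return list with `classification`, and `result` (one-row data.frame);
#'   classification is NA when either class is empty.
#' @export
intraSubjectContrast <- function(map, masks, alpha = 0.05) {
  gm <- map@values[getMask(masks, "GM")]
  nawm <- map@values[getMask(masks, "NAWM")]
  gm <- gm[!is.na(gm)]; nawm <- nawm[!is.na(nawm)]
  if (length(gm) < 2L || length(nawm) < 2L)
    return(list(classification = NA_character_,
                result = .testResult("intra_subject_contrast",
                                     note = "empty tissue class: skipped")))
  res <- unpairedT(nawm, gm)
  res$test <- "intra_subject_contrast"
  cls <- if (is.na(res$p_value) || res$p_value >= alpha) "NAWM=GM"
         else if (mean(nawm) < mean(gm)) "NAWM<GM" else "NAWM>GM"
  list(classification = cls, result = res)
}

#' Bonferroni correction
#'
#' A comparison is significant after correction iff p < alpha / m. The
#' post-hoc cohort trio (YC-EC, EC-SVD, YC-SVD) uses m = 3.
#'
#' @param pValues numeric vector of uncorrected p values.
#' @param m number of comparisons in the family (default
#'   `length(pValues)`).
#' @param alpha family-wise level (default 0.05).
#' @return logical vector of post-correction significance flags.
#' @export
bonferroniAdjust <- function(pValues, m = length(pValues), alpha = 0.05) {
  if (m < 1L) stop("m must be >= 1")
  pValues < alpha / m
}
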