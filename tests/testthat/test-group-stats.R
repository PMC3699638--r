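# The cohort statistics battery, checked against hand computations,
# independent library routes and Monte-Carlo calibration.

test_that("one-way ANOVA matches hand-computed sums of squares", {
  # oracle computed by hand: groups (1,2,3), (1,2,3), (11,12,13)
  vals <- c(1, 2, 3, 1, 2, 3, 11, 12, 13)
  grp <- rep(c("a", "b", "c"), each = 3)
  # group means 2, 2, 12; grand mean 16/3
  ssb <- 3 * (2 * (2 - 16 / 3)^2 + (12 - 16 / 3)^2)  # = 200
  ssw <- 3 * 2  # each group contributes 1 + 0 + 1 = 2
  fOracle <- (ssb / 2) / (ssw / 6)                   # = 100
  res <- oneWayAnova(vals, grp)
  expect_equal(res$statistic, fOracle, tolerance = 1e-12)
  expect_equal(c(res$df1, res$df2), c(2, 6))
  expect_lt(res$p_value, 0.001)

  # three identical groups: no between-group variance
  resF0 <- oneWayAnova(c(1, 2, 3, 1, 2, 3, 1, 2, 3), grp)
  expect_equal(resF0$statistic, 0, tolerance = 1e-12)

  # study-sized cohort: df (2, 25)
  set.seed(20)
  res28 <- oneWayAnova(rnorm(28), rep(c("YC", "EC", "SVD"), c(11, 10, 7)))
  expect_equal(c(res28$df1, res28$df2), c(2, 25))

  expect_error(oneWayAnova(c(1, 2, 3), c("a", "a", "b")),
               "at least 2 observations")
})

test_that("ANCOVA df bookkeeping and degenerate covariates behave", {
  set.seed(21)
  grp <- rep(c("YC", "EC", "SVD"), c(11, 10, 7))
  y <- rnorm(28) + as.numeric(factor(grp))
  c1 <- data.frame(thermal = rnorm(28))
  c3 <- cbind(c1, data.frame(vol = rnorm(28), pve = rnorm(28)))
  r1 <- ancovaGroupTest(y, grp, c1)
  r3 <- ancovaGroupTest(y, grp, c3)
  expect_equal(c(r1$df1, r1$df2), c(2, 24))
  expect_equal(c(r3$df1, r3$df2), c(2, 22))

  # zero covariates: exact agreement with one-way ANOVA
  r0 <- ancovaGroupTest(y, grp, NULL)
  a0 <- oneWayAnova(y, grp)
  expect_equal(r0$statistic, a0$statistic, tolerance = 1e-12)
  expect_equal(r0$p_value, a0$p_value, tolerance = 1e-12)

  # group effect wholly mediated by a covariate: once the covariate is
  # controlled the group term explains only residual noise (oracle:
  # residualising y on the covariate removes the group signal)
  covMed <- y + rnorm(28, 0, 0.01)
  rMed <- ancovaGroupTest(y, grp, data.frame(m = covMed))
  expect_gt(rMed$p_value, 0.05)
  expect_lt(rMed$statistic, a0$statistic / 10)

  # covariate nearly orthogonal to group and outcome: F close to ANOVA
  cOrth <- resid(lm(rnorm(28) ~ y + factor(grp)))
  rOrth <- ancovaGroupTest(y, grp, data.frame(o = cOrth))
  expect_equal(rOrth$statistic, a0$statistic, tolerance = 0.1)

  expect_error(ancovaGroupTest(y, grp, data.frame(a = rep(1, 28))),
               "rank deficient")
})

test_that("t-tests report two-tailed p, pooled df, and flag degeneracy", {
  a <- c(1, 2, 3, 4); b <- c(1.1, 2.1, 3.1, 4.1)
  # paired with near-constant +1 differences separates sharply
  set.seed(22)
  x <- rnorm(7); yv <- x + 1 + rnorm(7, 0, 1e-4)
  rp <- pairedT(yv, x)
  expect_equal(rp$df1, 6)           # n = 7 pairs -> df 6
  expect_gt(rp$statistic, 100)
  expect_lt(rp$p_value, 1e-10)

  # identical samples: flagged, not an error
  rid <- pairedT(a, a)
  expect_true(is.na(rid$statistic))
  expect_match(rid$note, "undefined")

  # unpaired pooled df = n1 + n2 - 2; F = t^2 with two groups
  ru <- unpairedT(a, b)
  expect_equal(ru$df1, 6)
  anova2 <- oneWayAnova(c(a, b + 2), rep(c("g1", "g2"), each = 4))
  t2 <- unpairedT(a, b + 2)
  expect_equal(anova2$statistic, t2$statistic^2, tolerance = 1e-10)

  # affine invariance of t and of Cohen's d
  ru2 <- unpairedT(10 + 2 * a, 10 + 2 * (b + 2))
  expect_equal(ru2$statistic, t2$statistic, tolerance = 1e-10)
  expect_equal(cohensD(10 + 2 * a, 10 + 2 * b), cohensD(a, b),
               tolerance = 1e-10)
})

test_that("Cohen's d matches hand computation in both variants", {
  expect_equal(cohensD(c(1, 2, 3), c(1, 2, 3)), 0)
  # a = (2,4), b = (1,3): pooled SD = sqrt(2), d = 1/sqrt(2)
  expect_equal(cohensD(c(2, 4), c(1, 3)), 1 / sqrt(2), tolerance = 1e-12)
  # unit case: means 1 and 0 with common SD 1
  set.seed(23)
  z <- exactMoments(50, 0, 1, seed = 23)
  expect_equal(cohensD(z + 1, z), 1, tolerance = 1e-10)
  # paired variant: mean difference / SD of differences
  d <- c(2, 4) - c(1, 3)  # constant differences -> NA
  expect_true(is.na(cohensD(c(2, 4), c(1, 3), paired = TRUE)))
  expect_equal(cohensD(c(2, 4.1), c(1, 3), paired = TRUE),
               mean(c(1, 1.1)) / sd(c(1, 1.1)), tolerance = 1e-12)
})

test_that("Levene on mean deviations agrees with the car route and has power", {
  skip_if_not_installed("car")
  set.seed(24)
  vals <- rnorm(60)
  grp <- rep(c("a", "b", "c"), each = 20)
  mine <- varianceHomogeneity(vals, grp)
  theirs <- car::leveneTest(vals ~ factor(grp), center = mean)
  expect_equal(mine$statistic, theirs[1, "F value"], tolerance = 1e-10)
  expect_equal(mine$p_value, theirs[1, "Pr(>F)"], tolerance = 1e-10)

  # a 10x variance group is detected
  vals2 <- c(rnorm(200), rnorm(200), rnorm(200, 0, sqrt(10)))
  grp2 <- rep(c("a", "b", "c"), each = 200)
  expect_lt(varianceHomogeneity(vals2, grp2)$p_value, 0.01)
})

test_that("null calibration: t, Levene and Shapiro reject at ~5%", {
  set.seed(25)
  nrep <- 200
  rejT <- rejL <- rejS <- logical(nrep)
  for (r in seq_len(nrep)) {
    a <- rnorm(20); b <- rnorm(20)
    rejT[r] <- unpairedT(a, b)$p_value < 0.05
    vals <- rnorm(60); grp <- rep(c("a", "b", "c"), each = 20)
    rejL[r] <- varianceHomogeneity(vals, grp)$p_value < 0.05
    rejS[r] <- normalityShapiro(rnorm(50))$p_value < 0.05
  }
  expect_lt(abs(mean(rejT) - 0.05), 0.03)
  expect_lt(abs(mean(rejL) - 0.05), 0.03)
  expect_lt(abs(mean(rejS) - 0.05), 0.03)
})

test_that("correlation and age regression recover generator truth", {
  x <- 1:10
  expect_equal(pearsonCorr(x, x)$effect_size, 1, tolerance = 1e-12)
  expect_match(pearsonCorr(rep(1, 5), 1:5)$note, "constant")

  set.seed(26)
  age <- runif(84, 19, 85)
  metric <- 2 * age + rnorm(84, 0, 20)
  fitRes <- ageRegression(metric, age)
  ci <- confint(lm(metric ~ age))["age", ]
  expect_gt(fitRes$slope, ci[1]); expect_lt(fitRes$slope, ci[2])
  expect_true(ci[1] < 2 && 2 < ci[2])  # truth inside the CI
  expect_lt(fitRes$p_value, 0.01)
  # covariate-adjusted p reported when extras supplied
  fit2 <- ageRegression(metric, age,
                        extraCovariates = data.frame(thk = rnorm(84)))
  expect_false(is.na(fit2$adjusted_p))

  # independence: p roughly uniform over replicates
  pv <- replicate(200, pearsonCorr(rnorm(84), rnorm(84))$p_value)
  expect_lt(abs(mean(pv < 0.05) - 0.05), 0.04)
  expect_lt(abs(mean(pv) - 0.5), 0.07)
})

test_that("intra-subject contrast classifies separation and calibrates under the null", {
  dims <- c(20, 20, 1)
  gm <- array(FALSE, dims); gm[1:10, , ] <- TRUE
  wm <- array(FALSE, dims); wm[11:20, , ] <- TRUE
  tm <- TissueMasks(list(GM = gm, WM = wm))
  set.seed(27)
  vals <- array(NA_real_, dims)
  vals[gm] <- rnorm(200, 2, 0.1); vals[wm] <- rnorm(200, 1, 0.1)
  m <- new("VoxelMetricMap", values = vals, metricName = "sigma_physio",
           trSeconds = 0.25)
  expect_equal(intraSubjectContrast(m, tm)$classification, "NAWM<GM")

  # identical distributions: "no difference" in about 95 % of replicates
  eq <- replicate(200, {
    v <- array(NA_real_, dims)
    v[gm] <- rnorm(200, 10); v[wm] <- rnorm(200, 10)
    mm <- new("VoxelMetricMap", values = v, metricName = "sigma_physio",
              trSeconds = 0.25)
    intraSubjectContrast(mm, tm)$classification == "NAWM=GM"
  })
  expect_lt(abs(mean(eq) - 0.95), 0.03)
})

test_that("Bonferroni correction uses the m = 3 post-hoc family rule", {
  # the EC-to-SVD case at p < 0.04 loses significance; p < 0.004 survives
  expect_false(bonferroniAdjust(0.04, m = 3))
  expect_true(bonferroniAdjust(0.004, m = 3))
  expect_equal(bonferroniAdjust(c(0.049, 0.051), m = 1), c(TRUE, FALSE))
})
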