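# Reliability and method-comparison statistics

test_that("PCC bands reproduce the published cutpoints, gaps to the lower band", {
  expect_equal(pccBand(0.645), "Good")       # reported intra-observer PCC
  expect_equal(pccBand(0.837), "Excellent")  # reported FCM-vs-RG PCC
  expect_equal(pccBand(0.845), "Excellent")
  expect_equal(pccBand(1), "Excellent")
  expect_equal(pccBand(0.8101), "Excellent")
  expect_equal(pccBand(0.810), "Good")       # band edge: not > 0.810
  expect_equal(pccBand(0.8095), "Good")      # gap value -> lower band
  expect_equal(pccBand(0.61), "Good")
  expect_equal(pccBand(0.6095), "Moderate")
  expect_equal(pccBand(0.410), "Moderate")
  expect_equal(pccBand(0.409), "Fair")
  expect_equal(pccBand(0.210), "Fair")
  expect_equal(pccBand(0.2095), "Poor")      # gap value -> lower band
  expect_equal(pccBand(0.208), "Poor")
  expect_equal(pccBand(-0.4), "Poor")
})

test_that("pearsonWithBand computes r and refuses constant series", {
  x <- c(40, 42, 38, 45, 41)
  expect_equal(pearsonWithBand(x, x), list(pcc = 1, band = "Excellent"))
  set.seed(2); y <- x + rnorm(5, 0, 4)
  expect_equal(pearsonWithBand(x, y)$pcc, cor(x, y))
  expect_error(pearsonWithBand(rep(1, 5), x), "constant")
})

test_that("pearson is invariant under positive affine transforms", {
  set.seed(4)
  x <- runif(12, 30, 50); y <- x + rnorm(12, 0, 3)
  r0 <- pearsonWithBand(x, y)$pcc
  expect_equal(pearsonWithBand(2.5 * x + 7, y)$pcc, r0, tolerance = 1e-12)
  expect_equal(pearsonWithBand(x, 0.1 * y - 3)$pcc, r0, tolerance = 1e-12)
})

test_that("paired t matches the reference implementation and handles degeneracy", {
  x <- c(40, 42, 38, 45, 41, 44, 39, 43, 40, 42)
  set.seed(6); y <- x + rnorm(10, 1, 2)
  mine <- pairedT(x, y)
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  expect_equal(mine$df, unname(ref$parameter))
  ident <- pairedT(x, x)
  expect_equal(ident$t, 0); expect_equal(ident$p, 1)
  deg <- pairedT(c(2, 3, 4, 5), c(1, 2, 3, 4))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p))
  # swapping the series flips t, leaves p unchanged
  expect_equal(pairedT(y, x)$t, -mine$t, tolerance = 1e-12)
  expect_equal(pairedT(y, x)$p, mine$p, tolerance = 1e-12)
})

test_that("absolute error is the documented asymmetric percentage", {
  expect_equal(absoluteError(40, 44)$errors, 10)
  expect_equal(absoluteError(c(40, 50), c(40, 50))$summary[["mean"]], 0)
  asym <- absoluteError(c(40, 50), c(44, 45))
  expect_equal(asym$errors, c(10, 10))
  expect_false(isTRUE(all.equal(absoluteError(c(44, 45), c(40, 50))$errors,
                                asym$errors)))
  expect_error(absoluteError(c(0, 1), c(1, 1)), "nonzero")
  set.seed(8)
  x <- runif(15, 30, 50); y <- x + rnorm(15, 0, 4)
  s <- absoluteError(x, y)$summary
  e <- 100 * abs(x - y) / x
  expect_equal(unname(s), c(mean(e), sd(e), min(e), max(e)))
})

test_that("ICC forms match the ANOVA mean-squares oracle", {
  ratings <- rbind(c(9, 2), c(1, 10), c(8, 8), c(2, 6), c(7, 6), c(8, 9))
  long <- data.frame(y = as.vector(ratings),
                     subj = factor(rep(1:6, 2)),
                     rater = factor(rep(1:2, each = 6)))
  ms <- summary(aov(y ~ subj + rater, data = long))[[1]]
  msr <- ms["subj", "Mean Sq"]; msc <- ms["rater", "Mean Sq"]
  mse <- ms["Residuals", "Mean Sq"]
  n <- 6; k <- 2
  icc2 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  icc3 <- (msr - mse) / (msr + (k - 1) * mse)
  expect_equal(iccAgreement(ratings), icc2, tolerance = 1e-10)
  expect_equal(iccAgreement(ratings, "ICC3"), icc3, tolerance = 1e-10)
  expect_equal(iccAgreement(cbind(1:8, 1:8, 1:8)), 1)
  set.seed(10)
  noise <- matrix(rnorm(400), 200, 2)
  expect_lt(abs(iccAgreement(noise)), 0.15)
  expect_error(iccAgreement(cbind(c(1, NA, 3), 1:3)), "missing|subjects")
})

test_that("split-plot ANOVA detects effects and respects invariances", {
  mkData <- function(nPerG, gShift = 0, lShift = 0, sd = 2, seed = 1) {
    set.seed(seed)
    levels <- c("L1/L2", "L2/L3", "L3/L4", "L4/L5")
    d <- expand.grid(subject_id = seq_len(2 * nPerG), level = levels)
    d$gender <- ifelse(d$subject_id <= nPerG, "F", "M")
    d$ratio_percent <- 38 + rnorm(nrow(d), 0, sd) +
      ifelse(d$gender == "M", gShift, 0) +
      lShift * as.integer(factor(d$level))
    d
  }
  d <- mkData(10, gShift = 5, seed = 31)
  a <- splitPlotAnova(d)
  expect_equal(a$effect, c("gender", "level", "gender:level"))
  expect_lt(a$p[a$effect == "gender"], 0.001)
  # adding a constant leaves every F unchanged
  d2 <- d; d2$ratio_percent <- d2$ratio_percent + 100
  expect_equal(splitPlotAnova(d2)$F, a$F, tolerance = 1e-9)
  # within-subject level effect is detected
  dl <- mkData(10, lShift = 2, seed = 32)
  expect_lt(splitPlotAnova(dl)$p[2], 0.001)
  # incomplete within-subject data falls back to the mixed model
  dInc <- d[-c(1, 45), ]
  aInc <- splitPlotAnova(dInc)
  expect_equal(nrow(aInc), 3)
  expect_true(all(is.finite(aInc$F)))
  dBad <- d[!(d$gender == "M" & d$level == "L1/L2") | d$subject_id == 11, ]
  expect_error(splitPlotAnova(dBad), "cells")
})

test_that("gender shifts are detected with high power", {
  hits <- 0L
  for (s in 1:40) {
    levels <- c("L1/L2", "L2/L3", "L3/L4", "L4/L5")
    set.seed(400 + s)
    d <- expand.grid(subject_id = 1:60, level = levels)
    d$gender <- ifelse(d$subject_id <= 30, "F", "M")
    d$ratio_percent <- 38 + rnorm(nrow(d), 0, 2) +
      ifelse(d$gender == "M", 5, 0)
    if (splitPlotAnova(d)$p[1] < 0.001) hits <- hits + 1L
  }
  expect_gte(hits / 40, 0.95)
})

test_that("Tukey HSD matches the two-sample t test for two groups", {
  set.seed(12)
  v <- c(rnorm(10, 40, 3), rnorm(10, 42, 3))
  g <- rep(c("a", "b"), each = 10)
  tk <- tukeyHsd(v, g)
  tt <- t.test(v ~ g, var.equal = TRUE)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-8)
  expect_error(tukeyHsd(c(1, 2, 3), c("a", "a", "b")), "at least 2")
})

test_that("Tukey HSD flags only genuinely shifted groups", {
  flagged <- matrix(0, 30, 3)
  for (s in 1:30) {
    set.seed(600 + s)
    v <- c(rnorm(12, 38, 2), rnorm(12, 38, 2), rnorm(12, 44, 2))
    g <- rep(c("g1", "g2", "g3"), each = 12)
    tk <- tukeyHsd(v, g)
    flagged[s, ] <- tk$p_adj < 0.05
  }
  pairs <- c("g2-g1", "g3-g1", "g3-g2")
  shifted <- pairs %in% c("g3-g1", "g3-g2")
  expect_gte(mean(rowSums(flagged[, shifted]) == 2), 0.9)
  expect_lte(mean(flagged[, !shifted]), 0.1)
  # identical groups: nothing significant
  set.seed(14)
  v0 <- rnorm(30, 40, 2); g0 <- rep(c("a", "b", "c"), each = 10)
  expect_true(all(tukeyHsd(v0, g0)$p_adj > 0.05))
})
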