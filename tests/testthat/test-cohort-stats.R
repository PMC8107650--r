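# Cohort statistics: paired t, ROC/AUC, DeLong, Pearson, logistic fit and
# balanced sub-sampling. pROC serves as the independent cross-check for the
# ROC quantities.

test_that("paired t-test matches the textbook formula and handles degeneracy", {
  set.seed(41)
  x <- rnorm(20, 3, 0.5); y <- x + rnorm(20, 0.2, 0.3)
  r <- pairedTTest(x, y)
  d <- x - y
  tOracle <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(r$t, tOracle, tolerance = 1e-12)
  expect_equal(r$pValue, 2 * pt(-abs(tOracle), length(d) - 1),
               tolerance = 1e-12)
  expect_equal(r$df, 19)
  same <- pairedTTest(x, x)
  expect_equal(same$t, 0); expect_equal(same$pValue, 1)
  shifted <- pairedTTest(x + 1, x)
  expect_true(is.infinite(shifted$t))
  expect_equal(shifted$pValue, 0)
  expect_error(pairedTTest(1, 1:2), "paired")
})

test_that("ROC analysis: separated, tied and oracle-checked cases", {
  sep <- rocAnalysis(c(1, 2, 3, 11, 12, 13), c(F, F, F, T, T, T))
  expect_equal(sep$auc, 1)
  tied <- rocAnalysis(rep(5, 8), c(T, F, T, F, T, F, T, F))
  expect_equal(tied$auc, 0.5)
  # pair-count oracle on a 6-subject toy with a tie across classes
  sc <- c(1, 3, 3, 2, 5, 4); lb <- c(F, F, T, F, T, T)
  r <- rocAnalysis(sc, lb)
  expect_equal(r$auc, pairCountAuc(sc, lb), tolerance = 1e-12)
  # monotone sweep
  expect_true(all(diff(r$sensitivity) <= 1e-12))
  expect_true(all(diff(r$specificity) >= -1e-12))
  expect_error(rocAnalysis(1:4, c(T, T, T, T)), "both classes")
})

test_that("operating point matches direct confusion-matrix arithmetic", {
  inc <- c(10, 24, 25, 26, 40, -5, 30, 25)
  lab <- c(T, T, T, T, T, F, F, F)
  op <- rocAnalysis(inc, lab, threshold = 25)$operating
  # strict rule: positives 26,40 among labels T -> 2 TP; 30 among F -> 1 FP
  expect_equal(op$sensitivity, 2 / 5)
  expect_equal(op$specificity, 2 / 3)
  expect_equal(op$accuracy, 4 / 8)
  expect_equal(op$precision, 2 / 3)
})

test_that("trapezoid AUC equals pair counting on random instances", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(8:20, 1)
    lb <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    sc <- sample(1:6, n, replace = TRUE) + ifelse(lb, runif(1, 0, 2), 0)
    expect_equal(rocAnalysis(sc, lb)$auc, pairCountAuc(sc, lb),
                 tolerance = 1e-12)
  }
})

test_that("AUC and DeLong agree with pROC as independent cross-check", {
  skip_if_not_installed("pROC")
  set.seed(43)
  n <- 40
  lb <- runif(n) > 0.45
  s1 <- rnorm(n) + 1.2 * lb
  s2 <- rnorm(n) + 0.8 * lb
  ours <- delongTest(s1, s2, lb)
  expect_equal(rocAnalysis(s1, lb)$auc,
               as.numeric(pROC::auc(pROC::roc(lb, s1, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
  ref <- pROC::roc.test(pROC::roc(lb, s1, quiet = TRUE, direction = "<"),
                        pROC::roc(lb, s2, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(ours$pValue, ref$p.value, tolerance = 1e-9)
  # variance of a single AUC also matches pROC's DeLong variance
  expect_equal(rocAnalysis(s1, lb)$aucVariance,
               pROC::var(pROC::roc(lb, s1, quiet = TRUE, direction = "<"),
                         method = "delong"),
               tolerance = 1e-9)
})

test_that("DeLong test is symmetric and p = 1 for identical scores", {
  set.seed(44)
  lb <- c(rep(TRUE, 12), rep(FALSE, 10))
  s1 <- rnorm(22) + lb
  s2 <- rnorm(22) + 0.5 * lb
  same <- delongTest(s1, s1, lb)
  expect_equal(same$pValue, 1)
  expect_equal(same$aucDiff, 0)
  ab <- delongTest(s1, s2, lb)
  ba <- delongTest(s2, s1, lb)
  expect_equal(ab$pValue, ba$pValue, tolerance = 1e-12)
  expect_equal(ab$aucDiff, -ba$aucDiff, tolerance = 1e-12)
})

test_that("DeLong variance on a 5-subject toy matches hand-computed placements", {
  # positives score {4, 2, 5}, negatives {3, 1}
  sc1 <- c(4, 3, 2, 1, 5); sc2 <- c(2, 3, 4, 1, 5)
  lb <- c(TRUE, FALSE, TRUE, FALSE, TRUE)
  # by hand, scores1: V10 = (1, 0.5, 1)  [4 beats both; 2 beats only 1; 5 both]
  #                   V01 = (1/3, 1)     [3 beaten by 4,5 of 3 -> 1-2/3; 1 by all]
  # wait: V01_j = fraction of positives that beat negative j
  # neg 3: beaten by 4 and 5 (not 2) -> 2/3; neg 1: beaten by all -> 1
  v10a <- c(1, 0.5, 1); v01a <- c(2/3, 1)
  # scores2: positives {2, 4, 5}, negatives {3, 1}
  v10b <- c(0.5, 1, 1); v01b <- c(2/3, 1)
  aucA <- mean(c(1, 0.5, 1))   # 5/6
  vd <- (var(cbind(v10a, v10b))[1, 1] + var(cbind(v10a, v10b))[2, 2] -
           2 * var(cbind(v10a, v10b))[1, 2]) / 3 +
        (var(cbind(v01a, v01b))[1, 1] + var(cbind(v01a, v01b))[2, 2] -
           2 * var(cbind(v01a, v01b))[1, 2]) / 2
  r <- delongTest(sc1, sc2, lb)
  expect_equal(r$auc1, aucA, tolerance = 1e-12)
  expect_equal(r$variance, vd, tolerance = 1e-12)
})

test_that("Pearson correlation matches its formula and flags constants", {
  x <- c(35, 42, 48, 51, 55, 58, 61, 44, 39, 63)
  y <- 2 * x + 1
  expect_equal(pearsonCorrelation(x, y)$r, 1, tolerance = 1e-12)
  set.seed(45)
  y2 <- rnorm(10, 50, 20)
  r <- pearsonCorrelation(x, y2)
  rOracle <- sum((x - mean(x)) * (y2 - mean(y2))) /
    sqrt(sum((x - mean(x))^2) * sum((y2 - mean(y2))^2))
  tOracle <- rOracle * sqrt(8 / (1 - rOracle^2))
  expect_equal(r$r, rOracle, tolerance = 1e-12)
  expect_equal(r$pValue, 2 * pt(-abs(tOracle), 8), tolerance = 1e-12)
  expect_error(pearsonCorrelation(rep(1, 5), 1:5), "constant")
})

test_that("logistic fit finds the symmetric threshold and flags degeneracies", {
  # symmetric design around TBR = 3 with overlap: threshold must be 3
  offs <- rep(c(1.5, 1.0, 0.6, 0.3, 0.1, -0.2), 4)
  tbr <- c(3 - offs, 3 + offs)
  lab <- c(rep(FALSE, length(offs)), rep(TRUE, length(offs)))
  f <- logisticFit(tbr, lab)
  expect_true(f$converged)
  expect_equal(f$classificationThreshold, 3, tolerance = 1e-6)
  # labels independent of tbr: no threshold reported
  set.seed(46)
  f0 <- logisticFit(rnorm(60, 3), rep(c(TRUE, FALSE), 30))
  expect_true(is.na(f0$classificationThreshold))
  # perfect separation is flagged, not silently estimated
  fs <- logisticFit(c(1, 1.2, 1.4, 5, 5.2, 5.4),
                    c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_true(fs$separated)
  expect_false(fs$converged)
  expect_error(logisticFit(1:5, rep(TRUE, 5)), "both classes")
})

test_that("logistic fit recovers simulated parameters", {
  set.seed(47)
  ok <- 0
  for (i in 1:10) {
    tbr <- runif(2000, 1, 6)
    p <- plogis(-8 + 2.5 * tbr)
    lab <- runif(2000) < p
    f <- logisticFit(tbr, lab)
    if (abs(f$intercept + 8) < 3 * f$se[["intercept"]] &&
        abs(f$slope - 2.5) < 3 * f$se[["slope"]]) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("balanced sub-sampling equalises classes deterministically", {
  rec <- data.frame(id = 1:72, label = c(rep(TRUE, 61), rep(FALSE, 11)))
  b <- balancedSubsample(rec, seed = 3L)
  expect_equal(sum(b$label), 11)
  expect_equal(sum(!b$label), 11)
  expect_identical(b, balancedSubsample(rec, seed = 3L))
  even <- data.frame(id = 1:10, label = rep(c(TRUE, FALSE), 5))
  expect_identical(balancedSubsample(even, 1L), even)
  expect_error(balancedSubsample(data.frame(label = rep(TRUE, 3)), 1L),
               "both classes")
})
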