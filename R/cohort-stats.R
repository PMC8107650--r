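# Cohort-level statistics: paired t-test, ROC with AUC and DeLong comparison,
# Pearson correlation, logistic regression with the TBR classification
# threshold, and balanced sub-sampling. All tests are two-sided at 95% CL.

#' Paired t-test between two algorithms' per-subject values
#'
#' Classical paired t on the per-subject differences (via stats::t.test).
#' Degenerate inputs are handled explicitly: all differences zero gives
#' t = 0, p = 1; constant nonzero differences give an infinite t and p = 0.
#'
#' @param x,y per-subject values, paired by position.
#' @return list with t, df, pValue, meanDiff
#' @export
pairedTTest <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("x and y must be paired vectors of length >= 2")
  d <- x - y
  n <- length(d)
  # constant differences (to rounding): zero-variance degenerate cases
  if (stats::sd(d) <= 1e-10 * (abs(mean(d)) + max(abs(d)) * 1e-6)) {
    if (abs(mean(d)) <= .Machine$double.eps * max(abs(x), 1))
      return(list(t = 0, df = n - 1L, pValue = 1, meanDiff = 0))
    return(list(t = sign(mean(d)) * Inf, df = n - 1L, pValue = 0,
                meanDiff = mean(d)))
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       pValue = ht$p.value, meanDiff = unname(ht$estimate))
}

# Mann-Whitney placement values: for each positive score, the fraction of
# negatives it beats (ties count 1/2), and vice versa. AUC is their mean.
delongPlacements <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp), v01 = 1 - colMeans(cmp), auc = mean(cmp))
}

#' ROC analysis with operating-point summary
#'
#' Sweeps all distinct score cutoffs (positivity: score strictly above the
#' cutoff), computes sensitivity/specificity per cutoff and the AUC by the
#' trapezoidal rule — which equals the Mann-Whitney pair-count AUC with ties
#' counted one half. The operating point reports sensitivity, specificity,
#' accuracy and precision at the classification threshold using the strict
#' rule of [classifyUptake()]. The AUC variance is the single-curve DeLong
#' structural-components estimate.
#'
#' @param scores per-subject scores (e.g. percent uptake increase).
#' @param labels logical true labels; both classes must be present.
#' @param threshold operating-point threshold (default 25).
#' @return list of class "rocResult": thresholds, sensitivity, specificity
#'   (per cutoff), auc, aucVariance, and the operating point summary.
#' @export
rocAnalysis <- function(scores, labels, threshold = 25) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores and labels must align")
  if (all(labels) || !any(labels))
    stop("both classes must be present for an ROC analysis")
  nPos <- sum(labels); nNeg <- sum(!labels)
  cuts <- c(-Inf, sort(unique(scores)))
  sens <- vapply(cuts, function(c) sum(scores > c & labels) / nPos, numeric(1))
  spec <- vapply(cuts, function(c) sum(scores <= c & !labels) / nNeg, numeric(1))
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(ord)]) / 2)
  pl <- delongPlacements(scores, labels)
  aucVar <- stats::var(pl$v10) / nPos + stats::var(pl$v01) / nNeg
  pred <- classifyUptake(scores, threshold)
  tp <- sum(pred & labels); fp <- sum(pred & !labels)
  tn <- sum(!pred & !labels); fn <- sum(!pred & labels)
  structure(list(
    thresholds = cuts, sensitivity = sens, specificity = spec,
    auc = auc, aucVariance = aucVar,
    operating = list(threshold = threshold,
                     sensitivity = tp / nPos, specificity = tn / nNeg,
                     accuracy = (tp + tn) / length(labels),
                     precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_)),
    class = "rocResult")
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors measured on the same subjects,
#' using DeLong's structural components to estimate the variance of the AUC
#' difference (accounting for the correlation between the curves), and a
#' two-sided z-test.
#'
#' @param scores1,scores2 per-subject scores from the two algorithms.
#' @param labels logical true labels shared by both.
#' @return list with auc1, auc2, aucDiff, variance, z, pValue, degenerate
#'   (TRUE when the variance estimate is zero with a nonzero difference)
#' @export
delongTest <- function(scores1, scores2, labels) {
  labels <- as.logical(labels)
  if (length(scores1) != length(labels) || length(scores2) != length(labels))
    stop("scores and labels must align")
  if (all(labels) || !any(labels)) stop("both classes must be present")
  p1 <- delongPlacements(scores1, labels)
  p2 <- delongPlacements(scores2, labels)
  nPos <- sum(labels); nNeg <- sum(!labels)
  s10 <- stats::cov(cbind(p1$v10, p2$v10))
  s01 <- stats::cov(cbind(p1$v01, p2$v01))
  vd <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / nPos +
        (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / nNeg
  diffA <- p1$auc - p2$auc
  if (vd <= 0) {
    if (abs(diffA) < 1e-12)
      return(list(auc1 = p1$auc, auc2 = p2$auc, aucDiff = 0, variance = 0,
                  z = 0, pValue = 1, degenerate = FALSE))
    return(list(auc1 = p1$auc, auc2 = p2$auc, aucDiff = diffA, variance = 0,
                z = NA_real_, pValue = NA_real_, degenerate = TRUE))
  }
  z <- diffA / sqrt(vd)
  list(auc1 = p1$auc, auc2 = p2$auc, aucDiff = diffA, variance = vd,
       z = z, pValue = 2 * stats::pnorm(-abs(z)), degenerate = FALSE)
}

#' Pearson correlation with significance
#'
#' Correlation between aneurysm diameter and uptake increase (or any paired
#' quantities), with the two-sided p-value from t = r sqrt((n-2)/(1-r^2)).
#'
#' @param x,y paired numeric vectors, n >= 3, each with nonzero variance.
#' @return list with r, pValue, n
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must be paired vectors of length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), pValue = ht$p.value, n = length(x))
}

#' Logistic regression of positivity on TBRmax
#'
#' Maximum-likelihood fit of logit P(positive) = beta0 + beta1 * TBR via
#' stats::glm (iteratively reweighted least squares), reporting Wald standard
#' errors and p-values, the residual deviance, the in-sample accuracy at
#' probability 0.5, and the TBR classification threshold -beta0/beta1 (the
#' probability-0.5 crossing). Perfect separation (or non-convergence) is
#' flagged and the threshold withheld rather than silently reported.
#'
#' @param tbr per-subject TBRmax values.
#' @param labels logical positivity labels; both classes must be present.
#' @return list of class "logisticFit": intercept, slope, se, pValues,
#'   residualDeviance, accuracy, classificationThreshold, converged, separated
#' @export
logisticFit <- function(tbr, labels) {
  labels <- as.logical(labels)
  if (length(tbr) != length(labels)) stop("tbr and labels must align")
  if (all(labels) || !any(labels)) stop("both classes must be present")
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(labels ~ tbr, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- summary(fit)$coefficients
  # glm does not always warn on perfect separation: detect saturated fits
  if (all(abs(stats::fitted(fit) - labels) < 1e-6)) separated <- TRUE
  converged <- fit$converged && !separated
  beta0 <- cf[1, 1]; beta1 <- cf[2, 1]
  # threshold only meaningful when the slope is informative (Wald 95% CL)
  slopeInformative <- converged && cf[2, 4] < 0.05 && abs(beta1) > 1e-8
  thr <- if (slopeInformative) -beta0 / beta1 else NA_real_
  pred <- stats::fitted(fit) > 0.5
  structure(list(
    intercept = beta0, slope = beta1,
    se = c(intercept = cf[1, 2], slope = cf[2, 2]),
    pValues = c(intercept = cf[1, 4], slope = cf[2, 4]),
    residualDeviance = fit$deviance,
    accuracy = mean(pred == labels),
    classificationThreshold = thr,
    converged = converged, separated = separated),
    class = "logisticFit")
}

#' Balanced sub-sampling of a cohort
#'
#' Down-samples the majority class to the minority class size, so the two
#' classes have the same number of cases. Deterministic given the seed; a
#' cohort that is already balanced is returned unchanged.
#'
#' @param records data.frame with a logical \code{label} column.
#' @param seed RNG seed.
#' @return the sub-sampled data.frame (original row order preserved)
#' @export
balancedSubsample <- function(records, seed = 1L) {
  stopifnot(is.data.frame(records), "label" %in% names(records))
  lab <- as.logical(records$label)
  if (all(lab) || !any(lab)) stop("both classes must be present")
  nPos <- sum(lab); nNeg <- sum(!lab)
  if (nPos == nNeg) return(records)
  majority <- which(lab == (nPos > nNeg))
  keepN <- min(nPos, nNeg)
  keep <- withSeed(seed, sort(sample(majority, keepN)))
  records[sort(c(which(lab != (nPos > nNeg)), keep)), , drop = FALSE]
}
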