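# ROI quantification: TBR_max, percentage uptake increase, the 25% EORTC
# classification rule, coefficient of variation, iteration selection and the
# kernel-parameter sweep selection rule.

maskValues <- function(image, mask) {
  if (!identical(dim(image@values), dim(mask)))
    stop("mask geometry does not match the image")
  if (!any(mask)) stop("ROI mask is empty")
  image@values[mask]
}

#' Maximum target-to-blood-pool ratio
#'
#' TBRmax(T) = max over the target mask divided by the mean over the blood
#' pool mask. The ratio is invariant to any positive rescaling of the image,
#' so SUV conversion does not change it (see [suvScale()]).
#'
#' @param image a VoxelImage.
#' @param roiT logical target mask.
#' @param roiB logical blood-pool mask.
#' @return unitless ratio
#' @export
tbrMax <- function(image, roiT, roiB) {
  tv <- maskValues(image, roiT)
  bv <- maskValues(image, roiB)
  mb <- mean(bv)
  if (mb <= 0) stop("blood-pool mean must be positive")
  max(tv) / mb
}

#' Percentage uptake increase between aneurysm and normal aorta
#'
#' 100 * (TBRmax(T) - TBRmax(A)) / TBRmax(A).
#'
#' @param tbrT,tbrA unitless TBR values; \code{tbrA} must be positive.
#' @return percent
#' @export
uptakeIncrease <- function(tbrT, tbrA) {
  if (any(tbrA <= 0)) stop("TBRmax(A) must be positive")
  100 * (tbrT - tbrA) / tbrA
}

#' EORTC-style uptake classification
#'
#' A subject is called positive when the uptake increase is strictly higher
#' than the threshold (default 25%).
#'
#' @param increase percent uptake increase.
#' @param threshold percent (default 25).
#' @return logical
#' @export
classifyUptake <- function(increase, threshold = 25) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  increase > threshold
}

#' Coefficient of variation over a mask
#'
#' Population standard deviation (denominator n) over the mask divided by the
#' mask mean. Used as the noise surrogate when selecting kernel parameters and
#' matching iterations across algorithms.
#'
#' @param image a VoxelImage.
#' @param mask logical mask.
#' @return unitless CoV
#' @export
roiCov <- function(image, mask) {
  v <- maskValues(image, mask)
  m <- mean(v)
  if (m <= 0) stop("mask mean must be positive for a CoV")
  sqrt(mean((v - m)^2)) / m
}

#' Optional SUV scaling
#'
#' Linear conversion of activity to standardised uptake values
#' (value * weight / dose). TBR is a ratio, so this never changes TBR-based
#' results; it is provided for interface completeness.
#'
#' @param image a VoxelImage.
#' @param dose injected dose (e.g. MBq); @param weightKg subject weight (kg).
#' @return the scaled VoxelImage
#' @export
suvScale <- function(image, dose, weightKg) {
  if (dose <= 0 || weightKg <= 0) stop("dose and weight must be positive")
  voxelImage(image@values * weightKg / dose, image@spacing)
}

#' Select the comparison iteration by true-positive count
#'
#' Given per-subject records over several stored iterations, returns the
#' iteration with the highest number of true positives (predicted positive
#' and truly positive); ties go to the earliest iteration.
#'
#' @param records data.frame with columns \code{iteration},
#'   \code{predicted} (logical) and \code{label} (logical).
#' @return the selected iteration index
#' @export
selectIteration <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("records must be a nonempty data.frame")
  stopifnot(all(c("iteration", "predicted", "label") %in% names(records)))
  its <- sort(unique(records$iteration))
  tp <- vapply(its, function(i) {
    r <- records[records$iteration == i, ]
    sum(r$predicted & r$label)
  }, numeric(1))
  its[which.max(tp)]   # which.max returns the earliest maximum
}

#' Select kernel parameters at fixed noise level
#'
#' Implements the sweep selection rule: among parameter candidates whose CoV
#' lies within a relative tolerance band of the reference CoV, return the one
#' with the highest TBRmax; ties go to the earliest candidate in the input.
#'
#' @param sweep data.frame with one row per candidate, columns \code{tbr} and
#'   \code{cov}, plus any parameter columns.
#' @param refCov reference CoV level defining the band centre.
#' @param covTolerance relative half-width of the band (default 0.1).
#' @return the selected row of \code{sweep}
#' @export
selectKernelParams <- function(sweep, refCov, covTolerance = 0.1) {
  if (!is.data.frame(sweep) || nrow(sweep) == 0L)
    stop("sweep must be a nonempty data.frame")
  stopifnot(all(c("tbr", "cov") %in% names(sweep)))
  inBand <- abs(sweep$cov - refCov) <= covTolerance * refCov
  if (!any(inBand)) {
    nearest <- order(abs(sweep$cov - refCov))[seq_len(min(3L, nrow(sweep)))]
    stop(sprintf(
      "no candidate within %.0f%% of CoV %.4g; nearest CoV values: %s",
      100 * covTolerance, refCov,
      paste(signif(sweep$cov[nearest], 4), collapse = ", ")))
  }
  cand <- which(inBand)
  cand[which.max(sweep$tbr[cand])]
  sweep[cand[which.max(sweep$tbr[cand])], , drop = FALSE]
}

#' Quantify one reconstructed image against a subject's ROIs
#'
#' Computes TBRmax(T), TBRmax(A), the percentage increase, the classification
#' at the threshold and the blood-pool CoV.
#'
#' @param image reconstructed VoxelImage.
#' @param rois a RoiSet.
#' @param threshold classification threshold in percent (default 25).
#' @param covRegion region for the CoV: "blood" (default) or "aorta".
#' @return one-row data.frame with columns tbrT, tbrA, increase, predicted, cov
#' @export
subjectMetrics <- function(image, rois, threshold = 25,
                           covRegion = c("blood", "aorta")) {
  covRegion <- match.arg(covRegion)
  tT <- tbrMax(image, rois@target, rois@blood)
  tA <- tbrMax(image, rois@aorta, rois@blood)
  inc <- uptakeIncrease(tT, tA)
  covMask <- if (covRegion == "blood") rois@blood else rois@aorta
  data.frame(tbrT = tT, tbrA = tA, increase = inc,
             predicted = classifyUptake(inc, threshold),
             cov = roiCov(image, covMask))
}
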