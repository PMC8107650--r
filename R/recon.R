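# Iterative reconstruction: ordered-subsets EM on kernel coefficients.
# With the identity kernel this is plain MLEM/OSEM; with the anatomical
# kernel it is KEM; with the anatomical x functional product rebuilt from the
# current iterate it is HKEM.

#' Reconstruction configuration
#'
#' @param algorithm "osem", "kem" or "hkem".
#' @param nSubsets ordered subsets per full iteration (default 21).
#' @param nIterations full iterations (default 10).
#' @param kernel a [kernelParams()] list (kem/hkem only).
#' @param postFilterFwhm Gaussian post-filter FWHM in mm applied to every
#'   stored OSEM image (default 5; ignored for kem/hkem).
#' @param epsilon small positive stabiliser added to ratio denominators.
#' @return a list of class "reconConfig"
#' @export
reconConfig <- function(algorithm = c("osem", "kem", "hkem"),
                        nSubsets = 21L, nIterations = 10L,
                        kernel = kernelParams(),
                        postFilterFwhm = 5, epsilon = 1e-10) {
  algorithm <- match.arg(algorithm)
  if (nSubsets < 1L) stop("nSubsets must be >= 1")
  if (nIterations < 1L) stop("nIterations must be >= 1")
  if (epsilon <= 0) stop("epsilon must be positive")
  if (postFilterFwhm < 0) stop("postFilterFwhm must be >= 0")
  structure(list(algorithm = algorithm, nSubsets = as.integer(nSubsets),
                 nIterations = as.integer(nIterations), kernel = kernel,
                 postFilterFwhm = postFilterFwhm, epsilon = epsilon),
            class = "reconConfig")
}

#' Gaussian post-reconstruction filter
#'
#' Isotropic Gaussian convolution with reflective boundaries, which preserves
#' the total image sum exactly. \code{fwhmMm = 0} returns the input unchanged.
#'
#' @param image a VoxelImage.
#' @param fwhmMm filter FWHM in mm.
#' @return the filtered VoxelImage
#' @export
gaussianPostFilter <- function(image, fwhmMm) {
  if (fwhmMm < 0) stop("filter FWHM must be >= 0")
  if (fwhmMm == 0) return(image)
  d <- dim(image@values)
  sigmaVox <- fwhmToSigma(fwhmMm) / image@spacing
  B1 <- convolutionMatrix1d(d[1], sigmaVox[1], "reflect")
  B2 <- convolutionMatrix1d(d[2], sigmaVox[2], "reflect")
  voxelImage(blurValues(image@values, B1, B2), image@spacing)
}

# One multiplicative EM update of the coefficient vector on one subset.
# alphaVec, numerator/sensitivity as plain vectors; kmat NULL = identity.
emUpdateVec <- function(alphaVec, kmat, yRows, sRows, model, rows, sensVec,
                        epsilon) {
  lambda <- if (is.null(kmat)) alphaVec else as.numeric(kmat %*% alphaVec)
  ybar <- projectVec(model, lambda, rows) + sRows
  ratio <- yRows / pmax(ybar, epsilon)
  bp <- backprojectVec(model, ratio, rows)
  num <- if (is.null(kmat)) bp else as.numeric(Matrix::crossprod(kmat, bp))
  upd <- alphaVec * num / pmax(sensVec, epsilon)
  upd[sensVec <= 0] <- alphaVec[sensVec <= 0]   # zero-sensitivity voxels frozen
  pmax(upd, 0)
}

#' One kernelized EM update
#'
#' Applies the multiplicative EM update for the kernel coefficients,
#' \code{alpha <- alpha * (K' P' (y / (P K alpha + s))) / (K' P' 1)},
#' restricted to the given subset. Voxels with zero sensitivity are frozen at
#' their current value rather than raising an error.
#'
#' @param alpha VoxelImage of current coefficients (nonnegative).
#' @param kernel a KernelModel, or NULL for the identity kernel.
#' @param data Sinogram of measured counts (all angles).
#' @param model a SystemModel.
#' @param additive Sinogram of expected additive counts, or NULL.
#' @param subset subset index, or NULL for all angles (MLEM).
#' @param epsilon denominator stabiliser.
#' @return the updated VoxelImage of coefficients
#' @export
emUpdate <- function(alpha, kernel, data, model, additive = NULL,
                     subset = NULL, epsilon = 1e-10) {
  checkImageGeometry(alpha, model)
  if (any(alpha@values < 0)) stop("alpha must be nonnegative")
  rows <- if (is.null(subset)) NULL else subsetRows(model, subset)
  yAll <- as.vector(t(data@values))
  sAll <- if (is.null(additive)) rep(0, length(yAll)) else as.vector(t(additive@values))
  yRows <- if (is.null(rows)) yAll else yAll[rows]
  sRows <- if (is.null(rows)) sAll else sAll[rows]
  kmat <- if (is.null(kernel)) NULL else kernel@kmat
  ones <- rep(1, length(yRows))
  sens <- backprojectVec(model, ones, rows)
  if (!is.null(kmat)) sens <- as.numeric(Matrix::crossprod(kmat, sens))
  v <- emUpdateVec(as.vector(alpha@values), kmat, yRows, sRows, model, rows,
                   sens, epsilon)
  voxelImage(matrix(v, model@imageDim[1], model@imageDim[2]), alpha@spacing)
}

# Poisson log-likelihood up to the data-dependent constant sum(lfactorial(y)).
poissonLogLik <- function(y, ybar, epsilon = 1e-10) {
  sum(y * log(pmax(ybar, epsilon)) - ybar)
}

#' Iterative reconstruction (OSEM, KEM or HKEM)
#'
#' Runs ordered-subsets EM with the algorithm-specific kernel:
#' \describe{
#'   \item{osem}{identity kernel; every stored image is smoothed with the
#'     Gaussian post-filter (the clinical "OSEM+G").}
#'   \item{kem}{static anatomical kernel K_m built once from the guidance
#'     image.}
#'   \item{hkem}{hybrid kernel K^(n) = K_m * K_p^(n), with the functional
#'     factor rebuilt from the current coefficient iterate before every subset
#'     update (or once per full iteration, per the kernel parameters).}
#' }
#' Coefficients are initialised to 1 everywhere; the activity image
#' lambda^(n) = K^(n) alpha^(n) is stored after every full iteration, together
#' with the Poisson log-likelihood of the full data.
#'
#' @param data Sinogram of measured counts.
#' @param model a SystemModel (its subset partition is replaced by
#'   \code{config$nSubsets}).
#' @param additive Sinogram of expected additive counts, or NULL.
#' @param anatomical VoxelImage guidance image (required for kem/hkem).
#' @param config a [reconConfig()] list.
#' @return a ReconResult
#' @export
reconstruct <- function(data, model, additive = NULL, anatomical = NULL,
                        config = reconConfig()) {
  stopifnot(inherits(config, "reconConfig"))
  alg <- config$algorithm
  if (alg %in% c("kem", "hkem") && is.null(anatomical))
    stop(sprintf("an anatomical guidance image is required for %s", alg))
  model <- makeSubsets(model, config$nSubsets)
  nVox <- prod(model@imageDim)
  eps <- config$epsilon
  yAll <- as.vector(t(data@values))
  sAll <- if (is.null(additive)) rep(0, length(yAll)) else as.vector(t(additive@values))
  km <- switch(alg,
               osem = NULL,
               kem = buildAnatomicalKernel(anatomical, config$kernel),
               hkem = buildAnatomicalKernel(anatomical, config$kernel))
  hybrid <- alg == "hkem"
  perSubsetKp <- hybrid && config$kernel$updateKernel == "subset"
  nS <- length(model@subsets)
  rowsList <- lapply(seq_len(nS), function(s) subsetRows(model, s))
  # kernel-independent part of the sensitivity, per subset
  bs <- lapply(rowsList, function(r) backprojectVec(model, rep(1, length(r)), r))
  alpha <- rep(1, nVox)
  alphaImg <- function(v) voxelImage(matrix(v, model@imageDim[1], model@imageDim[2]),
                                     model@spacing)
  currentKernel <- function(a) {
    if (!hybrid) return(km)
    kp <- buildFunctionalKernel(alphaImg(a), config$kernel, km)
    composeHybrid(km, kp, normalizeRows = config$kernel$normalizeRows)
  }
  K <- if (hybrid) currentKernel(alpha) else km
  images <- vector("list", config$nIterations)
  ll <- numeric(config$nIterations)
  for (it in seq_len(config$nIterations)) {
    if (hybrid && !perSubsetKp) K <- currentKernel(alpha)
    for (s in seq_len(nS)) {
      if (perSubsetKp) K <- currentKernel(alpha)
      rows <- rowsList[[s]]
      kmat <- if (is.null(K)) NULL else K@kmat
      sens <- if (is.null(kmat)) bs[[s]]
              else as.numeric(Matrix::crossprod(kmat, bs[[s]]))
      alpha <- emUpdateVec(alpha, kmat, yAll[rows], sAll[rows], model, rows,
                           sens, eps)
    }
    if (hybrid) K <- currentKernel(alpha)   # lambda^(n) uses the current iterate
    lambda <- if (is.null(K)) alpha else as.numeric(K@kmat %*% alpha)
    img <- alphaImg(lambda)
    if (alg == "osem" && config$postFilterFwhm > 0)
      img <- gaussianPostFilter(img, config$postFilterFwhm)
    images[[it]] <- img
    ll[it] <- poissonLogLik(yAll, projectVec(model, lambda) + sAll, eps)
  }
  new("ReconResult", images = images, alpha = alpha, logLik = ll,
      algorithm = alg, config = unclass(config))
}
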