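# Kernelized image model: lambda = K alpha, with K built from k-nearest
# neighbour Gaussian weights on patch features of a guidance image (anatomical
# kernel), of the current iterate (functional kernel), or their product
# (hybrid kernel).

#' Kernel parameters
#'
#' Parameters of the neighbourhood kernel: the number of neighbours per voxel,
#' the patch radius of the feature vectors, the intensity scales of the
#' anatomical (\code{sigmaM}) and functional (\code{sigmaP}) Gaussians, and
#' the spatial distance scales (\code{sigmaDm}, \code{sigmaDp}, voxel units).
#' Feature intensities are normalised by the source image's standard deviation
#' before the Gaussian, so the intensity scales are comparable across images.
#'
#' Neighbours are searched in the spatial window of half-width
#' \code{patchRadius}; the \code{nNeighbors} candidates closest in feature
#' space are kept (the voxel itself always first, remaining ties broken by
#' voxel index).
#'
#' @param nNeighbors neighbours per voxel (default 3).
#' @param patchRadius feature patch (and search window) half-width in voxels.
#' @param sigmaM,sigmaP intensity Gaussian scales (default 0.1).
#' @param sigmaDm,sigmaDp spatial Gaussian scales in voxels (default 3).
#' @param normalizeRows scale each kernel row to sum to 1 (default TRUE),
#'   which makes the kernel count-preserving on constant images.
#' @param hybrid use the hybrid (anatomical x functional) kernel (default
#'   TRUE for HKEM; ignored elsewhere).
#' @param updateKernel when hybrid: rebuild the functional kernel before every
#'   \code{"subset"} update (default) or once per full \code{"iteration"}.
#' @return a list of class "kernelParams"
#' @export
kernelParams <- function(nNeighbors = 3L, patchRadius = 1L,
                         sigmaM = 0.1, sigmaP = 0.1,
                         sigmaDm = 3, sigmaDp = 3,
                         normalizeRows = TRUE, hybrid = TRUE,
                         updateKernel = c("subset", "iteration")) {
  if (any(c(sigmaM, sigmaP, sigmaDm, sigmaDp) <= 0))
    stop("all kernel sigmas must be positive")
  if (nNeighbors < 1L) stop("nNeighbors must be >= 1")
  if (patchRadius < 0L) stop("patchRadius must be >= 0")
  structure(list(nNeighbors = as.integer(nNeighbors),
                 patchRadius = as.integer(patchRadius),
                 sigmaM = sigmaM, sigmaP = sigmaP,
                 sigmaDm = sigmaDm, sigmaDp = sigmaDp,
                 normalizeRows = isTRUE(normalizeRows),
                 hybrid = isTRUE(hybrid),
                 updateKernel = match.arg(updateKernel)),
            class = "kernelParams")
}

#' Extract per-voxel patch feature vectors
#'
#' The feature vector of voxel j is the vector of intensities in the
#' (2r+1)^2 patch centred on j, divided by the image's standard deviation
#' (fallback 1 for a constant image). Borders are handled by edge replication.
#'
#' @param image a VoxelImage (guidance image or current iterate).
#' @param patchRadius patch half-width in voxels.
#' @return numeric matrix, one row per voxel (column-major voxel order), one
#'   column per patch offset.
#' @export
extractFeatures <- function(image, patchRadius = 1L) {
  v <- image@values
  if (any(!is.finite(v))) stop("image must be finite")
  sc <- stats::sd(v)
  if (!is.finite(sc) || sc == 0) sc <- 1
  v <- v / sc
  r <- as.integer(patchRadius)
  d <- dim(v)
  # replicate-pad then gather shifted copies
  padIdx1 <- c(rep(1L, r), seq_len(d[1]), rep(d[1], r))
  padIdx2 <- c(rep(1L, r), seq_len(d[2]), rep(d[2], r))
  vp <- v[padIdx1, padIdx2, drop = FALSE]
  offs <- expand.grid(dx = -r:r, dy = -r:r)
  F <- matrix(0, prod(d), nrow(offs))
  for (o in seq_len(nrow(offs))) {
    i1 <- (1 + r + offs$dx[o]):(d[1] + r + offs$dx[o])
    i2 <- (1 + r + offs$dy[o]):(d[2] + r + offs$dy[o])
    F[, o] <- as.vector(vp[i1, i2, drop = FALSE])
  }
  F
}

# Candidate window offsets and, per offset, the candidate voxel index for each
# voxel (NA outside the grid) plus the squared spatial distance in voxel units.
windowCandidates <- function(d, radius) {
  offs <- expand.grid(dx = -radius:radius, dy = -radius:radius)
  i1 <- matrix(seq_len(d[1]), d[1], d[2])
  i2 <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  cand <- matrix(NA_integer_, prod(d), nrow(offs))
  for (o in seq_len(nrow(offs))) {
    c1 <- i1 + offs$dx[o]
    c2 <- i2 + offs$dy[o]
    ok <- c1 >= 1 & c1 <= d[1] & c2 >= 1 & c2 <= d[2]
    idx <- c1 + (c2 - 1L) * d[1]
    idx[!ok] <- NA_integer_
    cand[, o] <- as.vector(idx)
  }
  list(cand = cand, dist2 = offs$dx^2 + offs$dy^2)
}

#' Build the anatomical kernel K_m
#'
#' For each voxel j, the \code{nNeighbors} candidate voxels in the spatial
#' search window whose anatomical patch features are nearest in Euclidean
#' feature distance are selected (the voxel itself is always kept). The
#' kernel weight is the product of the intensity Gaussian
#' exp(-||v_j - v_f||^2 / 2 sigmaM^2) and the spatial Gaussian
#' exp(-||x_j - x_f||^2 / 2 sigmaDm^2); rows are normalised if configured.
#'
#' @param anatomical VoxelImage guidance image (CT-like).
#' @param params a [kernelParams()] list.
#' @return a KernelModel
#' @export
buildAnatomicalKernel <- function(anatomical, params) {
  stopifnot(inherits(params, "kernelParams"))
  d <- dim(anatomical@values)
  n <- params$nNeighbors
  r <- params$patchRadius
  win <- windowCandidates(d, max(r, 0L))
  if (ncol(win$cand) < n)
    stop(sprintf("search window of %d candidates is smaller than nNeighbors = %d",
                 ncol(win$cand), n))
  F <- extractFeatures(anatomical, r)
  nVox <- prod(d)
  nCand <- ncol(win$cand)
  d2 <- matrix(Inf, nVox, nCand)
  for (o in seq_len(nCand)) {
    cd <- win$cand[, o]
    ok <- !is.na(cd)
    if (!any(ok)) next
    df <- F[which(ok), , drop = FALSE] - F[cd[ok], , drop = FALSE]
    d2[ok, o] <- rowSums(df * df)
  }
  selfCol <- which(win$dist2 == 0)
  neighbors <- matrix(0L, nVox, n)
  featD2 <- spatD2 <- matrix(0, nVox, n)
  neighbors[, 1] <- seq_len(nVox)
  if (n > 1L) {
    # columns are ordered by increasing candidate voxel index, so
    # ties.method = "first" breaks distance ties by voxel index
    otherCols <- setdiff(seq_len(nCand), selfCol)
    dOther <- d2[, otherCols, drop = FALSE]
    for (p in seq_len(n - 1L)) {
      pick <- max.col(-dOther, ties.method = "first")
      sel <- cbind(seq_len(nVox), pick)
      neighbors[, p + 1L] <- win$cand[, otherCols][sel]
      featD2[, p + 1L] <- dOther[sel]
      spatD2[, p + 1L] <- win$dist2[otherCols][pick]
      dOther[sel] <- Inf
    }
    # border voxels can run out of in-grid candidates: duplicate self with
    # zero weight so the row keeps its shape
    na <- is.na(neighbors)
    if (any(na)) {
      neighbors[na] <- row(neighbors)[na]
      featD2[na] <- Inf
      spatD2[na] <- Inf
    }
  }
  w <- exp(-featD2 / (2 * params$sigmaM^2)) * exp(-spatD2 / (2 * params$sigmaDm^2))
  if (params$normalizeRows) w <- w / rowSums(w)
  newKernelModel(neighbors, w, spatD2, d, anatomical@spacing,
                 params$normalizeRows)
}

newKernelModel <- function(neighbors, weights, spatD2, d, spacing, normalized) {
  kmat <- Matrix::sparseMatrix(
    i = rep(seq_len(nrow(neighbors)), ncol(neighbors)),
    j = as.vector(neighbors), x = as.vector(weights),
    dims = c(nrow(neighbors), nrow(neighbors)))
  new("KernelModel", neighbors = neighbors, weights = weights,
      spatialDist2 = spatD2, imageDim = as.integer(d),
      spacing = spacing, normalized = normalized,
      kmat = methods::as(kmat, "CsparseMatrix"))
}

#' Build the functional kernel K_p^(n) on an existing sparsity pattern
#'
#' Same construction as the anatomical kernel, but the patch features come
#' from the current coefficient iterate and the neighbour structure is taken
#' from the anatomical kernel so that the two factors align (required for the
#' hybrid product). Weights use \code{sigmaP} and \code{sigmaDp}.
#'
#' @param current VoxelImage of the current coefficient image alpha^(n).
#' @param params a [kernelParams()] list.
#' @param anatomicalKernel the KernelModel providing the neighbour structure.
#' @return a KernelModel (unnormalised rows: the hybrid product is normalised
#'   after composition).
#' @export
buildFunctionalKernel <- function(current, params, anatomicalKernel) {
  if (!identical(dim(current@values), anatomicalKernel@imageDim))
    stop("current iterate geometry does not match the kernel's grid")
  F <- extractFeatures(current, params$patchRadius)
  nb <- anatomicalKernel@neighbors
  d2 <- matrix(0, nrow(nb), ncol(nb))
  for (c in seq(2L, length.out = ncol(nb) - 1L)) {
    df <- F - F[nb[, c], , drop = FALSE]
    d2[, c] <- rowSums(df * df)
  }
  w <- exp(-d2 / (2 * params$sigmaP^2)) *
       exp(-anatomicalKernel@spatialDist2 / (2 * params$sigmaDp^2))
  newKernelModel(nb, w, anatomicalKernel@spatialDist2,
                 anatomicalKernel@imageDim, anatomicalKernel@spacing,
                 normalized = FALSE)
}

#' Compose the hybrid kernel K^(n) = K_m * K_p^(n)
#'
#' Elementwise product of two kernels on an identical sparsity pattern,
#' re-normalising rows when requested.
#'
#' @param km anatomical KernelModel.
#' @param kp functional KernelModel (same neighbour structure).
#' @param normalizeRows normalise the product rows to sum 1 (default TRUE).
#' @return a KernelModel
#' @export
composeHybrid <- function(km, kp, normalizeRows = TRUE) {
  if (!identical(km@neighbors, kp@neighbors))
    stop("kernels do not share a sparsity pattern")
  w <- km@weights * kp@weights
  if (normalizeRows) w <- w / rowSums(w)
  newKernelModel(km@neighbors, w, km@spatialDist2, km@imageDim, km@spacing,
                 normalized = normalizeRows)
}

#' Identity kernel
#'
#' Self-only kernel with unit weight: applying it is the identity map, and
#' kernelized EM with it reduces to plain (OS)EM.
#'
#' @param imageDim integer(2) grid size.
#' @param spacing voxel size in mm.
#' @return a KernelModel
#' @export
identityKernel <- function(imageDim, spacing = c(1, 1)) {
  nVox <- prod(imageDim)
  newKernelModel(matrix(seq_len(nVox), nVox, 1L), matrix(1, nVox, 1L),
                 matrix(0, nVox, 1L), imageDim,
                 rep(as.numeric(spacing), length.out = 2L), normalized = TRUE)
}

checkKernelGeometry <- function(k, image) {
  if (!identical(dim(image@values), k@imageDim))
    stop("image geometry does not match the kernel model")
}

#' @describeIn applyKernel lambda_j = sum_f k_fj alpha_f over the sparse
#'   neighbour set; linear and nonnegativity-preserving.
#' @export
setMethod("applyKernel", signature(k = "KernelModel", alpha = "VoxelImage"),
  function(k, alpha) {
    checkKernelGeometry(k, alpha)
    v <- as.numeric(k@kmat %*% as.vector(alpha@values))
    voxelImage(matrix(v, k@imageDim[1], k@imageDim[2]), alpha@spacing)
  })

#' @describeIn applyKernelAdjoint transpose action (K^T image), as appears in
#'   the numerator and sensitivity of the kernelized EM update.
#' @export
setMethod("applyKernelAdjoint", signature(k = "KernelModel", image = "VoxelImage"),
  function(k, image) {
    checkKernelGeometry(k, image)
    v <- as.numeric(Matrix::crossprod(k@kmat, as.vector(image@values)))
    voxelImage(matrix(v, k@imageDim[1], k@imageDim[2]), image@spacing)
  })
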