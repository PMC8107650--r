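# System model: parallel-beam projector with image-space PSF, additive term,
# Poisson data generation and ordered-subsets partitioning.

# Sparse parallel-beam Radon matrix with linear interpolation between radial
# bins. Row index = (angle-1)*nRadial + bin; column index = vectorised voxel.
buildProjectorMatrix <- function(imageDim, spacing, angles, nRadial, radialSpacing) {
  co <- gridCoordinates(imageDim, spacing)
  nVox <- prod(imageDim)
  xs <- as.vector(co$X)
  ys <- as.vector(co$Y)
  center <- (nRadial + 1) / 2
  ii <- jj <- ww <- vector("list", length(angles))
  for (a in seq_along(angles)) {
    t <- xs * cos(angles[a]) + ys * sin(angles[a])
    p <- t / radialSpacing + center
    i0 <- floor(p)
    w1 <- i0 + 1 - p          # weight of bin i0
    rowBase <- (a - 1L) * nRadial
    keep0 <- i0 >= 1 & i0 <= nRadial
    keep1 <- (i0 + 1) >= 1 & (i0 + 1) <= nRadial
    ii[[a]] <- c(rowBase + i0[keep0], rowBase + i0[keep1] + 1)
    jj[[a]] <- c(seq_len(nVox)[keep0], seq_len(nVox)[keep1])
    ww[[a]] <- c(w1[keep0], (1 - w1)[keep1])
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(ww),
                       dims = c(length(angles) * nRadial, nVox))
}

#' Construct a PET system model
#'
#' Builds the parallel-beam projector embodying the system matrix c_ij: an
#' image-space isotropic Gaussian PSF followed by a discrete Radon transform
#' with linear interpolation onto radial bins. Optionally an attenuation map
#' is turned into per-LOR multiplicative factors exp(-line integral of mu).
#'
#' @param imageDim integer(2), image grid size in voxels.
#' @param spacing voxel size in mm (scalar or length 2).
#' @param nAngles number of projection angles, uniformly spaced over 180
#'   degrees. The default 63 divides evenly into 1, 3, 7, 9 or 21 subsets.
#' @param nRadial number of radial bins; default covers the grid diagonal.
#' @param psfFwhm in-plane PSF FWHM in mm (default 4.4).
#' @param nSubsets number of ordered subsets (default 1).
#' @param attenuationMap optional VoxelImage of linear attenuation
#'   coefficients (1/mm) on the same grid.
#' @return a SystemModel
#' @seealso [forwardProject()], [backProject()], [makeSubsets()]
#' @export
systemModel <- function(imageDim, spacing = c(1, 1), nAngles = 63L,
                        nRadial = NULL, psfFwhm = 4.4, nSubsets = 1L,
                        attenuationMap = NULL) {
  imageDim <- as.integer(imageDim)
  stopIfNot2dGrid(imageDim)
  spacing <- rep(as.numeric(spacing), length.out = 2L)
  radialSpacing <- spacing[1]
  if (is.null(nRadial)) {
    nRadial <- as.integer(ceiling(sqrt(sum(imageDim^2)))) + 2L
    if (nRadial %% 2L == 0L) nRadial <- nRadial + 1L
  }
  angles <- seq(0, pi, length.out = nAngles + 1L)[seq_len(nAngles)]
  P <- buildProjectorMatrix(imageDim, spacing, angles, nRadial, radialSpacing)
  sigmaVox <- fwhmToSigma(psfFwhm) / spacing
  b1 <- if (psfFwhm > 0) convolutionMatrix1d(imageDim[1], sigmaVox[1], "zero")
        else diag(imageDim[1])
  b2 <- if (psfFwhm > 0) convolutionMatrix1d(imageDim[2], sigmaVox[2], "zero")
        else diag(imageDim[2])
  att <- numeric(0)
  if (!is.null(attenuationMap)) {
    if (!identical(dim(attenuationMap@values), as.integer(imageDim)))
      stop("attenuation map grid does not match the model geometry")
    # line integral of mu approximated on the same interpolation grid
    att <- as.numeric(exp(-(P %*% as.vector(attenuationMap@values)) * radialSpacing))
  }
  m <- new("SystemModel", imageDim = imageDim, spacing = spacing,
           angles = angles, nRadial = as.integer(nRadial),
           radialSpacing = radialSpacing, psfFwhm = psfFwhm,
           subsets = list(seq_len(nAngles)), P = P,
           blur1 = b1, blur2 = b2, attenuation = att)
  if (nSubsets > 1L) m <- makeSubsets(m, nSubsets) else m
}

#' Partition a system model into ordered subsets
#'
#' Angles are assigned to subsets by interleaving (stride = nSubsets), which
#' maximises angular coverage within each subset. Subset sizes differ by at
#' most one angle; together they cover all angles disjointly.
#'
#' @param model a SystemModel
#' @param nSubsets number of subsets; must not exceed the number of angles.
#' @return the model with its subset partition replaced
#' @export
makeSubsets <- function(model, nSubsets) {
  nSubsets <- as.integer(nSubsets)
  nA <- length(model@angles)
  if (nSubsets < 1L) stop("nSubsets must be >= 1")
  if (nSubsets > nA)
    stop(sprintf("nSubsets (%d) exceeds the number of angles (%d)", nSubsets, nA))
  model@subsets <- lapply(seq_len(nSubsets),
                          function(s) seq.int(s, nA, by = nSubsets))
  validObject(model)
  model
}

# LOR (row) indices belonging to one subset's angles.
subsetRows <- function(model, subset = NULL) {
  if (is.null(subset)) return(seq_len(length(model@angles) * model@nRadial))
  if (subset < 1L || subset > length(model@subsets))
    stop("subset index out of range")
  ang <- model@subsets[[subset]]
  as.vector(outer(seq_len(model@nRadial), (ang - 1L) * model@nRadial, `+`))
}

# Fast internal projections on plain vectors (image vectorised column-major).
projectVec <- function(model, imgVec, rows = NULL) {
  v <- as.vector(blurValues(matrix(imgVec, model@imageDim[1], model@imageDim[2]),
                            model@blur1, model@blur2))
  y <- if (is.null(rows)) model@P %*% v else model@P[rows, , drop = FALSE] %*% v
  y <- as.numeric(y)
  if (length(model@attenuation))
    y <- y * (if (is.null(rows)) model@attenuation else model@attenuation[rows])
  y
}

backprojectVec <- function(model, sinoVec, rows = NULL) {
  if (length(model@attenuation))
    sinoVec <- sinoVec * (if (is.null(rows)) model@attenuation
                          else model@attenuation[rows])
  v <- if (is.null(rows)) Matrix::crossprod(model@P, sinoVec)
       else Matrix::crossprod(model@P[rows, , drop = FALSE], sinoVec)
  as.vector(blurValues(matrix(as.numeric(v), model@imageDim[1], model@imageDim[2]),
                       model@blur1, model@blur2))
}

checkImageGeometry <- function(image, model) {
  if (!identical(dim(image@values), model@imageDim) ||
      any(abs(image@spacing - model@spacing) > 1e-9))
    stop("image geometry does not match the system model")
}

#' @describeIn forwardProject project a VoxelImage through the system model;
#'   with \code{subset} given, only that subset's angles are computed.
#' @export
setMethod("forwardProject", signature(image = "VoxelImage", model = "SystemModel"),
  function(image, model, subset = NULL) {
    checkImageGeometry(image, model)
    rows <- if (is.null(subset)) NULL else subsetRows(model, subset)
    y <- projectVec(model, as.vector(image@values), rows)
    ang <- if (is.null(subset)) model@angles else model@angles[model@subsets[[subset]]]
    new("Sinogram",
        values = matrix(pmax(y, 0), length(ang), model@nRadial, byrow = TRUE),
        angles = ang, radialSpacing = model@radialSpacing)
  })

#' @describeIn backProject adjoint of [forwardProject()]: spreads sinogram
#'   values back along their LORs and applies the (self-adjoint) PSF.
#' @export
setMethod("backProject", signature(sino = "Sinogram", model = "SystemModel"),
  function(sino, model, subset = NULL) {
    rows <- if (is.null(subset)) NULL else subsetRows(model, subset)
    expAngles <- if (is.null(subset)) model@angles
                 else model@angles[model@subsets[[subset]]]
    if (length(sino@angles) != length(expAngles) ||
        any(abs(sino@angles - expAngles) > 1e-9) ||
        ncol(sino@values) != model@nRadial)
      stop("sinogram geometry does not match the system model")
    v <- backprojectVec(model, as.vector(t(sino@values)), rows)
    voxelImage(matrix(v, model@imageDim[1], model@imageDim[2]), model@spacing)
  })

#' Uniform additive (scatter + randoms) term
#'
#' The expected scatter-plus-randoms contribution s_i is modelled as a flat
#' sinogram whose total is a fraction of the expected true counts.
#'
#' @param model a SystemModel
#' @param totalCounts expected total true counts of the acquisition.
#' @param fraction additive fraction relative to true counts (default 0.3).
#' @return a Sinogram of expected additive counts
#' @export
uniformAdditive <- function(model, totalCounts, fraction = 0.3) {
  if (fraction < 0) stop("additive fraction must be nonnegative")
  nA <- length(model@angles)
  val <- fraction * totalCounts / (nA * model@nRadial)
  new("Sinogram", values = matrix(val, nA, model@nRadial),
      angles = model@angles, radialSpacing = model@radialSpacing)
}

#' Simulate Poisson emission data
#'
#' The ground-truth activity is forward projected, scaled so that the expected
#' true counts equal \code{totalCounts}, the additive term is added, and
#' independent Poisson counts are drawn per LOR.
#'
#' @param truth VoxelImage of ground-truth activity.
#' @param model a SystemModel.
#' @param additive Sinogram of expected scatter+randoms counts (all angles),
#'   or NULL for none.
#' @param totalCounts expected total true (non-additive) counts.
#' @param seed RNG seed; the draw is deterministic given the seed.
#' @return a Sinogram of counts, with attributes \code{scale} (the activity to
#'   counts scale factor applied) and \code{expected} (the noise-free mean).
#' @export
simulateCounts <- function(truth, model, additive = NULL, totalCounts, seed = 1L) {
  checkImageGeometry(truth, model)
  if (totalCounts <= 0) stop("totalCounts must be positive")
  fwd <- projectVec(model, as.vector(truth@values))
  s <- if (is.null(additive)) 0 else as.vector(t(additive@values))
  if (any(s < 0)) stop("additive term must be nonnegative")
  tot <- sum(fwd)
  scale <- if (tot > 0) totalCounts / tot else 0
  ybar <- scale * fwd + s
  y <- withSeed(seed, stats::rpois(length(ybar), ybar))
  out <- new("Sinogram",
             values = matrix(y, length(model@angles), model@nRadial, byrow = TRUE),
             angles = model@angles, radialSpacing = model@radialSpacing)
  attr(out, "scale") <- scale
  attr(out, "expected") <- ybar
  out
}
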