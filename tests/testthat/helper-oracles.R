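# Independent oracle implementations used to cross-check the package. These
# deliberately use direct, slow formulations (explicit loops, dense algebra)
# and share no code with the package internals they verify.

# Dense parallel-beam system matrix by direct per-voxel computation of the
# linear interpolation weights (no PSF).
denseRadonMatrix <- function(dim, spacing, angles, nRadial, radialSpacing) {
  nVox <- prod(dim)
  A <- matrix(0, length(angles) * nRadial, nVox)
  center <- (nRadial + 1) / 2
  for (j in seq_len(nVox)) {
    i1 <- (j - 1) %% dim[1] + 1
    i2 <- (j - 1) %/% dim[1] + 1
    x <- (i1 - (dim[1] + 1) / 2) * spacing[1]
    y <- (i2 - (dim[2] + 1) / 2) * spacing[2]
    for (a in seq_along(angles)) {
      p <- (x * cos(angles[a]) + y * sin(angles[a])) / radialSpacing + center
      b0 <- floor(p)
      w1 <- b0 + 1 - p
      if (b0 >= 1 && b0 <= nRadial)
        A[(a - 1) * nRadial + b0, j] <- A[(a - 1) * nRadial + b0, j] + w1
      if (b0 + 1 >= 1 && b0 + 1 <= nRadial)
        A[(a - 1) * nRadial + b0 + 1, j] <- A[(a - 1) * nRadial + b0 + 1, j] + (1 - w1)
    }
  }
  A
}

# Patch features by direct per-voxel extraction with edge replication,
# normalised by the image standard deviation.
denseFeatures <- function(values, r) {
  d <- dim(values)
  sc <- stats::sd(values); if (!is.finite(sc) || sc == 0) sc <- 1
  F <- matrix(0, prod(d), (2 * r + 1)^2)
  for (j in seq_len(prod(d))) {
    i1 <- (j - 1) %% d[1] + 1
    i2 <- (j - 1) %/% d[1] + 1
    col <- 0
    for (dy in -r:r) for (dx in -r:r) {
      col <- col + 1
      F[j, col] <- values[min(max(i1 + dx, 1), d[1]),
                          min(max(i2 + dy, 1), d[2])] / sc
    }
  }
  F
}

# Dense brute-force anatomical kernel: for every voxel j, rank all candidates
# in the (2r+1)^2 spatial window by feature distance (self forced first, ties
# by voxel index), keep n, and fill a dense matrix with the Gaussian product
# weights. Returns the dense K with rows optionally normalised.
denseAnatomicalKernel <- function(values, n, r, sigmaM, sigmaDm,
                                  normalize = TRUE) {
  d <- dim(values)
  F <- denseFeatures(values, r)
  nVox <- prod(d)
  K <- matrix(0, nVox, nVox)
  for (j in seq_len(nVox)) {
    i1 <- (j - 1) %% d[1] + 1
    i2 <- (j - 1) %/% d[1] + 1
    cand <- integer(0); sd2 <- numeric(0)
    for (dy in -r:r) for (dx in -r:r) {
      c1 <- i1 + dx; c2 <- i2 + dy
      if (c1 >= 1 && c1 <= d[1] && c2 >= 1 && c2 <= d[2]) {
        cand <- c(cand, c1 + (c2 - 1) * d[1])
        sd2 <- c(sd2, dx^2 + dy^2)
      }
    }
    fd2 <- colSums((t(F[cand, , drop = FALSE]) - F[j, ])^2)
    others <- cand != j
    ord <- order(fd2[others], cand[others])
    pick <- c(j, cand[others][ord])[seq_len(min(n, length(cand)))]
    pd2f <- c(0, fd2[others][ord])[seq_len(min(n, length(cand)))]
    pd2s <- c(0, sd2[others][ord])[seq_len(min(n, length(cand)))]
    w <- exp(-pd2f / (2 * sigmaM^2)) * exp(-pd2s / (2 * sigmaDm^2))
    if (normalize) w <- w / sum(w)
    K[j, pick] <- K[j, pick] + w
  }
  K
}

# Dense functional kernel on a given neighbour structure (matrix of indices,
# column 1 = self), from the current image's features.
denseFunctionalKernel <- function(values, neighbors, spatialDist2, r,
                                  sigmaP, sigmaDp) {
  F <- denseFeatures(values, r)
  nVox <- nrow(neighbors)
  K <- matrix(0, nVox, nVox)
  for (j in seq_len(nVox)) {
    for (c in seq_len(ncol(neighbors))) {
      f <- neighbors[j, c]
      fd2 <- sum((F[j, ] - F[f, ])^2)
      if (c == 1) fd2 <- 0
      w <- exp(-fd2 / (2 * sigmaP^2)) *
        exp(-spatialDist2[j, c] / (2 * sigmaDp^2))
      K[j, f] <- K[j, f] + w
    }
  }
  K
}

# Classical MLEM multiplicative update on a dense system matrix.
mlemDenseUpdate <- function(lambda, A, y, s) {
  sens <- colSums(A)
  ybar <- as.vector(A %*% lambda) + s
  ratio <- ifelse(ybar > 0, y / ybar, 0)
  upd <- lambda * as.vector(t(A) %*% ratio) / sens
  upd[sens == 0] <- lambda[sens == 0]
  upd
}

# Dense operator equivalent of a SystemModel (geometric projector after the
# separable PSF blur), for adjoint-free dense cross-checks.
denseSystemOperator <- function(model) {
  blurK <- kronecker(model@blur2, model@blur1)
  as.matrix(model@P) %*% blurK
}

# Mann-Whitney AUC by explicit positive-negative pair counting, ties = 1/2.
pairCountAuc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Small default phantom/model pair for reuse in tests.
testModel <- function(dim = 32L, spacing = 2, nAngles = 30L, psfFwhm = 4.4,
                      nSubsets = 1L)
  systemModel(c(dim, dim), spacing, nAngles = nAngles, psfFwhm = psfFwhm,
              nSubsets = nSubsets)

randomSinogram <- function(model, seed = 1) {
  set.seed(seed)
  new("Sinogram",
      values = matrix(stats::runif(length(model@angles) * model@nRadial),
                      length(model@angles), model@nRadial),
      angles = model@angles, radialSpacing = model@radialSpacing)
}
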