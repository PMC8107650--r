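# Sparse kernel construction vs dense brute-force evaluation.

test_that("patch features match direct extraction on a ramp image", {
  v <- matrix(seq_len(16), 4, 4)
  img <- voxelImage(v, 1)
  F <- extractFeatures(img, patchRadius = 1L)
  expect_equal(F, denseFeatures(v, 1L), tolerance = 1e-14)
  # radius 0: single normalised intensity
  F0 <- extractFeatures(img, patchRadius = 0L)
  expect_equal(as.vector(F0), as.vector(v) / stats::sd(v))
  # constant image: identical features, scale falls back to 1
  Fc <- extractFeatures(voxelImage(matrix(5, 4, 4), 1), 1L)
  expect_true(all(Fc == 5))
})

test_that("anatomical kernel matches the dense brute-force evaluation", {
  set.seed(21)
  for (d in c(3L, 8L, 16L)) {
    v <- matrix(runif(d * d), d, d)
    img <- voxelImage(v, 1)
    p <- kernelParams(nNeighbors = 3L, patchRadius = 1L, sigmaM = 0.1,
                      sigmaDm = 3)
    km <- buildAnatomicalKernel(img, p)
    Kd <- denseAnatomicalKernel(v, 3L, 1L, 0.1, 3, normalize = TRUE)
    expect_equal(as.matrix(km@kmat), Kd, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("functional kernel and hybrid product match dense oracles", {
  set.seed(22)
  d <- 8L
  anat <- voxelImage(matrix(runif(d * d), d, d), 1)
  cur <- voxelImage(matrix(rexp(d * d), d, d), 1)
  p <- kernelParams(nNeighbors = 4L, patchRadius = 1L, sigmaM = 0.2,
                    sigmaP = 0.15, sigmaDm = 2, sigmaDp = 2.5)
  km <- buildAnatomicalKernel(anat, p)
  kp <- buildFunctionalKernel(cur, p, km)
  Kpd <- denseFunctionalKernel(imgValues(cur), km@neighbors, km@spatialDist2,
                               1L, 0.15, 2.5)
  expect_equal(as.matrix(kp@kmat), Kpd, tolerance = 1e-10, ignore_attr = TRUE)
  hy <- composeHybrid(km, kp, normalizeRows = TRUE)
  Kmd <- as.matrix(km@kmat)
  Hd <- Kmd * Kpd
  Hd <- Hd / rowSums(Hd)
  expect_equal(as.matrix(hy@kmat), Hd, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("kernel application equals the dense matrix-vector product", {
  set.seed(23)
  d <- 8L
  anat <- voxelImage(matrix(runif(d * d), d, d), 1)
  p <- kernelParams(nNeighbors = 5L, patchRadius = 1L)
  km <- buildAnatomicalKernel(anat, p)
  a <- voxelImage(matrix(rexp(d * d), d, d), 1)
  expect_equal(as.vector(imgValues(applyKernel(km, a))),
               as.vector(as.matrix(km@kmat) %*% as.vector(imgValues(a))),
               tolerance = 1e-12)
  x <- voxelImage(matrix(runif(d * d), d, d), 1)
  expect_equal(as.vector(imgValues(applyKernelAdjoint(km, x))),
               as.vector(t(as.matrix(km@kmat)) %*% as.vector(imgValues(x))),
               tolerance = 1e-12)
  # adjoint inner-product identity
  lhs <- sum(imgValues(applyKernel(km, a)) * imgValues(x))
  rhs <- sum(imgValues(a) * imgValues(applyKernelAdjoint(km, x)))
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-10)
  # all-ones adjoint gives column sums
  ones <- voxelImage(matrix(1, d, d), 1)
  expect_equal(as.vector(imgValues(applyKernelAdjoint(km, ones))),
               Matrix::colSums(km@kmat), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("degenerate kernels behave as identities and constants", {
  d <- 6L
  anat <- voxelImage(matrix(runif(d * d), d, d), 1)
  # single neighbour: identity operator
  k1 <- buildAnatomicalKernel(anat, kernelParams(nNeighbors = 1L))
  a <- voxelImage(matrix(rexp(d * d), d, d), 1)
  expect_equal(imgValues(applyKernel(k1, a)), imgValues(a), tolerance = 1e-14)
  idk <- identityKernel(c(d, d), 1)
  expect_equal(imgValues(applyKernel(idk, a)), imgValues(a))
  # constant guidance: intensity factor 1, weights purely spatial
  kc <- buildAnatomicalKernel(voxelImage(matrix(3, d, d), 1),
                              kernelParams(nNeighbors = 3L, normalizeRows = FALSE))
  expect_equal(kc@weights, exp(-kc@spatialDist2 / (2 * 3^2)), tolerance = 1e-12)
  # row-normalised kernel maps constants to themselves
  km <- buildAnatomicalKernel(anat, kernelParams(nNeighbors = 4L))
  expect_equal(rowSums(km@weights), rep(1, d * d), tolerance = 1e-12)
  cimg <- voxelImage(matrix(2.5, d, d), 1)
  expect_equal(imgValues(applyKernel(km, cimg)), imgValues(cimg),
               tolerance = 1e-12)
})

test_that("flat functional factor makes the hybrid collapse to the anatomical kernel", {
  set.seed(25)
  d <- 8L
  anat <- voxelImage(matrix(runif(d * d), d, d), 1)
  cur <- voxelImage(matrix(rexp(d * d), d, d), 1)
  p <- kernelParams(nNeighbors = 3L, sigmaP = 1e6, sigmaDp = 1e6)
  km <- buildAnatomicalKernel(anat, p)
  kp <- buildFunctionalKernel(cur, p, km)
  expect_equal(max(abs(kp@weights - 1)), 0, tolerance = 1e-9)
  hy <- composeHybrid(km, kp)
  expect_equal(hy@weights, km@weights, tolerance = 1e-9)
  # constant current image: intensity factor identically 1
  kpc <- buildFunctionalKernel(voxelImage(matrix(1, d, d), 1),
                               kernelParams(nNeighbors = 3L, sigmaDp = 1e6), km)
  expect_equal(max(abs(kpc@weights - 1)), 0, tolerance = 1e-12)
  # mismatched patterns are rejected
  km2 <- buildAnatomicalKernel(voxelImage(matrix(runif(36), 6, 6), 1), p)
  expect_error(composeHybrid(km, km2), "pattern|shape|identical")
})

test_that("window smaller than the neighbour count is a configuration error", {
  img <- voxelImage(matrix(runif(16), 4, 4), 1)
  expect_error(
    buildAnatomicalKernel(img, kernelParams(nNeighbors = 2L, patchRadius = 0L)),
    "smaller than nNeighbors")
})
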