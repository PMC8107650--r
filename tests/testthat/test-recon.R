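# EM update correctness, algorithm equivalences, likelihood monotonicity and
# the Gaussian post-filter.

simulatedCase <- function(dim = 16L, nAngles = 12L, counts = 2e4, seed = 5L,
                          psfFwhm = 4.4) {
  m <- testModel(dim, 2, nAngles = nAngles, psfFwhm = psfFwhm)
  s <- generateSubject(phantomSpec(gridShape = c(dim, dim),
                                   voxelSize = 192 / dim,
                                   seed = seed))
  truth <- voxelImage(imgValues(s@activityTruth), 2)
  add <- uniformAdditive(m, counts, 0.3)
  y <- simulateCounts(truth, m, add, counts, seed = seed)
  list(model = m, data = y, additive = add, subject = s)
}

test_that("identity-kernel EM update equals the classical MLEM update", {
  cs <- simulatedCase()
  A <- denseSystemOperator(cs$model)
  y <- as.vector(t(sinoValues(cs$data)))
  s <- as.vector(t(sinoValues(cs$additive)))
  alpha <- voxelImage(matrix(1, 16, 16), 2)
  ours <- emUpdate(alpha, NULL, cs$data, cs$model, cs$additive)
  oracle <- mlemDenseUpdate(rep(1, 256), A, y, s)
  expect_equal(as.vector(imgValues(ours)), oracle, tolerance = 1e-10)
  idk <- identityKernel(c(16L, 16L), 2)
  viaIdentity <- emUpdate(alpha, idk, cs$data, cs$model, cs$additive)
  expect_equal(imgValues(viaIdentity), imgValues(ours), tolerance = 1e-12)
})

test_that("EM update leaves a consistent estimate fixed", {
  cs <- simulatedCase()
  set.seed(8)
  alpha <- voxelImage(matrix(rexp(256) + 0.5, 16, 16), 2)
  lam <- forwardProject(alpha, cs$model)
  yExact <- new("Sinogram",
                values = sinoValues(lam) + sinoValues(cs$additive),
                angles = cs$model@angles,
                radialSpacing = cs$model@radialSpacing)
  upd <- emUpdate(alpha, NULL, yExact, cs$model, cs$additive)
  expect_equal(imgValues(upd), imgValues(alpha), tolerance = 1e-8)
})

test_that("a two-voxel toy system reproduces the scalar hand-computed update", {
  # 2x1 grid, one angle, three radial bins: a genuinely tiny dense system
  m <- systemModel(c(2L, 1L), 1, nAngles = 1L, nRadial = 3L, psfFwhm = 0)
  A <- as.matrix(m@P)
  y <- c(4, 3, 6)
  s <- c(0.5, 0.5, 0.5)
  alpha <- c(1, 2)
  # scalar arithmetic of the multiplicative update
  ybar <- as.vector(A %*% alpha) + s
  expected <- alpha * as.vector(t(A) %*% (y / ybar)) / colSums(A)
  got <- emUpdate(voxelImage(matrix(alpha, 2, 1), 1), NULL,
                  new("Sinogram", values = matrix(y, 1, 3), angles = m@angles,
                      radialSpacing = 1),
                  m,
                  new("Sinogram", values = matrix(s, 1, 3), angles = m@angles,
                      radialSpacing = 1))
  expect_equal(as.vector(imgValues(got)), expected, tolerance = 1e-12)
})

test_that("KEM with a self-only neighbourhood equals unfiltered MLEM", {
  cs <- simulatedCase()
  mlem <- reconstruct(cs$data, cs$model, cs$additive, NULL,
                      reconConfig("osem", nSubsets = 1L, nIterations = 3L,
                                  postFilterFwhm = 0))
  kem1 <- reconstruct(cs$data, cs$model, cs$additive, cs$subject@anatomical,
                      reconConfig("kem", nSubsets = 1L, nIterations = 3L,
                                  kernel = kernelParams(nNeighbors = 1L)))
  for (i in 1:3)
    expect_equal(imgValues(kem1@images[[i]]), imgValues(mlem@images[[i]]),
                 tolerance = 1e-10)
})

test_that("OSEM with one subset equals MLEM and iterates stay nonnegative", {
  cs <- simulatedCase()
  r1 <- reconstruct(cs$data, cs$model, cs$additive, NULL,
                    reconConfig("osem", nSubsets = 1L, nIterations = 2L,
                                postFilterFwhm = 0))
  A <- denseSystemOperator(cs$model)
  y <- as.vector(t(sinoValues(cs$data)))
  s <- as.vector(t(sinoValues(cs$additive)))
  lam <- rep(1, 256)
  for (i in 1:2) lam <- mlemDenseUpdate(lam, A, y, s)
  expect_equal(as.vector(imgValues(r1@images[[2]])), lam, tolerance = 1e-8)
  expect_true(all(imgValues(r1@images[[2]]) >= 0))
  expect_true(all(r1@alpha >= 0))
})

test_that("flat functional factor makes HKEM match KEM", {
  cs <- simulatedCase(dim = 32L, nAngles = 30L, counts = 5e4)
  kp <- kernelParams(nNeighbors = 3L, sigmaP = 1e6, sigmaDp = 1e6)
  kem <- reconstruct(cs$data, cs$model, cs$additive, cs$subject@anatomical,
                     reconConfig("kem", nSubsets = 3L, nIterations = 2L,
                                 kernel = kp))
  hkem <- reconstruct(cs$data, cs$model, cs$additive, cs$subject@anatomical,
                      reconConfig("hkem", nSubsets = 3L, nIterations = 2L,
                                  kernel = kp))
  a <- imgValues(kem@images[[2]]); b <- imgValues(hkem@images[[2]])
  expect_lt(max(abs(a - b)) / max(a), 1e-3)
})

test_that("HKEM runs with per-iteration kernel update cadence too", {
  cs <- simulatedCase()
  kp <- kernelParams(updateKernel = "iteration")
  r <- reconstruct(cs$data, cs$model, cs$additive, cs$subject@anatomical,
                   reconConfig("hkem", nSubsets = 2L, nIterations = 2L,
                               kernel = kp))
  expect_length(r@images, 2L)
  expect_true(all(imgValues(r@images[[2]]) >= 0))
})

test_that("MLEM log-likelihood is non-decreasing", {
  cs <- simulatedCase(dim = 16L, nAngles = 12L, counts = 1e4, seed = 13L)
  r <- reconstruct(cs$data, cs$model, cs$additive, NULL,
                   reconConfig("osem", nSubsets = 1L, nIterations = 25L,
                               postFilterFwhm = 0))
  expect_true(all(diff(r@logLik) > -1e-6))
})

test_that("anatomical image is required for kernel algorithms", {
  cs <- simulatedCase()
  expect_error(reconstruct(cs$data, cs$model, cs$additive, NULL,
                           reconConfig("kem")), "anatomical")
})

test_that("Gaussian post-filter preserves mass and matches the analytic peak", {
  set.seed(31)
  img <- voxelImage(matrix(runif(1024), 32, 32), 2)
  expect_identical(gaussianPostFilter(img, 0), img)
  f <- gaussianPostFilter(img, 5)
  expect_equal(sum(imgValues(f)), sum(imgValues(img)), tolerance = 1e-6)
  # delta image: peak equals the product of the central 1D kernel taps
  delta <- matrix(0, 33, 33); delta[17, 17] <- 1
  fd <- gaussianPostFilter(voxelImage(delta, 2), 5)
  sigmaVox <- fwhmToSigma(5) / 2
  taps <- exp(-(-9:9)^2 / (2 * sigmaVox^2))
  taps <- taps / sum(taps)
  expect_equal(max(imgValues(fd)), max(taps)^2, tolerance = 1e-6)
  expect_error(gaussianPostFilter(img, -1), ">= 0")
})
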