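# Synthetic 2D abdominal phantom: spine (hot NaF bone uptake), aneurysmal
# aorta cross-section with calcified micro-lesions in the wall, a normal
# aorta cross-section, and the vena cava blood pool, plus the T/A/B analysis
# masks the quantification assumes.

#' Phantom specification
#'
#' Describes one synthetic axial abdominal slice. Geometry is in mm on a grid
#' centred at the origin; activities are unitless uptake ratios. The aneurysm
#' target region T is the aneurysm wall annulus (with voxels within
#' \code{spineMargin} of the spine excluded, mimicking the spill-in avoidance
#' of the analysis protocol), A is the wall annulus of the normal aorta
#' section, and B is the vena cava disc.
#'
#' @param gridShape integer(2) voxels per axis (default 64 x 64).
#' @param voxelSize voxel size in mm (default 3).
#' @param aortaCenter,aortaRadius,aortaLumenRadius normal aorta cross-section.
#' @param aneurysmCenter,aneurysmRadius aneurysmal aorta cross-section;
#'   the lumen radius is \code{lumenFraction * aneurysmRadius}.
#' @param lumenFraction lumen/outer radius ratio of the aneurysm.
#' @param spineCenter,spineRadius,spineMargin vertebral body and the T-mask
#'   exclusion margin (mm) around it.
#' @param venaCavaCenter,venaCavaRadius blood-pool reference region.
#' @param lesionCount number of calcified micro-lesions in the aneurysm wall.
#' @param lesionRadius lesion radius in mm.
#' @param lesionContrast lesion activity relative to the aorta wall; 1 means
#'   no lesion uptake (control).
#' @param spineActivity,backgroundActivity,bloodActivity,wallActivity
#'   unitless uptake ratios; the spine is the hottest structure (NaF bone
#'   uptake) so spill-in toward the aorta is represented.
#' @param anatomicalBlurFwhm optional Gaussian blur (mm FWHM) of the CT-like
#'   image to emulate texture; 0 = noiseless (default).
#' @param noiseScale expected total true counts of the simulated acquisition.
#' @param seed RNG seed for lesion placement and counts.
#' @return a PhantomSpec
#' @export
phantomSpec <- function(gridShape = c(64L, 64L), voxelSize = 3,
                        aortaCenter = c(0, 40), aortaRadius = 9,
                        aortaLumenRadius = 5,
                        aneurysmCenter = c(0, -10), aneurysmRadius = 24,
                        lumenFraction = 0.55,
                        spineCenter = c(0, -62), spineRadius = 14,
                        spineMargin = 6,
                        venaCavaCenter = c(28, 40), venaCavaRadius = 7,
                        lesionCount = 2L, lesionRadius = 3,
                        lesionContrast = 2.5,
                        spineActivity = 5, backgroundActivity = 1,
                        bloodActivity = 1, wallActivity = 1.2,
                        anatomicalBlurFwhm = 0, noiseScale = 6e5,
                        seed = 1L) {
  new("PhantomSpec", gridShape = as.integer(gridShape),
      voxelSize = as.numeric(voxelSize),
      aortaCenter = aortaCenter, aortaRadius = aortaRadius,
      aortaLumenRadius = aortaLumenRadius,
      aneurysmCenter = aneurysmCenter, aneurysmRadius = aneurysmRadius,
      lumenFraction = lumenFraction,
      spineCenter = spineCenter, spineRadius = spineRadius,
      spineMargin = spineMargin,
      venaCavaCenter = venaCavaCenter, venaCavaRadius = venaCavaRadius,
      lesionCount = as.integer(lesionCount), lesionRadius = lesionRadius,
      lesionContrast = lesionContrast,
      spineActivity = spineActivity, backgroundActivity = backgroundActivity,
      bloodActivity = bloodActivity, wallActivity = wallActivity,
      anatomicalBlurFwhm = anatomicalBlurFwhm, noiseScale = noiseScale,
      seed = as.integer(seed))
}

discMask <- function(X, Y, center, radius)
  (X - center[1])^2 + (Y - center[2])^2 <= radius^2

#' Generate one synthetic subject
#'
#' Builds the CT-like anatomical image (bright spine, vessel walls, calcified
#' lesions), the ground-truth activity image (hot spine, wall uptake, focal
#' lesion uptake at \code{lesionContrast} times the wall) and the T/A/B masks.
#' Lesions are placed at jittered, well-separated angles in the aneurysm wall
#' annulus, restricted to the arc facing away from the spine so they survive
#' the spine-margin exclusion. Fully deterministic given \code{spec@seed}.
#'
#' @param spec a [phantomSpec()].
#' @return a SubjectData; its label is TRUE iff \code{lesionContrast > 1} and
#'   \code{lesionCount >= 1}.
#' @export
generateSubject <- function(spec) {
  validObject(spec)
  d <- spec@gridShape
  sp <- rep(spec@voxelSize, 2L)
  co <- gridCoordinates(d, sp)
  X <- co$X; Y <- co$Y
  lumenR <- spec@lumenFraction * spec@aneurysmRadius
  spine <- discMask(X, Y, spec@spineCenter, spec@spineRadius)
  aneuOuter <- discMask(X, Y, spec@aneurysmCenter, spec@aneurysmRadius)
  aneuLumen <- discMask(X, Y, spec@aneurysmCenter, lumenR)
  aneuWall <- aneuOuter & !aneuLumen
  aortaOuter <- discMask(X, Y, spec@aortaCenter, spec@aortaRadius)
  aortaLumen <- discMask(X, Y, spec@aortaCenter, spec@aortaLumenRadius)
  aortaWall <- aortaOuter & !aortaLumen
  cava <- discMask(X, Y, spec@venaCavaCenter, spec@venaCavaRadius)

  positive <- spec@lesionContrast > 1 && spec@lesionCount >= 1L
  lesions <- matrix(FALSE, d[1], d[2])
  if (spec@lesionCount >= 1L && spec@lesionContrast > 1) {
    midR <- (lumenR + spec@aneurysmRadius) / 2
    # arc facing away from the spine (exclude +/-60 degrees around it)
    spineDir <- atan2(spec@spineCenter[2] - spec@aneurysmCenter[2],
                      spec@spineCenter[1] - spec@aneurysmCenter[1])
    arc <- 2 * pi - 2 * (pi / 3)
    base <- spineDir + pi / 3 + (seq_len(spec@lesionCount) - 0.5) *
      arc / spec@lesionCount
    jitterMax <- arc / (4 * spec@lesionCount)
    ang <- withSeed(spec@seed,
                    base + stats::runif(spec@lesionCount, -jitterMax, jitterMax))
    for (a in ang) {
      c0 <- spec@aneurysmCenter + midR * c(cos(a), sin(a))
      lesions <- lesions | (discMask(X, Y, c0, spec@lesionRadius) & aneuWall)
    }
  }

  act <- matrix(spec@backgroundActivity, d[1], d[2])
  act[aortaLumen | aneuLumen | cava] <- spec@bloodActivity
  act[aortaWall | aneuWall] <- spec@wallActivity
  act[lesions] <- spec@lesionContrast * spec@wallActivity
  act[spine] <- spec@spineActivity

  # CT-like image in arbitrary HU-flavoured units
  anat <- matrix(40, d[1], d[2])
  anat[aortaLumen | aneuLumen | cava] <- 55
  anat[aortaWall | aneuWall] <- 110
  anat[lesions] <- 800                      # calcification is CT-bright
  anat[spine] <- 1000
  anatImg <- voxelImage(anat, sp)
  if (spec@anatomicalBlurFwhm > 0)
    anatImg <- gaussianPostFilter(anatImg, spec@anatomicalBlurFwhm)

  distSpine <- sqrt((X - spec@spineCenter[1])^2 + (Y - spec@spineCenter[2])^2)
  target <- aneuWall & (distSpine > spec@spineRadius + spec@spineMargin)
  rois <- roiSet(target = target, aorta = aortaWall, blood = cava)

  new("SubjectData", anatomical = anatImg, activityTruth = voxelImage(act, sp),
      rois = rois, label = positive,
      aneurysmDiameter = 2 * spec@aneurysmRadius, spec = spec)
}

defaultSpecRanges <- function() {
  list(gridShape = c(64L, 64L),
       voxelSize = 3,
       diameterRange = c(35, 65),
       controlDiameterRange = c(18, 28),
       contrastRange = c(1.5, 4),
       lesionCountRange = c(1L, 3L),
       lesionRadius = 3,
       noiseScale = 6e5)
}

#' Generate a synthetic cohort
#'
#' Draws \code{nPositive} AAA-positive subjects (aneurysm diameter uniform on
#' \code{diameterRange}, lesion contrast uniform on \code{contrastRange},
#' lesion count uniform over \code{lesionCountRange}) and \code{nControl}
#' control subjects (no lesions, normal-calibre aorta at the aneurysm
#' location, diameter from \code{controlDiameterRange}). Per-subject seeds are
#' derived from \code{seed}, so the whole cohort is reproducible.
#'
#' @param nPositive,nControl subject counts (>= 0).
#' @param specRanges named list overriding entries of the default ranges
#'   (diameterRange, controlDiameterRange, contrastRange, lesionCountRange,
#'   lesionRadius, noiseScale).
#' @param seed cohort RNG seed.
#' @return a list of SubjectData (positives first)
#' @export
generateCohort <- function(nPositive, nControl, specRanges = list(), seed = 1L) {
  if (nPositive < 0 || nControl < 0) stop("subject counts must be >= 0")
  rg <- utils::modifyList(defaultSpecRanges(), specRanges)
  for (nm in c("diameterRange", "controlDiameterRange", "contrastRange",
               "lesionCountRange")) {
    v <- rg[[nm]]
    if (length(v) != 2L || any(!is.finite(v)) || v[1] > v[2])
      stop(sprintf("invalid range for %s", nm))
  }
  n <- nPositive + nControl
  if (n == 0L) return(list())
  draws <- withSeed(seed, {
    list(diamPos = stats::runif(nPositive, rg$diameterRange[1], rg$diameterRange[2]),
         diamCtl = stats::runif(nControl, rg$controlDiameterRange[1],
                                rg$controlDiameterRange[2]),
         contrast = stats::runif(nPositive, rg$contrastRange[1], rg$contrastRange[2]),
         nLesions = sample(seq.int(rg$lesionCountRange[1], rg$lesionCountRange[2]),
                           max(nPositive, 1L), replace = TRUE),
         seeds = sample.int(.Machine$integer.max - 1L, n))
  })
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    pos <- i <= nPositive
    spec <- phantomSpec(
      gridShape = rg$gridShape,
      voxelSize = rg$voxelSize,
      aneurysmRadius = if (pos) draws$diamPos[i] / 2
                       else draws$diamCtl[i - nPositive] / 2,
      lesionCount = if (pos) draws$nLesions[i] else 0L,
      lesionContrast = if (pos) draws$contrast[i] else 1,
      lesionRadius = rg$lesionRadius,
      noiseScale = rg$noiseScale,
      seed = draws$seeds[i])
    subjects[[i]] <- generateSubject(spec)
  }
  subjects
}
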