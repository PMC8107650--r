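#' @import methods
#' @importClassesFrom Matrix dgCMatrix
NULL

#' VoxelImage: a 2D voxel grid with physical spacing
#'
#' Container for all image-domain quantities: activity images (lambda),
#' anatomical guidance images, coefficient images (alpha) and attenuation maps.
#' Values are stored column-major, so voxel j of the vectorised image is
#' \code{values[j]} with \code{j = i1 + (i2-1)*dim[1]}.
#'
#' @slot values numeric matrix of voxel values.
#' @slot spacing numeric(2), voxel size in mm per axis.
#' @export
setClass("VoxelImage",
  representation(values = "matrix", spacing = "numeric"),
  validity = function(object) {
    if (length(object@spacing) != 2L || any(object@spacing <= 0))
      return("spacing must be two positive voxel sizes (mm)")
    if (!is.numeric(object@values)) return("values must be numeric")
    if (any(!is.finite(object@values))) return("values must be finite")
    TRUE
  })

#' Sinogram: PET projection data
#'
#' One row per projection angle, one column per radial bin. Each element is the
#' count (or expected count) on one line of response.
#'
#' @slot values numeric matrix, angles x radial bins.
#' @slot angles numeric, projection angles in radians.
#' @slot radialSpacing numeric(1), radial bin width in mm.
#' @export
setClass("Sinogram",
  representation(values = "matrix", angles = "numeric", radialSpacing = "numeric"),
  validity = function(object) {
    if (nrow(object@values) != length(object@angles))
      return("one row of values per angle required")
    if (any(!is.finite(object@values))) return("sinogram values must be finite")
    if (any(object@values < 0)) return("sinogram values must be nonnegative")
    if (object@radialSpacing <= 0) return("radialSpacing must be positive")
    TRUE
  })

#' SystemModel: projector geometry, PSF and subset partition
#'
#' Embodies the system matrix c_ij as a sparse parallel-beam Radon projector
#' with an image-space Gaussian PSF. The sparse matrix maps vectorised blurred
#' images to vectorised sinograms; subsets are disjoint groups of angle indices
#' for ordered-subsets algorithms.
#'
#' @slot imageDim integer(2) image grid.
#' @slot spacing numeric(2) voxel size (mm).
#' @slot angles numeric projection angles (radians).
#' @slot nRadial integer(1) number of radial bins.
#' @slot radialSpacing numeric(1) radial bin width (mm).
#' @slot psfFwhm numeric(1) in-plane PSF FWHM (mm).
#' @slot subsets list of integer vectors partitioning the angle indices.
#' @slot P dgCMatrix sparse geometric projector (nLOR x nVoxel).
#' @slot blur1,blur2 matrix separable PSF convolution operators (zero-padded,
#'   hence self-adjoint); 1x1 identity when psfFwhm = 0.
#' @slot attenuation numeric per-LOR multiplicative attenuation factors
#'   (length 0 when attenuation is off).
#' @export
setClass("SystemModel",
  representation(imageDim = "integer", spacing = "numeric", angles = "numeric",
                 nRadial = "integer", radialSpacing = "numeric",
                 psfFwhm = "numeric", subsets = "list", P = "dgCMatrix",
                 blur1 = "matrix", blur2 = "matrix", attenuation = "numeric"),
  validity = function(object) {
    if (object@psfFwhm < 0) return("psfFwhm must be >= 0")
    idx <- sort(unlist(object@subsets))
    if (!identical(as.integer(idx), seq_along(object@angles)))
      return("subsets must partition the angle indices disjointly")
    nLor <- length(object@angles) * object@nRadial
    if (nrow(object@P) != nLor || ncol(object@P) != prod(object@imageDim))
      return("projector matrix dimensions inconsistent with geometry")
    if (length(object@attenuation) && length(object@attenuation) != nLor)
      return("attenuation factors must have one entry per LOR")
    TRUE
  })

#' KernelModel: sparse neighbour structure and kernel weights
#'
#' Realises the kernel matrix K of the kernelized image model lambda = K alpha
#' as a per-voxel list of neighbours f and weights k_fj. The anatomical kernel,
#' the functional kernel and their hybrid product all share this container and
#' the same sparsity pattern.
#'
#' @slot neighbors integer matrix (nVoxel x nNeighbors): voxel indices f for
#'   each voxel j; column 1 is always j itself.
#' @slot weights numeric matrix of kernel values k_fj, same shape.
#' @slot spatialDist2 numeric matrix of squared voxel-coordinate distances
#'   between j and each neighbour (voxel units; reused by the functional kernel).
#' @slot imageDim integer(2); @slot spacing numeric(2).
#' @slot normalized logical(1): rows scaled to sum to 1.
#' @slot kmat dgCMatrix the same operator as a sparse matrix, with element
#'   (j, f) equal to k_fj.
#' @export
setClass("KernelModel",
  representation(neighbors = "matrix", weights = "matrix",
                 spatialDist2 = "matrix", imageDim = "integer",
                 spacing = "numeric", normalized = "logical", kmat = "dgCMatrix"),
  validity = function(object) {
    if (!identical(dim(object@neighbors), dim(object@weights)))
      return("neighbors and weights must have identical shape")
    if (any(object@weights < 0)) return("kernel weights must be nonnegative")
    if (!all(object@neighbors[, 1] == seq_len(nrow(object@neighbors))))
      return("each voxel must be its own first neighbour")
    if (isTRUE(object@normalized)) {
      rs <- rowSums(object@weights)
      if (any(abs(rs - 1) > 1e-12)) return("normalized rows must sum to 1")
    }
    TRUE
  })

#' RoiSet: the three analysis regions
#'
#' Logical masks on the image grid for the target aneurysm region (T), the
#' non-aneurysmal aorta (A) and the blood-pool / vena cava reference (B).
#' The three masks must be pairwise disjoint and nonempty.
#'
#' @slot target,aorta,blood logical matrices on the image grid.
#' @export
setClass("RoiSet",
  representation(target = "matrix", aorta = "matrix", blood = "matrix"),
  validity = function(object) {
    for (nm in c("target", "aorta", "blood")) {
      m <- slot(object, nm)
      if (!is.logical(m)) return(sprintf("%s mask must be logical", nm))
      if (!any(m)) return(sprintf("%s mask is empty", nm))
    }
    if (any(object@target & object@aorta) || any(object@target & object@blood) ||
        any(object@aorta & object@blood))
      return("ROI masks must be pairwise disjoint")
    TRUE
  })

#' PhantomSpec: parametric description of one synthetic abdominal slice
#'
#' Defines the geometry and tracer-uptake ratios of a 2D axial abdominal
#' phantom: spine (hot bone uptake), aneurysmal aorta cross-section with
#' calcified micro-lesions in the wall, a normal aorta cross-section and the
#' vena cava blood pool. All lengths are in mm; activities are unitless ratios.
#'
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", voxelSize = "numeric",
                 aortaCenter = "numeric", aortaRadius = "numeric",
                 aortaLumenRadius = "numeric",
                 aneurysmCenter = "numeric", aneurysmRadius = "numeric",
                 lumenFraction = "numeric",
                 spineCenter = "numeric", spineRadius = "numeric",
                 spineMargin = "numeric",
                 venaCavaCenter = "numeric", venaCavaRadius = "numeric",
                 lesionCount = "integer", lesionRadius = "numeric",
                 lesionContrast = "numeric",
                 spineActivity = "numeric", backgroundActivity = "numeric",
                 bloodActivity = "numeric", wallActivity = "numeric",
                 anatomicalBlurFwhm = "numeric", noiseScale = "numeric",
                 seed = "integer"),
  validity = function(object) {
    radii <- c(object@aortaRadius, object@aortaLumenRadius, object@aneurysmRadius,
               object@spineRadius, object@venaCavaRadius, object@lesionRadius)
    if (any(radii <= 0)) return("all radii must be positive")
    if (object@lesionContrast < 1) return("lesionContrast must be >= 1")
    if (object@lesionCount < 0) return("lesionCount must be >= 0")
    if (object@noiseScale <= 0) return("noiseScale (expected counts) must be > 0")
    if (object@lumenFraction <= 0 || object@lumenFraction >= 1)
      return("lumenFraction must be in (0, 1)")
    fov <- object@gridShape * object@voxelSize / 2
    inside <- function(center, radius)
      all(abs(center) + radius <= fov)
    if (!inside(object@aortaCenter, object@aortaRadius) ||
        !inside(object@aneurysmCenter, object@aneurysmRadius) ||
        !inside(object@spineCenter, object@spineRadius) ||
        !inside(object@venaCavaCenter, object@venaCavaRadius))
      return("a phantom structure extends outside the image grid")
    sep <- function(c1, r1, c2, r2) sqrt(sum((c1 - c2)^2)) > r1 + r2
    if (!sep(object@aneurysmCenter, object@aneurysmRadius,
             object@spineCenter, object@spineRadius))
      return("aneurysm overlaps the spine")
    if (!sep(object@aneurysmCenter, object@aneurysmRadius,
             object@aortaCenter, object@aortaRadius))
      return("aneurysm overlaps the normal aorta section")
    if (!sep(object@aneurysmCenter, object@aneurysmRadius,
             object@venaCavaCenter, object@venaCavaRadius))
      return("aneurysm overlaps the vena cava")
    if (!sep(object@aortaCenter, object@aortaRadius,
             object@venaCavaCenter, object@venaCavaRadius))
      return("normal aorta overlaps the vena cava")
    TRUE
  })

#' SubjectData: one synthetic subject
#'
#' @slot anatomical CT-like guidance image.
#' @slot activityTruth ground-truth tracer activity.
#' @slot rois RoiSet on the same grid.
#' @slot label logical, TRUE for an AAA-positive subject.
#' @slot aneurysmDiameter mm.
#' @slot spec the generating PhantomSpec.
#' @export
setClass("SubjectData",
  representation(anatomical = "VoxelImage", activityTruth = "VoxelImage",
                 rois = "RoiSet", label = "logical",
                 aneurysmDiameter = "numeric", spec = "PhantomSpec"),
  validity = function(object) {
    if (!identical(dim(object@anatomical@values), dim(object@activityTruth@values)))
      return("anatomical and activity grids must match")
    if (!identical(dim(object@rois@target), dim(object@activityTruth@values)))
      return("ROI masks must live on the image grid")
    TRUE
  })

#' ReconResult: output of an iterative reconstruction
#'
#' @slot images list of VoxelImage, the activity estimate lambda^(n) after each
#'   full iteration (post-filtered for OSEM+G).
#' @slot alpha numeric final coefficient vector.
#' @slot logLik numeric Poisson log-likelihood (up to a data-dependent
#'   constant) after each full iteration.
#' @slot algorithm character: "osem", "kem" or "hkem".
#' @slot config list of the settings used.
#' @export
setClass("ReconResult",
  representation(images = "list", alpha = "numeric", logLik = "numeric",
                 algorithm = "character", config = "list"),
  validity = function(object) {
    if (any(object@alpha < 0)) return("coefficients must be nonnegative")
    if (length(object@images) != length(object@logLik))
      return("one stored image per completed full iteration")
    TRUE
  })
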