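# Generics and accessors.

#' @rdname VoxelImage-class
#' @param object,x a VoxelImage
#' @export
setGeneric("imgValues", function(x) standardGeneric("imgValues"))
#' @rdname VoxelImage-class
#' @export
setMethod("imgValues", "VoxelImage", function(x) x@values)

#' @rdname VoxelImage-class
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname VoxelImage-class
#' @export
setMethod("voxelSpacing", "VoxelImage", function(x) x@spacing)

#' @rdname VoxelImage-class
#' @export
setGeneric("imgDim", function(x) standardGeneric("imgDim"))
#' @rdname VoxelImage-class
#' @export
setMethod("imgDim", "VoxelImage", function(x) dim(x@values))

#' @rdname Sinogram-class
#' @param x a Sinogram
#' @export
setGeneric("sinoValues", function(x) standardGeneric("sinoValues"))
#' @rdname Sinogram-class
#' @export
setMethod("sinoValues", "Sinogram", function(x) x@values)

#' @rdname RoiSet-class
#' @param x a RoiSet
#' @export
setGeneric("roiTarget", function(x) standardGeneric("roiTarget"))
#' @rdname RoiSet-class
#' @export
setMethod("roiTarget", "RoiSet", function(x) x@target)
#' @rdname RoiSet-class
#' @export
setGeneric("roiAorta", function(x) standardGeneric("roiAorta"))
#' @rdname RoiSet-class
#' @export
setMethod("roiAorta", "RoiSet", function(x) x@aorta)
#' @rdname RoiSet-class
#' @export
setGeneric("roiBlood", function(x) standardGeneric("roiBlood"))
#' @rdname RoiSet-class
#' @export
setMethod("roiBlood", "RoiSet", function(x) x@blood)

#' Forward projection (generic)
#'
#' @param image image-domain object
#' @param model a SystemModel
#' @param subset optional subset index
#' @export
setGeneric("forwardProject",
           function(image, model, subset = NULL) standardGeneric("forwardProject"))

#' Back projection (generic)
#'
#' @param sino projection-domain object
#' @param model a SystemModel
#' @param subset optional subset index
#' @export
setGeneric("backProject",
           function(sino, model, subset = NULL) standardGeneric("backProject"))

#' Apply a kernel model (generic): lambda = K alpha
#'
#' @param k a KernelModel
#' @param alpha coefficient image
#' @export
setGeneric("applyKernel", function(k, alpha) standardGeneric("applyKernel"))

#' Apply the adjoint of a kernel model (generic): K^T image
#'
#' @param k a KernelModel
#' @param image image-domain object
#' @export
setGeneric("applyKernelAdjoint",
           function(k, image) standardGeneric("applyKernelAdjoint"))

#' Per-iteration image of a reconstruction (generic)
#'
#' @param x a ReconResult
#' @param i full-iteration index (1-based); defaults to the last iteration.
#' @export
setGeneric("iterationImage",
           function(x, i = length(x@images)) standardGeneric("iterationImage"))
#' @rdname iterationImage
#' @export
setMethod("iterationImage", "ReconResult", function(x, i = length(x@images)) {
  if (i < 1L || i > length(x@images)) stop("iteration index out of range")
  x@images[[i]]
})

setMethod("show", "VoxelImage", function(object) {
  d <- dim(object@values)
  cat(sprintf("VoxelImage %dx%d, %.3gx%.3g mm voxels, range [%.4g, %.4g]\n",
              d[1], d[2], object@spacing[1], object@spacing[2],
              min(object@values), max(object@values)))
})

setMethod("show", "Sinogram", function(object) {
  cat(sprintf("Sinogram: %d angles x %d radial bins (%.3g mm), total counts %.6g\n",
              nrow(object@values), ncol(object@values), object@radialSpacing,
              sum(object@values)))
})

setMethod("show", "SystemModel", function(object) {
  cat(sprintf(paste0("SystemModel: %dx%d grid (%.3g mm), %d angles x %d bins, ",
                     "PSF %.3g mm FWHM, %d subset(s)%s\n"),
              object@imageDim[1], object@imageDim[2], object@spacing[1],
              length(object@angles), object@nRadial, object@psfFwhm,
              length(object@subsets),
              if (length(object@attenuation)) ", attenuated" else ""))
})

setMethod("show", "KernelModel", function(object) {
  cat(sprintf("KernelModel: %d voxels x %d neighbours%s\n",
              nrow(object@neighbors), ncol(object@neighbors),
              if (isTRUE(object@normalized)) ", row-normalized" else ""))
})

setMethod("show", "SubjectData", function(object) {
  cat(sprintf("SubjectData: %s, aneurysm diameter %.1f mm, grid %dx%d\n",
              if (object@label) "AAA-positive" else "control",
              object@aneurysmDiameter,
              dim(object@activityTruth@values)[1],
              dim(object@activityTruth@values)[2]))
})

setMethod("show", "ReconResult", function(object) {
  cat(sprintf("ReconResult: %s, %d full iteration(s), final logLik %.6g\n",
              toupper(object@algorithm), length(object@images),
              object@logLik[length(object@logLik)]))
})

#' Construct a VoxelImage
#'
#' @param values numeric matrix (or vector with dim attribute).
#' @param spacing voxel size in mm, recycled to length 2.
#' @return a VoxelImage
#' @export
voxelImage <- function(values, spacing = c(1, 1)) {
  new("VoxelImage", values = as.matrix(values),
      spacing = rep(as.numeric(spacing), length.out = 2L))
}

#' Construct a RoiSet from three logical masks
#'
#' @param target,aorta,blood logical matrices (T, A and B regions).
#' @return a RoiSet
#' @export
roiSet <- function(target, aorta, blood)
  new("RoiSet", target = target, aorta = aorta, blood = blood)
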