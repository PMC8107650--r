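# NIfTI image and label-map I/O, sinogram I/O (NIfTI + YAML sidecar) and
# experiment configuration files.

#' Read a NIfTI image as a VoxelImage
#'
#' @param path path to a NIfTI-1 file.
#' @return a VoxelImage with voxel spacing from the file's pixdim
#' @export
readImage <- function(path) {
  if (!file.exists(path)) stop(sprintf("image file not found: %s", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf("failed to read %s: %s",
                                                   path, conditionMessage(e))))
  a <- as.array(img)
  d <- dim(a)[dim(a) > 1L]
  stopIfNot2dGrid(d)
  voxelImage(matrix(as.numeric(a), d[1], d[2]), RNifti::pixdim(img)[1:2])
}

#' Write a VoxelImage as NIfTI
#'
#' @param image a VoxelImage.
#' @param path output path (.nii or .nii.gz).
#' @return the path, invisibly
#' @export
writeImage <- function(image, path) {
  nif <- RNifti::asNifti(image@values)
  RNifti::pixdim(nif) <- image@spacing
  RNifti::writeNifti(nif, path)
  invisible(path)
}

#' Write a stack of per-iteration images as a 3D NIfTI
#'
#' Third dimension indexes the stored full iterations of a ReconResult.
#'
#' @param result a ReconResult; @param path output path.
#' @return the path, invisibly
#' @export
writeReconResult <- function(result, path) {
  arr <- simplify2array(lapply(result@images, function(i) i@values))
  sp <- result@images[[1]]@spacing
  nif <- RNifti::asNifti(arr)
  RNifti::pixdim(nif) <- c(sp, 1)
  RNifti::writeNifti(nif, path)
  invisible(path)
}

#' Convert an integer label map to a RoiSet
#'
#' Label conventions: 1 = target (T), 2 = non-AAA aorta (A), 3 = blood pool
#' (B).
#'
#' @param labelImage VoxelImage of integer labels.
#' @param reference optional VoxelImage whose geometry the labels must match
#'   (mismatched grid or spacing is a hard error).
#' @return a RoiSet
#' @export
roiSetFromLabels <- function(labelImage, reference = NULL) {
  if (!is.null(reference)) {
    if (!identical(dim(labelImage@values), dim(reference@values)) ||
        any(abs(labelImage@spacing - reference@spacing) > 1e-6))
      stop("label map geometry does not match the reference image")
  }
  v <- round(labelImage@values)
  roiSet(target = v == 1, aorta = v == 2, blood = v == 3)
}

#' Write a RoiSet as an integer label map
#'
#' @param rois a RoiSet; @param spacing voxel spacing (mm);
#' @param path output path.
#' @return the path, invisibly
#' @export
writeRoiLabels <- function(rois, spacing, path) {
  lab <- matrix(0, nrow(rois@target), ncol(rois@target))
  lab[rois@target] <- 1; lab[rois@aorta] <- 2; lab[rois@blood] <- 3
  writeImage(voxelImage(lab, spacing), path)
}

#' Write a sinogram (NIfTI values + YAML geometry sidecar)
#'
#' @param sino a Sinogram; @param path output path ending in .nii or .nii.gz;
#'   the sidecar gets the same path with a .yaml extension appended.
#' @return the path, invisibly
#' @export
writeSinogram <- function(sino, path) {
  nif <- RNifti::asNifti(sino@values)
  RNifti::writeNifti(nif, path)
  yaml::write_yaml(list(angles = as.numeric(sino@angles),
                        radial_spacing_mm = sino@radialSpacing),
                   paste0(path, ".yaml"), precision = 15L)
  invisible(path)
}

#' Read a sinogram written by [writeSinogram()]
#'
#' @param path the NIfTI path (a .yaml sidecar must sit next to it).
#' @return a Sinogram
#' @export
readSinogram <- function(path) {
  side <- paste0(path, ".yaml")
  if (!file.exists(side)) stop(sprintf("missing sinogram sidecar: %s", side))
  meta <- yaml::read_yaml(side)
  a <- as.array(RNifti::readNifti(path))
  d <- dim(a)[dim(a) > 1L]
  v <- matrix(as.numeric(a), d[1], d[2])
  new("Sinogram", values = v, angles = as.numeric(meta$angles),
      radialSpacing = as.numeric(meta$radial_spacing_mm))
}
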