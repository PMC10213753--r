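# NIfTI-1 volume I/O. Coordinate convention throughout the package:
# 0-based voxel indices, physical position = index * spacing, identity
# orientation (no direction-matrix handling).

#' Write a 3D volume as NIfTI-1
#'
#' @param data 3D numeric or integer array.
#' @param spacing numeric(3) voxel spacing in mm, stored in the header.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype "float" for images, "uint8" for label volumes.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(data, spacing, path, datatype = "float") {
  img <- RNifti::asNifti(data * 1)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path path to the volume.
#' @return list with `data` (plain array) and `spacing` (numeric(3), mm).
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim(img)),
       spacing = as.numeric(RNifti::pixdim(img))[1:3])
}
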