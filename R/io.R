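#' Read/write image volumes as NIfTI
#'
#' Thin wrappers around RNifti keeping the package's plain-array + affine
#' convention. Uncompressed `.nii` is written so output bytes depend only on
#' the data (no archive timestamps), which the run manifest relies on.
#'
#' @param vol 3D or 4D numeric array.
#' @param path output path (`.nii`).
#' @param voxel_mm voxel size (mm) for the first three dimensions.
#' @rdname nifti_io
#' @export
write_volume_nifti <- function(vol, path, voxel_mm = c(1, 1, 1)) {
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- c(voxel_mm, rep(1, length(dim(vol)) - 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attr(arr, "voxel_mm") <- RNifti::pixdim(img)[seq_len(min(3, length(dim(arr))))]
  arr
}
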