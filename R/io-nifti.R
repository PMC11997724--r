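#' @include grid.R
NULL

#' Write a LesionMask as NIfTI-1
#'
#' @param mask a \linkS4class{LesionMask}.
#' @param path output path (.nii or .nii.gz).
#' @export
writeLesionMask <- function(mask, path) {
  arr <- maskArray(mask)
  storage.mode(arr) <- "integer"
  img <- RNifti::asNifti(arr)
  A <- worldAffine(mask)
  RNifti::pixdim(img) <- sqrt(colSums(A[1:3, 1:3]^2))
  img <- RNifti::`qform<-`(img, structure(A, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI lesion mask
#'
#' Honors the qform/sform affine as exposed by RNifti; any nonzero voxel is
#' treated as lesion.
#'
#' @param path path to a .nii/.nii.gz binary mask.
#' @return a \linkS4class{LesionMask}.
#' @export
readLesionMask <- function(path) {
  img <- RNifti::readNifti(path)
  A <- unclass(RNifti::xform(img))
  attributes(A) <- list(dim = dim(A))
  arr <- array(as.integer(as.array(img) != 0), dim = dim(img))
  lesionMask(arr, A)
}
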