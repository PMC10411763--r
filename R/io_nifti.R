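#' Read / write NIfTI-1 volumes with quantitation preserved
#'
#' The internal world frame is the scanner/LPS convention (as in DICOM);
#' NIfTI stores RAS, so reading and writing applies an explicit x/y axis
#' flip to the affine — values and grid layout are untouched. Scale factors
#' (`scl_slope`/`scl_inter`) are honoured in both directions: values
#' returned to R are always in true stored units. This contract is what
#' precludes the classic conversion bug in which mis-handled scale factors
#' inflate counts by large factors.
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param value_kind value kind to stamp on the volume (NIfTI does not
#'   record it).
#' @param acquisition_time_h optional acquisition time to attach.
#' @return `read_nifti_volume`: a [volume3d()].
#' @export
read_nifti_volume <- function(path, value_kind = "counts",
                              acquisition_time_h = NA_real_) {
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  if (hdr$scl_slope == 0)
    message("NIfTI scale slope is 0/unset; treating it as 1 (values taken as stored)")
  A <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  flip <- diag(c(-1, -1, 1))
  R <- flip %*% A[1:3, 1:3]
  spacing <- sqrt(colSums(R^2))
  orientation <- sweep(R, 2, spacing, "/")
  origin <- drop(flip %*% A[1:3, 4])
  vals <- array(as.numeric(img), dim(img)[1:3])
  if (value_kind != "HU") vals <- pmax(vals, 0)
  volume3d(vals, spacing = spacing, origin = origin,
           orientation = orientation, value_kind = value_kind,
           acquisition_time_h = acquisition_time_h)
}

#' @rdname read_nifti_volume
#' @param volume a [volume3d()].
#' @param datatype on-disk datatype (default `"double"`, lossless;
#'   `"int16"` engages RNifti's slope/intercept quantization).
#' @return `write_nifti_volume`: `path`, invisibly.
#' @export
write_nifti_volume <- function(volume, path, datatype = "double") {
  img <- RNifti::asNifti(volume$values)
  RNifti::pixdim(img) <- volume$spacing
  flip <- diag(c(-1, -1, 1))
  A <- diag(4)
  A[1:3, 1:3] <- flip %*% volume$orientation %*% diag(volume$spacing)
  A[1:3, 4] <- drop(flip %*% volume$origin)
  RNifti::sform(img) <- structure(A, code = 2L)
  RNifti::qform(img) <- structure(A, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
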