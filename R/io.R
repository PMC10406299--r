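## NIfTI-1 input/output, via RNifti.  Volumes and masks are 3D images;
## displacement fields are stored as 4D images with the last axis holding
## the (u, v, t) components.  The world affine is preserved on write.

.check_nifti_path <- function(path) {
    if (!is.character(path) || length(path) != 1L || !file.exists(path))
        stop("not a readable file: ", path, call. = FALSE)
}

#' Read a 3D NIfTI volume
#'
#' No intensity rescaling is applied beyond the NIfTI scl slope/intercept
#' handled by the reader.
#'
#' @param path path to a .nii or .nii.gz file containing a 3D image.
#' @return A [Volume-class].
#' @export
readVolume <- function(path) {
    .check_nifti_path(path)
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e) stop("cannot read NIfTI file '", path,
                                             "': ", conditionMessage(e),
                                             call. = FALSE))
    if (length(dim(img)) != 3L)
        stop("expected a 3D image, got ", length(dim(img)), "D: ", path,
             call. = FALSE)
    aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
    Volume(array(as.numeric(img), dim = dim(img)),
           spacing = abs(RNifti::pixdim(img))[1:3],
           affine = matrix(as.numeric(aff), 4L, 4L))
}

#' Write a Volume to NIfTI
#'
#' @param vol a [Volume-class].
#' @param path output path (.nii or .nii.gz).
#' @param datatype NIfTI storage type, e.g. "double" or "uint8".
#' @return The path, invisibly.
#' @export
writeVolume <- function(vol, path, datatype = "double") {
    stopifnot(is(vol, "Volume") || is(vol, "BinaryMask"))
    dat <- voxelData(vol)
    sp <- if (is(vol, "Volume")) vol@spacing else c(1, 1, 1)
    img <- RNifti::asNifti(dat)
    RNifti::pixdim(img) <- sp
    if (is(vol, "Volume"))
        img <- RNifti::`sform<-`(img, structure(vol@affine, code = 2L))
    RNifti::writeNifti(img, path, datatype = datatype)
    invisible(path)
}

#' Read a binary mask from NIfTI
#'
#' Nonzero voxels become 1.
#'
#' @param path path to a 3D NIfTI file.
#' @return A [BinaryMask-class].
#' @export
readMask <- function(path) {
    BinaryMask(voxelData(readVolume(path)) != 0)
}

#' Write a BinaryMask to NIfTI (uint8)
#'
#' @param mask a [BinaryMask-class].
#' @param path output path.
#' @param spacing voxel size in mm written to the header.
#' @return The path, invisibly.
#' @export
writeMask <- function(mask, path, spacing = c(1, 1, 1)) {
    stopifnot(is(mask, "BinaryMask"))
    img <- RNifti::asNifti(mask@data)
    RNifti::pixdim(img) <- spacing
    RNifti::writeNifti(img, path, datatype = "uint8")
    invisible(path)
}

#' Write a DisplacementField to NIfTI (4D, last axis = component)
#'
#' @param field a [DisplacementField-class].
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeField <- function(field, path) {
    stopifnot(is(field, "DisplacementField"))
    img <- RNifti::asNifti(field@field)
    RNifti::pixdim(img) <- c(field@spacing, 1)
    RNifti::writeNifti(img, path, datatype = "double")
    invisible(path)
}

#' Read a DisplacementField from a 4D NIfTI file
#'
#' @param path path to a 4D NIfTI file whose last axis has 3 components.
#' @return A [DisplacementField-class].
#' @export
readField <- function(path) {
    .check_nifti_path(path)
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 4L || d[4L] != 3L)
        stop("expected a 4D field with 3 components: ", path, call. = FALSE)
    DisplacementField(array(as.numeric(img), dim = d),
                      spacing = abs(RNifti::pixdim(img))[1:3])
}
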