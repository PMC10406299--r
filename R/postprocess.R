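## Post-detection cleanup: small-component filtering, parenchyma masking
## and signed split of the change map.

.label_comps <- function(maskArr, connectivity = 26L) {
    array(c_label_components(as.integer(maskArr), as.integer(dim(maskArr)),
                             as.integer(connectivity)),
          dim = dim(maskArr))
}

#' Remove connected components below a physical volume
#'
#' Components (26-connected by default) whose physical volume is smaller
#' than `minVolume` mm^3 are discarded; a component of exactly the
#' threshold volume is kept.
#'
#' @param c a [BinaryMask-class] change map.
#' @param spacing voxel size in mm (length 3 or 1).
#' @param minVolume minimum component volume in mm^3 (default 3).
#' @param connectivity 6, 18 or 26 (default 26).
#' @return The filtered [BinaryMask-class].
#' @export
filterSmallComponents <- function(c, spacing = c(1, 1, 1), minVolume = 3,
                                  connectivity = 26L) {
    stopifnot(is(c, "BinaryMask"), all(spacing > 0))
    if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
    lab <- .label_comps(c@data, connectivity)
    if (max(lab) == 0L) return(c)
    voxVol <- prod(spacing)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes * voxVol >= minVolume)
    BinaryMask(array(lab %in% keep, dim = dim(c@data)))
}

#' Restrict a change map to the brain parenchyma
#'
#' @param c a [BinaryMask-class] change map.
#' @param parenchyma a same-grid [BinaryMask-class] (union of gray and
#'   white matter).
#' @return The voxelwise AND of the two masks as a [BinaryMask-class].
#' @export
applyParenchymaMask <- function(c, parenchyma) {
    stopifnot(is(c, "BinaryMask"), is(parenchyma, "BinaryMask"))
    if (!all(dim(c@data) == dim(parenchyma@data)))
        stop("shape mismatch between change map and parenchyma mask",
             call. = FALSE)
    BinaryMask(c@data * parenchyma@data)
}

#' Split a change map by intensity change sign
#'
#' @param c a [BinaryMask-class] change map.
#' @param I1 baseline [Volume-class].
#' @param I2w warped follow-up [Volume-class].
#' @return list with `positive` (c AND I2w > I1) and `negative`
#'   (c AND I2w < I1) [BinaryMask-class] maps; equal-intensity voxels
#'   belong to neither.
#' @export
splitSigned <- function(c, I1, I2w) {
    stopifnot(is(c, "BinaryMask"), is(I1, "Volume"), is(I2w, "Volume"))
    d <- I2w@data - I1@data
    list(positive = BinaryMask(c@data * (d > 0)),
         negative = BinaryMask(c@data * (d < 0)))
}
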