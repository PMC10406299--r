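## Backward warping, gradients, smoothing and multiresolution pyramids.

#' Backward-warp a Volume by a DisplacementField
#'
#' Computes out(x) = I(x - w(x)) by trilinear interpolation.  Samples that
#' fall outside the grid use border replication and are flagged invalid in
#' the returned mask, so data terms and metrics can exclude them.
#'
#' @param I a [Volume-class].
#' @param w a [DisplacementField-class] of the same grid shape (voxel
#'   units).
#' @return list with elements `volume` (warped [Volume-class]) and `valid`
#'   (a [BinaryMask-class] of in-grid samples).
#' @export
warpBackward <- function(I, w) {
    stopifnot(is(I, "Volume"), is(w, "DisplacementField"))
    d <- dim(I@data)
    if (!all(d == dim(w@field)[1:3]))
        stop("volume and field shapes differ", call. = FALSE)
    res <- c_warp_backward(as.numeric(I@data), as.integer(d),
                           as.numeric(w@field[, , , 1L]),
                           as.numeric(w@field[, , , 2L]),
                           as.numeric(w@field[, , , 3L]))
    list(volume = Volume(array(res$data, dim = d), spacing = I@spacing,
                         affine = I@affine),
         valid = BinaryMask(array(res$valid, dim = d)))
}

## Reindex an array along one dimension.
.index_dim <- function(a, d, ord) {
    sel <- list(TRUE, TRUE, TRUE)
    sel[[d]] <- ord
    do.call(`[`, c(list(a), sel, list(drop = FALSE)))
}

#' Spatial gradient of a Volume
#'
#' Central differences in the interior, one-sided at the boundaries, in
#' intensity-per-voxel units.
#'
#' @param I a [Volume-class] with every dimension >= 2.
#' @return 4D array with the last axis holding the 3 partial derivatives.
#' @export
spatialGradient <- function(I) {
    stopifnot(is(I, "Volume"))
    a <- I@data
    d <- dim(a)
    if (any(d < 2L)) stop("each dimension must be >= 2", call. = FALSE)
    g <- array(0, dim = c(d, 3L))
    for (k in 1:3) {
        n <- d[k]
        ip <- pmin(seq_len(n) + 1L, n)
        im <- pmax(seq_len(n) - 1L, 1L)
        num <- .index_dim(a, k, ip) - .index_dim(a, k, im)
        g[, , , k] <- sweep(num, k, ip - im, "/")
    }
    g
}

## Separable Gaussian smoothing of a 3D array (replicate boundary).
.gaussian_smooth <- function(a, sigma) {
    if (sigma <= 0) return(a)
    r <- max(1L, as.integer(ceiling(3 * sigma)))
    k <- dnorm(seq(-r, r), sd = sigma)
    k <- k / sum(k)
    d <- dim(a)
    out <- as.numeric(a)
    for (ax in 0:2)
        out <- c_conv_dim(out, as.integer(d), k, ax)
    array(out, dim = d)
}

## Trilinear resample onto a new shape; src coordinate = dst index * scale
## (0-based, anchored at index 0).
.resample_scale <- function(a, outShape, scale) {
    array(c_resample_scale(as.numeric(a), as.integer(dim(a)),
                           as.integer(outShape), as.numeric(scale)),
          dim = outShape)
}

#' Build a coarse-to-fine Gaussian pyramid
#'
#' Each coarser level is Gaussian-smoothed (sigma = 0.8 * factor voxels,
#' a standard anti-aliasing choice) then subsampled; level 1 of the
#' returned stack is the coarsest, the last level is the source.
#'
#' @param I a [Volume-class].
#' @param levels number of levels (>= 1).
#' @param factor per-level downsampling ratio (> 1).
#' @return A [Pyramid-class]; coarsest level first.
#' @export
buildPyramid <- function(I, levels, factor = 2) {
    stopifnot(is(I, "Volume"), levels >= 1)
    if (levels > 1 && factor <= 1) stop("factor must be > 1", call. = FALSE)
    shapes <- vector("list", levels)
    shapes[[levels]] <- dim(I@data)
    if (levels > 1)
        for (l in (levels - 1):1)
            shapes[[l]] <- as.integer(ceiling(shapes[[l + 1]] / factor))
    if (any(shapes[[1L]] < 4L))
        stop("coarsest pyramid level smaller than 4 voxels per axis; ",
             "reduce the level count", call. = FALSE)
    out <- vector("list", levels)
    out[[levels]] <- I
    if (levels > 1) {
        for (l in (levels - 1):1) {
            src <- out[[l + 1L]]
            sm <- .gaussian_smooth(src@data, 0.8 * factor)
            dat <- .resample_scale(sm, shapes[[l]], rep(factor, 3L))
            out[[l]] <- Volume(dat, spacing = src@spacing * factor,
                               affine = src@affine %*% diag(c(rep(factor, 3), 1)))
        }
    }
    new("Pyramid", levels = out, factor = factor)
}

## Downsample a binary mask to a coarser shape (trilinear + 0.5 threshold).
.resize_mask <- function(mask, outShape) {
    a <- voxelData(mask)
    if (all(dim(a) == outShape)) return(mask)
    scale <- dim(a) / outShape
    BinaryMask(.resample_scale(a + 0, outShape, scale) >= 0.5)
}

## Conservative downsampling for change maps: a coarse voxel is masked
## when *any* fine-level change voxel falls in its footprint (dilate by
## the scale factor, then sample).  Majority downsampling would let small
## lesions vanish at coarse pyramid levels, re-exposing them to the data
## term there.
.resize_change_mask <- function(mask, outShape) {
    a <- voxelData(mask)
    if (all(dim(a) == outShape)) return(mask)
    scale <- dim(a) / outShape
    dil <- c_dilate_ball(as.integer(a), as.integer(dim(a)),
                         as.numeric(ceiling(max(scale))))
    BinaryMask(.resample_scale(array(dil, dim = dim(a)) + 0, outShape,
                               scale) >= 0.5)
}

## Resample a field to an arbitrary shape, rescaling voxel-unit values by
## the per-axis shape ratio (used for both prolongation and restriction).
.resize_field <- function(w, targetShape) {
    src <- dim(w@field)[1:3]
    targetShape <- as.integer(targetShape)
    if (all(src == targetShape)) return(w)
    ratio <- targetShape / src
    out <- array(0, dim = c(targetShape, 3L))
    for (k in 1:3)
        out[, , , k] <- ratio[k] *
            .resample_scale(w@field[, , , k], targetShape, src / targetShape)
    DisplacementField(out, spacing = w@spacing * src / targetShape)
}

#' Prolong a DisplacementField to a finer grid
#'
#' Each component is trilinearly upsampled and multiplied by the per-axis
#' shape ratio, since displacements are stored in voxel units at the
#' field's own resolution.
#'
#' @param w a [DisplacementField-class].
#' @param targetShape finer grid dimensions (length 3, each >= source).
#' @return A [DisplacementField-class] on the target grid.
#' @export
prolongField <- function(w, targetShape) {
    stopifnot(is(w, "DisplacementField"),
              all(targetShape >= dim(w@field)[1:3]))
    .resize_field(w, targetShape)
}
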