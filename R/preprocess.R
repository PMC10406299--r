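## Harmonization of the image pair: intensity scaling to a median of 100
## inside the brain mask, resampling to 1 mm isotropic, differential
## bias-field correction (median-filtered log ratio), robust residual
## scale, and a plumbing-grade affine pre-alignment.

#' Scale a Volume so its in-mask median intensity equals a target
#'
#' @param I a [Volume-class].
#' @param mask a non-empty [BinaryMask-class] (brain mask).
#' @param target target median intensity (default 100).
#' @return list with `volume` (scaled [Volume-class]) and `scale` (the
#'   multiplicative factor applied).
#' @export
normalizeMedianIntensity <- function(I, mask, target = 100) {
    stopifnot(is(I, "Volume"), is(mask, "BinaryMask"))
    inm <- mask@data == 1L
    if (!any(inm)) stop("mask is empty", call. = FALSE)
    med <- median(I@data[inm])
    if (!is.finite(med) || med <= 0)
        stop("non-positive in-mask median intensity; cannot normalize",
             call. = FALSE)
    s <- target / med
    list(volume = Volume(I@data * s, spacing = I@spacing, affine = I@affine),
         scale = s)
}

#' Resample a Volume to isotropic resolution
#'
#' Trilinear resampling onto a grid of the given target spacing covering
#' the same world extent; the affine is updated accordingly.
#'
#' @param I a [Volume-class].
#' @param target target isotropic spacing in mm (default 1).
#' @return A resampled [Volume-class].
#' @export
resampleIsotropic <- function(I, target = 1) {
    stopifnot(is(I, "Volume"), target > 0)
    scale <- target / I@spacing
    if (all(abs(scale - 1) < 1e-12)) return(I)
    outShape <- pmax(1L, as.integer(ceiling(dim(I@data) / scale)))
    dat <- .resample_scale(I@data, outShape, scale)
    Volume(dat, spacing = rep(target, 3L),
           affine = I@affine %*% diag(c(scale, 1)))
}

#' Differential bias-field correction of a longitudinal pair
#'
#' Removes the smooth multiplicative intensity discrepancy between two
#' scans of the same subject: the log-ratio log(I2/I1) is median-filtered
#' with a cubic kernel inside the brain mask (a robust smooth estimate of
#' the differential bias field), and I2 is divided by its exponential.
#' Voxels outside the mask are left uncorrected.
#'
#' @param I1,I2 same-grid [Volume-class] pair with positive in-mask
#'   intensities.
#' @param mask a [BinaryMask-class] (brain mask).
#' @param kernel odd cubic median-filter size in voxels (default 21).
#' @return The corrected I2 as a [Volume-class].
#' @export
differentialBiasCorrection <- function(I1, I2, mask, kernel = 21L) {
    stopifnot(is(I1, "Volume"), is(I2, "Volume"), is(mask, "BinaryMask"),
              kernel %% 2 == 1, kernel >= 1)
    d <- dim(I1@data)
    if (!all(d == dim(I2@data))) stop("shape mismatch", call. = FALSE)
    inm <- mask@data == 1L
    if (any(I1@data[inm] <= 0) || any(I2@data[inm] <= 0))
        stop("non-positive intensities inside the mask; cannot take log ratio",
             call. = FALSE)
    r <- array(0, dim = d)
    r[inm] <- log(I2@data[inm] / I1@data[inm])
    m <- c_masked_median_filter(as.numeric(r), as.integer(mask@data),
                                as.integer(d), as.integer((kernel - 1) / 2))
    Volume(I2@data / exp(array(m, dim = d)), spacing = I2@spacing,
           affine = I2@affine)
}

#' Robust residual scale (MAD of in-mask intensity differences)
#'
#' sigma = median(|d - median(d)|) over in-mask voxels, where d is the
#' voxelwise difference between the (warped) follow-up and the baseline.
#' The result is floored at a machine-scale positive constant so degenerate
#' identical pairs remain usable.
#'
#' @param I1 baseline [Volume-class].
#' @param I2w (warped) follow-up [Volume-class] on the same grid.
#' @param mask a non-empty [BinaryMask-class].
#' @return Positive scalar sigma.
#' @export
estimateSigma <- function(I1, I2w, mask) {
    stopifnot(is(I1, "Volume"), is(I2w, "Volume"), is(mask, "BinaryMask"))
    inm <- mask@data == 1L
    if (!any(inm)) stop("mask is empty", call. = FALSE)
    d <- I2w@data[inm] - I1@data[inm]
    s <- median(abs(d - median(d)))
    max(s, 1e-8)
}

## ---- plumbing-grade affine pre-alignment --------------------------------

## 3x4 voxel-coordinate transform from 12 parameters (translation,
## rotation in radians, log-scale, shear), applied about the grid center.
.affine_matrix <- function(par, center) {
    tr <- par[1:3]
    rot <- par[4:6]
    sc <- exp(par[7:9])
    sh <- par[10:12]
    cx <- cos(rot[1]); sx <- sin(rot[1])
    cy <- cos(rot[2]); sy <- sin(rot[2])
    cz <- cos(rot[3]); sz <- sin(rot[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
    S <- diag(sc)
    H <- matrix(c(1, 0, 0, sh[1], 1, 0, sh[2], sh[3], 1), 3, 3)
    M <- Rz %*% Ry %*% Rx %*% S %*% H
    b <- center - M %*% center + tr
    cbind(M, b)
}

.ncc <- function(a, b) {
    a <- a - mean(a); b <- b - mean(b)
    den <- sqrt(sum(a^2) * sum(b^2))
    if (den == 0) return(0)
    sum(a * b) / den
}

.affine_resample <- function(dat, A) {
    array(c_warp_affine(as.numeric(dat), as.integer(dim(dat)), A),
          dim = dim(dat))
}

#' Affine pre-alignment of a longitudinal pair
#'
#' A simple multiresolution derivative-free optimizer (Nelder-Mead over
#' translation, then rigid, then full 12-parameter affine) of negative
#' normalized cross-correlation.  This is pipeline plumbing for inputs
#' that are not already aligned; it makes no claim of parity with
#' dedicated registration tools.
#'
#' @param I1 fixed baseline [Volume-class].
#' @param I2 moving follow-up [Volume-class] on the same grid.
#' @param maxit Nelder-Mead iteration cap per stage.
#' @return list with `affine` (3x4 voxel-coordinate matrix mapping I1 grid
#'   coordinates into I2), `params` (the 12 parameters) and `volume` (I2
#'   resampled onto I1's grid).
#' @export
affinePrealign <- function(I1, I2, maxit = 300L) {
    stopifnot(is(I1, "Volume"), is(I2, "Volume"))
    d <- dim(I1@data)
    center <- (d - 1) / 2
    ## coarse then half-resolution grids keep the search cheap and smooth
    lv <- max(1L, min(3L, floor(log2(min(d) / 16))))
    pyr1 <- buildPyramid(I1, lv + 1L, 2)@levels
    pyr2 <- buildPyramid(I2, lv + 1L, 2)@levels
    par <- rep(0, 12)
    stages <- list(1:3, 1:6, 1:12)
    ## skip full-resolution refinement on large grids (NCC evals get costly)
    useLevels <- if (min(d) > 80) seq_len(lv) else seq_len(lv + 1L)
    res <- tryCatch({
        for (li in useLevels) {
            f1 <- pyr1[[li]]@data
            f2 <- pyr2[[li]]@data
            dl <- dim(f1)
            cl <- (dl - 1) / 2
            sc <- d / dl            # voxel-size ratio w.r.t. full resolution
            for (st in stages) {
                obj <- function(p) {
                    full <- par
                    full[st] <- p
                    pl <- full
                    pl[1:3] <- full[1:3] / sc  # translation in level voxels
                    A <- .affine_matrix(pl, cl)
                    -.ncc(f1, .affine_resample(f2, A))
                }
                psc <- c(rep(1, 3), rep(0.05, 9))[st]
                opt <- optim(par[st], obj, method = "Nelder-Mead",
                             control = list(maxit = maxit, parscale = psc))
                par[st] <- opt$par
            }
        }
        A <- .affine_matrix(par, center)
        list(affine = A, params = par,
             volume = Volume(.affine_resample(I2@data, A),
                             spacing = I1@spacing, affine = I1@affine))
    }, error = function(e) {
        warning("affine pre-alignment failed (", conditionMessage(e),
                "); returning identity", call. = FALSE)
        A <- .affine_matrix(rep(0, 12), center)
        list(affine = A, params = rep(0, 12), volume = I2)
    })
    res
}
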