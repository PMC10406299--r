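## Core S4 containers for the volumetric pipeline.

#' Volume: a 3D scalar image
#'
#' Holds one 3D scalar grid together with its voxel spacing (mm) and its
#' 4x4 voxel-to-world affine.  This is the container for the baseline and
#' follow-up scans and for every derived scalar image.
#'
#' @slot data 3D numeric array of intensities.
#' @slot spacing numeric(3), voxel size along each axis in mm.
#' @slot affine 4x4 voxel-to-world matrix (0-based voxel indices).
#' @export
setClass("Volume",
    representation(data = "array", spacing = "numeric", affine = "matrix"),
    validity = function(object) {
        d <- dim(object@data)
        if (length(d) != 3L) return("data must be a 3D array")
        if (any(d < 1L)) return("all dimensions must be >= 1")
        if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
            any(object@spacing <= 0)) return("spacing must be 3 positive values")
        if (!all(dim(object@affine) == c(4L, 4L))) return("affine must be 4x4")
        if (!all(is.finite(object@data))) return("data values must be finite")
        TRUE
    })

#' DisplacementField: a dense per-voxel 3-vector field
#'
#' Displacements are stored in voxel units at the field's own resolution
#' (processing is at 1 mm isotropic, so voxel units and mm coincide).  The
#' warping convention is backward: a field w maps the follow-up I2 to
#' I2(x - w(x)).
#'
#' @slot field 4D numeric array; last axis holds the (u, v, t) components.
#' @slot spacing numeric(3), voxel size in mm.
#' @export
setClass("DisplacementField",
    representation(field = "array", spacing = "numeric"),
    validity = function(object) {
        d <- dim(object@field)
        if (length(d) != 4L || d[4L] != 3L)
            return("field must be a 4D array with 3 components")
        if (!all(is.finite(object@field))) return("components must be finite")
        if (length(object@spacing) != 3L || any(object@spacing <= 0))
            return("spacing must be 3 positive values")
        TRUE
    })

#' BinaryMask: a 3D binary label grid
#'
#' Container for the change map c and for brain/parenchyma masks.
#'
#' @slot data 3D integer array with values exactly 0 or 1.
#' @export
setClass("BinaryMask",
    representation(data = "array"),
    validity = function(object) {
        if (length(dim(object@data)) != 3L) return("data must be a 3D array")
        if (!all(object@data %in% c(0L, 1L)))
            return("mask values must be exactly 0 or 1")
        TRUE
    })

#' Pyramid: a coarse-to-fine stack of Volumes
#'
#' @slot levels list of Volumes ordered coarsest to finest.
#' @slot factor per-level downsampling ratio (> 1).
#' @export
setClass("Pyramid",
    representation(levels = "list", factor = "numeric"),
    validity = function(object) {
        if (length(object@levels) < 1L) return("at least one level required")
        if (!all(vapply(object@levels, is, TRUE, class2 = "Volume")))
            return("levels must be Volumes")
        TRUE
    })

#' ResidualModel: per-voxel linearization of the intensity data term
#'
#' Coefficients of the linearized residual g(x)' w(x) + It(x): the spatial
#' gradient g of the warped follow-up, the temporal difference It (shifted
#' so the residual is linear in the *total* field), the robust scale sigma
#' (MAD of in-mask intensity differences) and the warp validity mask.
#'
#' @slot g 4D array, per-voxel gradient 3-vector.
#' @slot it 3D array, temporal difference at the linearization point.
#' @slot sigma positive scalar, robust residual scale.
#' @slot valid 3D 0/1 array flagging in-grid warp samples.
#' @export
setClass("ResidualModel",
    representation(g = "array", it = "array", sigma = "numeric",
                   valid = "array"),
    validity = function(object) {
        if (!all(is.finite(object@g)) || !all(is.finite(object@it)))
            return("g and it must be finite")
        if (length(object@sigma) != 1L || object@sigma <= 0)
            return("sigma must be a positive scalar")
        TRUE
    })

#' SolverConfig: all hyperparameters and solver knobs
#'
#' lambda1 weighs the Tikhonov field regularizer, lambda2 is the intensity
#' change threshold, lambda3 weighs the Potts change-map regularizer.  mu
#' is the ADMM penalty.  Defaults follow the published setting: lambda1 =
#' 70, (lambda2, lambda3) = (16, 5), ADMM tolerance 2e-3 / cap 300, outer
#' tolerance 1e-3 / cap 5.
#'
#' @slot lambda1,lambda2,lambda3 nonnegative energy weights.
#' @slot mu positive ADMM penalty.
#' @slot pyramidLevels,pyramidFactor,warpsPerLevel coarse-to-fine schedule.
#' @slot admmTol,admmMaxIter inner (ADMM) stopping rule.
#' @slot outerTol,outerMaxIter outer (alternation) stopping rule.
#' @export
setClass("SolverConfig",
    representation(lambda1 = "numeric", lambda2 = "numeric",
                   lambda3 = "numeric", mu = "numeric",
                   pyramidLevels = "integer", pyramidFactor = "numeric",
                   warpsPerLevel = "integer",
                   admmTol = "numeric", admmMaxIter = "integer",
                   outerTol = "numeric", outerMaxIter = "integer"),
    validity = function(object) {
        if (object@lambda1 < 0 || object@lambda2 < 0 || object@lambda3 < 0)
            return("lambda weights must be nonnegative")
        if (object@mu <= 0) return("mu must be positive")
        if (object@admmTol <= 0 || object@outerTol <= 0)
            return("tolerances must be positive")
        if (object@admmMaxIter < 1L || object@outerMaxIter < 1L ||
            object@pyramidLevels < 1L || object@warpsPerLevel < 1L)
            return("iteration caps must be >= 1")
        if (object@pyramidFactor <= 1 && object@pyramidLevels > 1L)
            return("pyramid factor must be > 1")
        TRUE
    })

#' RunResult: output of one detection pipeline run
#'
#' @slot field the final DisplacementField.
#' @slot changeMap the final binary change map.
#' @slot energyTrace coupled-energy value at each outer iteration.
#' @slot flipTrace fraction of change-map labels flipped at each iteration.
#' @slot iterations number of outer iterations performed.
#' @slot method one of "joint", "sequential", "affine".
#' @export
setClass("RunResult",
    representation(field = "DisplacementField", changeMap = "BinaryMask",
                   energyTrace = "numeric", flipTrace = "numeric",
                   iterations = "integer", method = "character"),
    validity = function(object) {
        if (!object@method %in% c("joint", "sequential", "affine"))
            return("method must be joint, sequential or affine")
        if (length(object@energyTrace) != object@iterations)
            return("energy trace length must equal iteration count")
        TRUE
    })

## ---- constructors -------------------------------------------------------

#' Create a Volume
#'
#' @param data 3D numeric array.
#' @param spacing voxel size in mm (length 3, recycled from length 1).
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   scaling by `spacing`.
#' @return A [Volume-class] object.
#' @export
Volume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
    if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
    storage.mode(data) <- "double"
    if (is.null(affine)) affine <- diag(c(spacing, 1))
    new("Volume", data = data, spacing = as.numeric(spacing),
        affine = affine)
}

#' Create a DisplacementField
#'
#' @param field either a 4D array (last axis = component) or the u
#'   component as a 3D array.
#' @param v,t remaining components when `field` is 3D.
#' @param spacing voxel size in mm.
#' @return A [DisplacementField-class] object.
#' @export
DisplacementField <- function(field, v = NULL, t = NULL,
                              spacing = c(1, 1, 1)) {
    if (length(dim(field)) == 3L) {
        stopifnot(!is.null(v), !is.null(t))
        field <- array(c(field, v, t), dim = c(dim(field), 3L))
    }
    if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
    storage.mode(field) <- "double"
    new("DisplacementField", field = field, spacing = as.numeric(spacing))
}

#' Create an all-zero DisplacementField
#'
#' @param shape grid dimensions (length 3).
#' @param spacing voxel size in mm.
#' @return A zero [DisplacementField-class].
#' @export
zeroField <- function(shape, spacing = c(1, 1, 1)) {
    DisplacementField(array(0, dim = c(shape, 3L)), spacing = spacing)
}

#' Create a BinaryMask
#'
#' @param data 3D array coercible to 0/1 (logical or numeric).
#' @return A [BinaryMask-class] object.
#' @export
BinaryMask <- function(data) {
    d <- dim(data)
    data <- array(as.integer(data != 0), dim = d)
    new("BinaryMask", data = data)
}

## ---- accessors ----------------------------------------------------------

#' Extract the voxel array of a volumetric object
#' @param x a Volume, BinaryMask, DisplacementField or ResidualModel.
#' @return The underlying array.
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname voxelData
#' @export
setMethod("voxelData", "Volume", function(x) x@data)

#' @rdname voxelData
#' @export
setMethod("voxelData", "BinaryMask", function(x) x@data)

#' @rdname voxelData
#' @export
setMethod("voxelData", "DisplacementField", function(x) x@field)

#' Voxel spacing in mm
#' @param x a Volume or DisplacementField.
#' @return numeric(3) voxel size.
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname spacing
#' @export
setMethod("spacing", "Volume", function(x) x@spacing)

#' @rdname spacing
#' @export
setMethod("spacing", "DisplacementField", function(x) x@spacing)

#' Voxel-to-world affine of a Volume
#' @param x a Volume.
#' @return 4x4 matrix.
#' @export
setGeneric("worldAffine", function(x) standardGeneric("worldAffine"))

#' @rdname worldAffine
#' @export
setMethod("worldAffine", "Volume", function(x) x@affine)

#' One component of a DisplacementField
#' @param x a DisplacementField.
#' @param i component index (1 = u, 2 = v, 3 = t).
#' @return 3D array.
#' @export
fieldComponent <- function(x, i) {
    stopifnot(is(x, "DisplacementField"), i %in% 1:3)
    x@field[, , , i, drop = TRUE]
}

#' Grid dimensions of a volumetric object
#' @param x a Volume, BinaryMask or DisplacementField.
#' @return integer(3).
#' @export
gridDim <- function(x) {
    if (is(x, "DisplacementField")) dim(x@field)[1:3] else dim(voxelData(x))
}

#' Final change map of a run
#' @param x a RunResult.
#' @return A [BinaryMask-class].
#' @export
changeMap <- function(x) { stopifnot(is(x, "RunResult")); x@changeMap }

#' Final displacement field of a run
#' @param x a RunResult.
#' @return A [DisplacementField-class].
#' @export
displacementField <- function(x) { stopifnot(is(x, "RunResult")); x@field }

#' Coupled-energy trace of a run
#' @param x a RunResult.
#' @return numeric vector, one value per outer iteration.
#' @export
energyTrace <- function(x) { stopifnot(is(x, "RunResult")); x@energyTrace }

## ---- show methods -------------------------------------------------------

setMethod("show", "Volume", function(object) {
    d <- dim(object@data)
    cat(sprintf("Volume %dx%dx%d, spacing %s mm, range [%.4g, %.4g]\n",
                d[1], d[2], d[3],
                paste(signif(object@spacing, 3), collapse = "x"),
                min(object@data), max(object@data)))
})

setMethod("show", "DisplacementField", function(object) {
    d <- dim(object@field)
    mag <- sqrt(rowSums(matrix(object@field, ncol = 3L)^2))
    cat(sprintf("DisplacementField %dx%dx%d, max |w| = %.3f voxels\n",
                d[1], d[2], d[3], max(mag)))
})

setMethod("show", "BinaryMask", function(object) {
    d <- dim(object@data)
    cat(sprintf("BinaryMask %dx%dx%d, %d foreground voxels\n",
                d[1], d[2], d[3], sum(object@data)))
})

setMethod("show", "SolverConfig", function(object) {
    cat(sprintf(paste0(
        "SolverConfig: lambda1=%g lambda2=%g lambda3=%g mu=%g\n",
        "  pyramid %d levels x%g, %d warps/level\n",
        "  ADMM tol %g cap %d; outer tol %g cap %d\n"),
        object@lambda1, object@lambda2, object@lambda3, object@mu,
        object@pyramidLevels, object@pyramidFactor, object@warpsPerLevel,
        object@admmTol, object@admmMaxIter,
        object@outerTol, object@outerMaxIter))
})

setMethod("show", "RunResult", function(object) {
    cat(sprintf(paste0(
        "RunResult (%s): %d outer iteration(s), %d change voxels\n",
        "  final energy %.6g\n"),
        object@method, object@iterations, sum(object@changeMap@data),
        if (object@iterations > 0) object@energyTrace[object@iterations]
        else NA_real_))
})
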