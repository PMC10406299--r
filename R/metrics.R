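## Evaluation: voxel-wise DSC / PPV / TPR, local DSC in a dilated
## ground-truth neighborhood, lesion-wise detection metrics, and the
## no-change summary.

#' Voxel-wise detection metrics
#'
#' DSC = 2TP/(2TP+FP+FN), PPV = TP/(TP+FP), TPR = TP/(TP+FN), computed
#' over the evaluation mask.  Ratios with a zero denominator are returned
#' as NaN.
#'
#' @param c estimated [BinaryMask-class] change map.
#' @param gt ground-truth [BinaryMask-class].
#' @param mask optional evaluation [BinaryMask-class]; NULL = whole grid.
#' @return list with `dsc`, `ppv`, `tpr` and the confusion counts `tp`,
#'   `tn`, `fp`, `fn`.
#' @export
voxelMetrics <- function(c, gt, mask = NULL) {
    stopifnot(is(c, "BinaryMask"), is(gt, "BinaryMask"))
    if (!all(dim(c@data) == dim(gt@data)))
        stop("shape mismatch", call. = FALSE)
    sel <- if (is.null(mask)) TRUE else mask@data == 1L
    ce <- c@data[sel]
    ge <- gt@data[sel]
    tp <- sum(ce == 1L & ge == 1L)
    fp <- sum(ce == 1L & ge == 0L)
    fn <- sum(ce == 0L & ge == 1L)
    tn <- sum(ce == 0L & ge == 0L)
    ratio <- function(num, den) if (den == 0) NaN else num / den
    list(dsc = ratio(2 * tp, 2 * tp + fp + fn),
         ppv = ratio(tp, tp + fp),
         tpr = ratio(tp, tp + fn),
         tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Local DSC inside a dilation of the ground truth
#'
#' DSC restricted to the morphological dilation of the ground truth by a
#' Euclidean ball (default radius 4 voxels), focusing the evaluation on
#' local spatial accuracy rather than remote false positives.
#'
#' @param c estimated [BinaryMask-class].
#' @param gt ground-truth [BinaryMask-class].
#' @param radius dilation ball radius in voxels (default 4).
#' @return Scalar local DSC; NaN when the ground truth is empty.
#' @export
localDSC <- function(c, gt, radius = 4) {
    stopifnot(is(c, "BinaryMask"), is(gt, "BinaryMask"))
    if (!all(dim(c@data) == dim(gt@data)))
        stop("shape mismatch", call. = FALSE)
    if (sum(gt@data) == 0L) return(NaN)
    dil <- array(c_dilate_ball(as.integer(gt@data),
                               as.integer(dim(gt@data)),
                               as.numeric(radius)),
                 dim = dim(gt@data))
    voxelMetrics(c, gt, BinaryMask(dil))$dsc
}

#' Lesion-wise detection metrics
#'
#' Connected components (18-connected by default, following common MS
#' lesion evaluation conventions) of the ground truth count as detected
#' when at least `overlap` of their voxels are covered by the estimate;
#' estimated components count as true when at least `overlap` of their
#' voxels lie on ground truth.  L-TPR = detected / total ground-truth
#' components; L-PPV = true / total estimated components.
#'
#' @param c estimated [BinaryMask-class].
#' @param gt ground-truth [BinaryMask-class].
#' @param overlap minimum overlap fraction (default 0.1).
#' @param connectivity component connectivity (default 18).
#' @return list with `ltpr`, `lppv`, `nTruth`, `nEstimated`, `nDetected`,
#'   `nTrue`.
#' @export
lesionMetrics <- function(c, gt, overlap = 0.1, connectivity = 18L) {
    stopifnot(is(c, "BinaryMask"), is(gt, "BinaryMask"))
    if (!all(dim(c@data) == dim(gt@data)))
        stop("shape mismatch", call. = FALSE)
    labG <- .label_comps(gt@data, connectivity)
    labE <- .label_comps(c@data, connectivity)
    nG <- max(labG)
    nE <- max(labE)
    compFrac <- function(lab, n, other) {
        if (n == 0L) return(numeric(0))
        tot <- tabulate(lab[lab > 0L], nbins = n)
        hit <- tabulate(lab[lab > 0L & other == 1L], nbins = n)
        hit / tot
    }
    det <- sum(compFrac(labG, nG, c@data) >= overlap)
    tru <- sum(compFrac(labE, nE, gt@data) >= overlap)
    list(ltpr = if (nG == 0L) NaN else det / nG,
         lppv = if (nE == 0L) NaN else tru / nE,
         nTruth = nG, nEstimated = nE, nDetected = det, nTrue = tru)
}

#' Summary of detections when no ground-truth change exists
#'
#' @param c a [BinaryMask-class] change map.
#' @param spacing voxel size in mm.
#' @param connectivity component connectivity (default 26).
#' @return list with `components` (count) and `volume` (total detected
#'   volume in cm^3).
#' @export
noChangeSummary <- function(c, spacing = c(1, 1, 1), connectivity = 26L) {
    stopifnot(is(c, "BinaryMask"))
    if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
    lab <- .label_comps(c@data, connectivity)
    list(components = max(lab),
         volume = sum(c@data) * prod(spacing) / 1000)
}
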