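## Outer drivers: alternating joint minimization, and the sequential and
## affine baselines.

.run_result <- function(field, cm, energy, flips, iters, method) {
    new("RunResult", field = field, changeMap = cm,
        energyTrace = energy, flipTrace = flips,
        iterations = as.integer(iters), method = method)
}

#' Joint registration and change detection
#'
#' Alternating minimization of the coupled energy: starting from c = 0
#' and w = 0, each outer iteration re-solves the field subproblem with
#' the current change map masked out of the data term (full coarse-to-fine
#' schedule, initialized from the previous field), then re-solves the
#' change-map subproblem by graph cut at the current field.  Stops when
#' the relative RMS field change drops below `cfg@outerTol` (default 1e-3)
#' and the fraction of flipped change labels drops below the same
#' tolerance, or after `cfg@outerMaxIter` (default 5) iterations.  The
#' coupled energy is recorded at every iteration.
#'
#' @param I1 preprocessed baseline [Volume-class].
#' @param I2 preprocessed follow-up [Volume-class], same grid.
#' @param mask brain [BinaryMask-class] (NULL = whole grid).
#' @param cfg a [SolverConfig-class].
#' @return A [RunResult-class] with method "joint".
#' @export
runJoint <- function(I1, I2, mask = NULL, cfg = solverConfig()) {
    d <- dim(I1@data)
    cm <- BinaryMask(array(0L, dim = d))
    w <- zeroField(d, spacing = I1@spacing)
    nMask <- if (is.null(mask)) prod(d) else max(sum(mask@data), 1)
    energy <- numeric(0)
    flips <- numeric(0)
    wPrev <- w@field
    iters <- 0L
    ## sigma is estimated during the first alternation and then frozen, so
    ## later alternations perform block-coordinate descent on one fixed
    ## objective (re-estimating it every iteration rescales the energy
    ## between iterations and breaks trace comparability)
    sigmaRef <- NULL
    ## after the first alternation the field is refined at full resolution
    ## only: restricting the converged field to a coarse grid and
    ## re-running the pyramid loses detail the alternation already earned
    cfgRefine <- cfg
    cfgRefine@pyramidLevels <- 1L
    for (k in seq_len(cfg@outerMaxIter)) {
        iters <- k
        wNew <- if (k == 1L)
            registerDeformable(I1, I2, cm, cfg, mask)
        else
            registerDeformable(I1, I2, cm, cfgRefine, mask, wInit = w,
                               sigma = sigmaRef)
        cmNew <- detectChanges(I1, I2, wNew, cfg, mask, sigma = sigmaRef)
        if (is.null(sigmaRef)) sigmaRef <- attr(cmNew, "sigma")
        eNew <- jointEnergy(I1, I2, wNew, cmNew, cfg, mask,
                            sigma = sigmaRef)
        if (k > 1L && eNew > energy[k - 1L]) {
            ## safeguard: the linearized field step overshot the coupled
            ## energy; keep the previous iterate and stop (converged up
            ## to the surrogate's accuracy)
            energy <- c(energy, energy[k - 1L])
            flips <- c(flips, 0)
            break
        }
        energy <- c(energy, eNew)
        flip <- sum(cmNew@data != cm@data) / nMask
        flips <- c(flips, flip)
        relW <- sqrt(mean((wNew@field - wPrev)^2)) /
            (sqrt(mean(wPrev^2)) + 1e-12)
        cm <- cmNew
        w <- wNew
        wPrev <- w@field
        if (relW < cfg@outerTol && flip < cfg@outerTol) break
    }
    .run_result(w, cm, energy, flips, iters, "joint")
}

#' Sequential baseline: register once, then detect once
#'
#' One unmasked deformable registration (c = 0) followed by one change
#' detection; no alternation.  This is the conventional pipeline the
#' joint method is compared against, and is exactly the first iteration
#' of [runJoint].
#'
#' @inheritParams runJoint
#' @return A [RunResult-class] with method "sequential".
#' @export
runSequential <- function(I1, I2, mask = NULL, cfg = solverConfig()) {
    d <- dim(I1@data)
    cm0 <- BinaryMask(array(0L, dim = d))
    w <- registerDeformable(I1, I2, cm0, cfg, mask)
    cm <- detectChanges(I1, I2, w, cfg, mask)
    e <- jointEnergy(I1, I2, w, cm, cfg, mask, sigma = attr(cm, "sigma"))
    nMask <- if (is.null(mask)) prod(d) else max(sum(mask@data), 1)
    .run_result(w, cm, e, sum(cm@data) / nMask, 1L, "sequential")
}

#' Affine baseline: no deformable registration
#'
#' Change detection on the (optionally affinely pre-aligned) pair with a
#' zero displacement field — the most common clinical pipeline.
#'
#' @inheritParams runJoint
#' @param prealign when TRUE, run [affinePrealign] on the pair first; when
#'   FALSE (default) the inputs are assumed already affinely aligned.
#' @return A [RunResult-class] with method "affine".
#' @export
runAffine <- function(I1, I2, mask = NULL, cfg = solverConfig(),
                      prealign = FALSE) {
    d <- dim(I1@data)
    if (prealign) I2 <- affinePrealign(I1, I2)$volume
    w <- zeroField(d, spacing = I1@spacing)
    cm <- detectChanges(I1, I2, w, cfg, mask)
    e <- jointEnergy(I1, I2, w, cm, cfg, mask, sigma = attr(cm, "sigma"))
    nMask <- if (is.null(mask)) prod(d) else max(sum(mask@data), 1)
    .run_result(w, cm, e, sum(cm@data) / nMask, 1L, "affine")
}
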