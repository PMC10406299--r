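## The change-map subproblem: exact binary Potts minimization on the
## 6-connected voxel graph by max-flow/min-cut.

#' Normalized squared residual map
#'
#' rho(x) = (I2w(x) - I1(x))^2 / sigma^2 on valid voxels; 0 on invalid
#' voxels (no evidence of change outside the warp overlap).
#'
#' @param I1 baseline [Volume-class].
#' @param I2w warped follow-up [Volume-class].
#' @param sigma positive residual scale.
#' @param valid a [BinaryMask-class] of valid warp samples (NULL = all).
#' @return 3D array of residual values.
#' @export
residualMap <- function(I1, I2w, sigma, valid = NULL) {
    stopifnot(is(I1, "Volume"), is(I2w, "Volume"), sigma > 0)
    d <- dim(I1@data)
    if (!all(d == dim(I2w@data))) stop("shape mismatch", call. = FALSE)
    rho <- (I2w@data - I1@data)^2 / sigma^2
    if (!is.null(valid)) rho <- rho * valid@data
    rho
}

## Ordered (from, to) in-grid 6-neighbor voxel index pairs along one axis.
.neighbor_pairs <- function(d, ax) {
    n <- prod(d)
    idx <- array(seq_len(n), dim = d)
    from <- .index_dim(idx, ax, 1:(d[ax] - 1))
    to <- .index_dim(idx, ax, 2:d[ax])
    cbind(as.integer(from), as.integer(to))
}

#' Exact binary Potts segmentation by graph cut
#'
#' Minimizes sum_x [ lambda2 c(x) + (1 - c(x)) rho(x) ] +
#' lambda3 * (ordered-pair Potts boundary sum) over in-mask voxels;
#' out-of-mask voxels are fixed to 0.  The pairwise sum counts each
#' unordered 6-neighbor pair twice (both orderings), so each differing
#' neighbor pair costs 2 * lambda3.  With lambda3 = 0 this reduces to the
#' threshold rule c(x) = 1 iff rho(x) > lambda2 (ties resolve to 0).
#'
#' @param rho 3D array of nonnegative unary change evidence.
#' @param lambda2 positive label-1 cost (detection threshold).
#' @param lambda3 nonnegative pairwise weight.
#' @param mask optional [BinaryMask-class]; NULL = whole grid.
#' @return A [BinaryMask-class] holding the exact global minimizer.
#' @export
solvePotts <- function(rho, lambda2, lambda3, mask = NULL) {
    stopifnot(is.array(rho), lambda2 > 0, lambda3 >= 0)
    d <- dim(rho)
    if (any(rho < 0) || any(!is.finite(rho)))
        stop("unary costs must be nonnegative and finite", call. = FALSE)
    maskArr <- if (is.null(mask)) array(1L, dim = d) else mask@data
    if (lambda3 == 0)
        return(BinaryMask((rho > lambda2) & (maskArr == 1L)))
    inIdx <- which(maskArr == 1L)
    nIn <- length(inIdx)
    if (nIn == 0L) return(BinaryMask(array(0L, dim = d)))
    nodeOf <- integer(prod(d))
    nodeOf[inIdx] <- seq_len(nIn)
    s <- nIn + 1L
    t <- nIn + 2L
    ## t-links: source->x pays rho (cut when x takes label 0, i.e. sink
    ## side); x->sink pays lambda2 (cut when x takes label 1, source side)
    from <- c(rep(s, nIn), seq_len(nIn))
    to <- c(seq_len(nIn), rep(t, nIn))
    cap <- c(rho[inIdx], rep(lambda2, nIn))
    ## n-links: 2*lambda3 in both directions; a differing unordered pair
    ## contributes one cut edge, matching the ordered double-counted sum
    for (ax in 1:3) {
        if (d[ax] < 2L) next
        pr <- .neighbor_pairs(d, ax)
        keep <- maskArr[pr[, 1L]] == 1L & maskArr[pr[, 2L]] == 1L
        if (!any(keep)) next
        a <- nodeOf[pr[keep, 1L]]
        b <- nodeOf[pr[keep, 2L]]
        from <- c(from, a, b)
        to <- c(to, b, a)
        cap <- c(cap, rep(2 * lambda3, 2L * length(a)))
    }
    g <- igraph::make_graph(edges = as.vector(rbind(from, to)), n = t,
                            directed = TRUE)
    mf <- igraph::max_flow(g, source = s, target = t, capacity = cap)
    lab <- array(0L, dim = d)
    srcSide <- as.integer(mf$partition1)
    srcSide <- srcSide[srcSide <= nIn]
    lab[inIdx[srcSide]] <- 1L
    BinaryMask(lab)
}

## Potts + unary energy of a labeling, for exactness checks and tests.
.potts_label_energy <- function(cArr, rho, lambda2, lambda3, maskArr) {
    unary <- sum((cArr * lambda2 + (1 - cArr) * rho)[maskArr == 1L])
    unary + lambda3 * .potts_energy(cArr, maskArr)
}

#' Detect changes for a fixed deformation field
#'
#' Warps the follow-up by w, estimates sigma (MAD of in-mask warped
#' differences), forms the residual map and solves the Potts subproblem
#' exactly by graph cut.  Deterministic given its inputs.
#'
#' @param I1,I2 same-grid [Volume-class] pair.
#' @param w a [DisplacementField-class].
#' @param cfg a [SolverConfig-class] (lambda2, lambda3).
#' @param mask optional brain [BinaryMask-class].
#' @param sigma optional fixed residual scale (estimated when NULL).
#' @return A [BinaryMask-class] change map with attribute `sigma`.
#' @export
detectChanges <- function(I1, I2, w, cfg, mask = NULL, sigma = NULL) {
    stopifnot(is(I1, "Volume"), is(I2, "Volume"),
              is(w, "DisplacementField"), is(cfg, "SolverConfig"))
    wb <- warpBackward(I2, w)
    d <- dim(I1@data)
    maskArr <- if (is.null(mask)) array(1L, dim = d) else mask@data
    sigMask <- BinaryMask(maskArr * wb$valid@data)
    if (is.null(sigma)) sigma <- estimateSigma(I1, wb$volume, sigMask)
    rho <- residualMap(I1, wb$volume, sigma, wb$valid)
    cm <- solvePotts(rho, cfg@lambda2, cfg@lambda3,
                     if (is.null(mask)) NULL else mask)
    attr(cm, "sigma") <- sigma
    cm
}
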