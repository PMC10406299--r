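## The field subproblem: masked linearized SSD + first-order Tikhonov,
## solved by ADMM proximal splitting inside a coarse-to-fine pyramid.
##
## Scaled-form ADMM on  min  sum_x (1-c) rho_l(w, x) + lambda1 Psi(z)
##                      s.t. w = z :
##   w <- prox_{data/mu}(z - alpha/mu)        (voxelwise, closed form)
##   z <- prox_{lambda1 Psi / mu}(w + alpha/mu)  (DCT-domain linear solve)
##   alpha <- alpha + mu (w - z)

## ---- DCT-domain Tikhonov solve ------------------------------------------

## Unnormalized DCT-II along the first dimension of a matrix (N x M):
## C_k = sum_m x_m cos(pi k (m + 1/2) / N), via the N-point FFT of the
## even/odd reordered rows (Makhoul's single-length trick, valid for
## real input).
## Per-length cache of reorder indices and phase vectors.
.dct_cache <- new.env(parent = emptyenv())

.dct_consts <- function(N) {
    key <- as.character(N)
    cs <- .dct_cache[[key]]
    if (is.null(cs)) {
        cs <- list(
            fwdOrd = c(seq(1L, N, 2L), rev(seq(2L, N, 2L))),
            revOrd = c(1L, N:2L),
            phF = exp(complex(imaginary = -pi * (0:(N - 1)) / (2 * N))),
            phI = exp(complex(imaginary = pi * (0:(N - 1)) / (2 * N))),
            deEven = seq(1L, N, 2L), deOdd = seq(2L, N, 2L),
            half = ceiling(N / 2))
        .dct_cache[[key]] <- cs
    }
    cs
}

.dct2_mat <- function(X) {
    N <- nrow(X)
    if (N == 1L) return(X)
    cs <- .dct_consts(N)
    Re(cs$phF * mvfft(X[cs$fwdOrd, , drop = FALSE]))
}

## Exact inverse of .dct2_mat (normalization included).
.idct2_mat <- function(Y) {
    N <- nrow(Y)
    if (N == 1L) return(Y)
    cs <- .dct_consts(N)
    Yrev <- Y[cs$revOrd, , drop = FALSE]
    Yrev[1L, ] <- 0
    v <- Re(mvfft(cs$phI * (Y - complex(imaginary = 1) * Yrev),
                  inverse = TRUE)) / N
    out <- v
    out[cs$deEven, ] <- v[1:cs$half, , drop = FALSE]
    out[cs$deOdd, ] <- v[N:(cs$half + 1L), , drop = FALSE]
    out
}

## Eigenvalues of the 1D Neumann (path-graph) Laplacian in the DCT-II basis.
.dct_eigs <- function(n) 4 * sin(pi * (0:(n - 1)) / (2 * n))^2

## Apply a matrix transform along dimension k of a 4D field array, with
## the remaining voxel dimensions and the component axis batched into
## columns (one FFT call per dimension instead of one per component).
.dct_field_tx <- function(a4, k, fun) {
    d <- dim(a4)
    if (k == 1L) {
        m <- fun(matrix(a4, nrow = d[1L]))
        dim(m) <- d
        return(m)
    }
    perm <- c(k, setdiff(1:3, k), 4L)
    m <- matrix(aperm(a4, perm), nrow = d[k])
    m <- fun(m)
    aperm(array(m, dim = d[perm]), order(perm))
}

## Solve (I + coef * L) z = v for every component of a 4D field at once.
.dct_solve_field <- function(v, coef) {
    if (coef == 0) return(v)
    d <- dim(v)[1:3]
    for (k in 1:3) v <- .dct_field_tx(v, k, .dct2_mat)
    eig <- outer(outer(.dct_eigs(d[1]), .dct_eigs(d[2]), `+`),
                 .dct_eigs(d[3]), `+`)
    v <- v / as.vector(1 + coef * eig)   # recycled over the component axis
    for (k in 1:3) v <- .dct_field_tx(v, k, .idct2_mat)
    v
}

## Solve (I + coef * L) z = v for a 3D scalar array, L the 6-neighbor
## Neumann Laplacian, diagonalized by the 3D DCT-II.
.dct_solve <- function(v, coef) {
    d <- dim(v)
    array(.dct_solve_field(array(v, dim = c(d, 1L)), coef), dim = d)
}

## ---- linearization ------------------------------------------------------

#' Linearize the intensity data term at an expansion field
#'
#' Warps the follow-up by `w0` and expands the backward-warp residual
#' I2(x - w(x)) - I1(x) to first order in the *total* field w around w0:
#'   residual(w) ~ g' w + It,
#' with g = -grad(I2 warped by w0) (the minus sign comes from the
#' backward warp convention) and It = I2(x - w0(x)) - I1(x) - g' w0.
#' sigma is the MAD of the in-mask warped intensity differences.
#'
#' @param I1,I2 same-grid [Volume-class] pair.
#' @param w0 expansion [DisplacementField-class].
#' @param mask optional [BinaryMask-class] for the sigma estimate.
#' @param sigma optional fixed residual scale; estimated from the warped
#'   pair when NULL.
#' @return A [ResidualModel-class].
#' @export
linearize <- function(I1, I2, w0, mask = NULL, sigma = NULL) {
    stopifnot(is(I1, "Volume"), is(I2, "Volume"))
    d <- dim(I1@data)
    wb <- warpBackward(I2, w0)
    I2w <- wb$volume
    g <- -spatialGradient(I2w)
    gw0 <- g[, , , 1] * w0@field[, , , 1] +
           g[, , , 2] * w0@field[, , , 2] +
           g[, , , 3] * w0@field[, , , 3]
    it <- I2w@data - I1@data - gw0
    if (is.null(sigma)) {
        sigMask <- if (is.null(mask)) wb$valid else
            BinaryMask(mask@data * wb$valid@data)
        if (!any(sigMask@data == 1L)) sigMask <- wb$valid
        sigma <- estimateSigma(I1, I2w, sigMask)
    }
    new("ResidualModel", g = g, it = it, sigma = sigma,
        valid = wb$valid@data)
}

## ---- proximal operators -------------------------------------------------

#' Proximal step of the masked linearized data term
#'
#' Per voxel, the exact minimizer of
#'   (mu/2) ||w - v||^2 + (1 - c) (1/sigma^2) (g' w + It)^2
#' by the rank-one (Sherman-Morrison) identity.  Voxels with c = 1 or an
#' invalid warp sample return v unchanged: the data term is cancelled in
#' change regions.
#'
#' @param v input [DisplacementField-class] (the point the prox is taken
#'   at).
#' @param c a [BinaryMask-class] change map.
#' @param rm a [ResidualModel-class].
#' @param mu positive ADMM penalty.
#' @return A [DisplacementField-class].
#' @export
proxData <- function(v, c, rm, mu) {
    stopifnot(is(v, "DisplacementField"), is(c, "BinaryMask"),
              is(rm, "ResidualModel"), mu > 0)
    g1 <- rm@g[, , , 1]; g2 <- rm@g[, , , 2]; g3 <- rm@g[, , , 3]
    a <- (1 - c@data) * rm@valid * (2 / (mu * rm@sigma^2))
    v1 <- v@field[, , , 1]; v2 <- v@field[, , , 2]; v3 <- v@field[, , , 3]
    resid <- g1 * v1 + g2 * v2 + g3 * v3 + rm@it
    f <- a * resid / (1 + a * (g1^2 + g2^2 + g3^2))
    DisplacementField(v1 - f * g1, v2 - f * g2, v3 - f * g3,
                      spacing = v@spacing)
}

#' Proximal step of the Tikhonov field regularizer
#'
#' The exact minimizer of (mu/2) ||z - v||^2 + lambda1 sum ||grad z||^2,
#' solved componentwise as (I + (2 lambda1/mu) L) z = v with L the
#' 6-neighbor Neumann Laplacian, diagonalized by the discrete cosine
#' transform.
#'
#' @param v input [DisplacementField-class].
#' @param lambda1 nonnegative regularization weight.
#' @param mu positive ADMM penalty.
#' @return A [DisplacementField-class].
#' @export
proxTikhonov <- function(v, lambda1, mu) {
    stopifnot(is(v, "DisplacementField"), lambda1 >= 0, mu > 0)
    if (lambda1 == 0) return(v)
    DisplacementField(.dct_solve_field(v@field, 2 * lambda1 / mu),
                      spacing = v@spacing)
}

## ---- ADMM ---------------------------------------------------------------

#' Solve the linearized field subproblem by ADMM
#'
#' Iterates the data prox, the Tikhonov prox and the dual ascent
#' alpha <- alpha + mu (w - z); stops when the relative RMS change of w
#' between consecutive iterations drops below `cfg@admmTol` (default
#' 2e-3) or after `cfg@admmMaxIter` (default 300) iterations.  The
#' regularized iterate z is returned, so smoothness holds exactly at
#' finite iteration counts.
#'
#' @param rm a [ResidualModel-class].
#' @param c a [BinaryMask-class] change map.
#' @param wInit initial [DisplacementField-class].
#' @param cfg a [SolverConfig-class].
#' @param alphaInit optional scaled-dual warm start (4D array) from a
#'   previous solve on the same grid; NULL starts from zero.
#' @return A [DisplacementField-class] (the z iterate), with attributes
#'   `iterations`, `converged` and `alpha` (the final scaled dual, for
#'   warm-starting a subsequent solve).
#' @export
admmSolve <- function(rm, c, wInit, cfg, alphaInit = NULL) {
    stopifnot(is(rm, "ResidualModel"), is(wInit, "DisplacementField"),
              is(cfg, "SolverConfig"))
    mu <- cfg@mu
    w <- wInit
    z <- wInit
    alpha <- zeroField(dim(wInit@field)[1:3], spacing = wInit@spacing)
    if (!is.null(alphaInit)) alpha@field <- alphaInit
    wPrev <- w@field
    converged <- FALSE
    iters <- 0L
    for (k in seq_len(cfg@admmMaxIter)) {
        iters <- k
        v <- DisplacementField(z@field - alpha@field / mu,
                               spacing = w@spacing)
        w <- proxData(v, c, rm, mu)
        z <- proxTikhonov(DisplacementField(w@field + alpha@field / mu,
                                            spacing = w@spacing),
                          cfg@lambda1, mu)
        alpha@field <- alpha@field + mu * (w@field - z@field)
        nrmW <- sqrt(mean(w@field^2))
        if (nrmW > 1e6)
            stop("ADMM divergence: field RMS ", signif(nrmW, 4),
                 " at iteration ", k, call. = FALSE)
        rel <- sqrt(mean((w@field - wPrev)^2)) /
            (sqrt(mean(wPrev^2)) + 1e-12)
        wPrev <- w@field
        if (rel < cfg@admmTol) { converged <- TRUE; break }
    }
    attr(z, "iterations") <- iters
    attr(z, "converged") <- converged
    attr(z, "alpha") <- alpha@field
    z
}

## ---- coarse-to-fine driver ----------------------------------------------

#' Deformable registration with a masked data term
#'
#' Solves the field subproblem of the coupled energy: for each pyramid
#' level from coarsest to finest, the current field is prolonged, the data
#' term is (re)linearized at the current field, and the linearized convex
#' problem is solved by ADMM; linearization and solve are repeated
#' `cfg@warpsPerLevel` times per level.  Voxels with c = 1 are excluded
#' from the data term, so the field there is driven by regularization
#' only.
#'
#' @param I1 baseline [Volume-class].
#' @param I2 follow-up [Volume-class] on the same grid.
#' @param c a [BinaryMask-class] change map (all-zero for unmasked
#'   registration).
#' @param cfg a [SolverConfig-class].
#' @param mask optional brain [BinaryMask-class] used for the sigma
#'   estimate.
#' @param wInit optional full-resolution [DisplacementField-class] used to
#'   initialize the coarsest level (restricted down); NULL starts from a
#'   zero field.
#' @param sigma optional fixed residual scale passed to every
#'   linearization; NULL re-estimates per linearization.
#' @return The finest-level [DisplacementField-class].
#' @export
registerDeformable <- function(I1, I2, c, cfg, mask = NULL, wInit = NULL,
                               sigma = NULL) {
    stopifnot(is(I1, "Volume"), is(I2, "Volume"), is(c, "BinaryMask"),
              is(cfg, "SolverConfig"))
    p1 <- buildPyramid(I1, cfg@pyramidLevels, cfg@pyramidFactor)
    p2 <- buildPyramid(I2, cfg@pyramidLevels, cfg@pyramidFactor)
    L <- cfg@pyramidLevels
    w <- if (is.null(wInit))
        zeroField(dim(p1@levels[[1L]]@data),
                  spacing = p1@levels[[1L]]@spacing)
    else .resize_field(wInit, dim(p1@levels[[1L]]@data))
    for (l in seq_len(L)) {
        shape <- dim(p1@levels[[l]]@data)
        if (l > 1L) w <- prolongField(w, shape)
        cl <- .resize_change_mask(c, shape)
        ml <- if (is.null(mask)) NULL else .resize_mask(mask, shape)
        alpha <- NULL   # scaled dual carried across warps at this level
        for (it in seq_len(cfg@warpsPerLevel)) {
            rm <- linearize(p1@levels[[l]], p2@levels[[l]], w, ml, sigma)
            w <- admmSolve(rm, cl, w, cfg, alphaInit = alpha)
            alpha <- attr(w, "alpha")
        }
    }
    w
}

## ---- energy evaluation --------------------------------------------------

## Forward-difference Tikhonov energy sum ||grad w||^2 over all components.
.tikhonov_energy <- function(field) {
    e <- 0
    for (comp in 1:3) {
        a <- field[, , , comp]
        d <- dim(a)
        for (k in 1:3) {
            n <- d[k]
            if (n < 2) next
            diff <- .index_dim(a, k, 2:n) - .index_dim(a, k, 1:(n - 1))
            e <- e + sum(diff^2)
        }
    }
    e
}

## Potts energy as the ordered-pair (double-counted) sum over the
## 6-neighborhood, restricted to pairs with both voxels in the mask.
.potts_energy <- function(cArr, maskArr) {
    e <- 0
    d <- dim(cArr)
    for (k in 1:3) {
        n <- d[k]
        if (n < 2) next
        ca <- .index_dim(cArr, k, 2:n)
        cb <- .index_dim(cArr, k, 1:(n - 1))
        ma <- .index_dim(maskArr, k, 2:n)
        mb <- .index_dim(maskArr, k, 1:(n - 1))
        e <- e + 2 * sum((ca != cb) & (ma == 1) & (mb == 1))
    }
    e
}

#' Evaluate the coupled (nonlinear) energy
#'
#' The full objective: the masked nonlinearized intensity residual plus
#' lambda2 times the change volume, plus lambda1 times the Tikhonov field
#' energy, plus lambda3 times the Potts boundary energy (ordered-pair
#' sum).  Warp samples outside the grid are excluded from the data term.
#'
#' @param I1,I2 same-grid [Volume-class] pair.
#' @param w a [DisplacementField-class].
#' @param c a [BinaryMask-class] change map.
#' @param cfg a [SolverConfig-class].
#' @param mask optional brain [BinaryMask-class]: data and Potts terms are
#'   restricted to it.
#' @param sigma optional fixed residual scale; estimated from the warped
#'   pair when NULL.
#' @return Scalar energy value.
#' @export
jointEnergy <- function(I1, I2, w, c, cfg, mask = NULL, sigma = NULL) {
    stopifnot(is(I1, "Volume"), is(I2, "Volume"),
              is(w, "DisplacementField"), is(c, "BinaryMask"),
              is(cfg, "SolverConfig"))
    d <- dim(I1@data)
    wb <- warpBackward(I2, w)
    maskArr <- if (is.null(mask)) array(1L, dim = d) else mask@data
    evalMask <- wb$valid@data * maskArr
    if (is.null(sigma))
        sigma <- estimateSigma(I1, wb$volume, BinaryMask(evalMask))
    rho <- (wb$volume@data - I1@data)^2 / sigma^2
    dataTerm <- sum((1 - c@data) * rho * evalMask) +
        cfg@lambda2 * sum(c@data * maskArr)
    dataTerm + cfg@lambda1 * .tikhonov_energy(w@field) +
        cfg@lambda3 * .potts_energy(c@data, maskArr)
}
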