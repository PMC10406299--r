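# Linearization, proximal operators, ADMM and the coarse-to-fine driver.

test_that("linearization at the identity reduces to the plain difference", {
    I1 <- rand_volume(c(6, 6, 6), seed = 1)
    I2 <- rand_volume(c(6, 6, 6), seed = 2)
    rm0 <- linearize(I1, I2, zeroField(c(6, 6, 6)))
    expect_equal(rm0@it, voxelData(I2) - voxelData(I1), tolerance = 1e-12)
    ## the stored gradient carries the backward-warp sign
    expect_equal(rm0@g, -spatialGradient(I2), tolerance = 1e-12)
    ## identical images: zero temporal difference
    rmId <- linearize(I1, I1, zeroField(c(6, 6, 6)))
    expect_equal(max(abs(rmId@it)), 0)
})

test_that("linearized residual vanishes at the true shift of a linear ramp", {
    d <- c(12, 8, 8)
    s <- 1.25
    x <- rep(0:(d[1] - 1), times = prod(d[2:3]))
    I1 <- Volume(array(x, dim = d))
    I2 <- Volume(array(x + s, dim = d))   # I2(y) = I1(y) + s = I1(y + s)...
    ## I2(x - w) = I1(x) requires w = s (ramp slope 1)
    rm0 <- linearize(I1, I2, zeroField(d))
    wTrue <- array(rep(c(s, 0, 0), each = prod(d)), dim = c(d, 3))
    resid <- rm0@g[, , , 1] * wTrue[, , , 1] + rm0@it
    interior <- resid[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)]
    expect_lt(max(abs(interior)), 1e-10)
})

test_that("data prox matches a dense numeric minimizer voxel by voxel", {
    set.seed(3)
    for (rep in 1:25) {
        g <- rnorm(3)
        it <- rnorm(1)
        v <- rnorm(3)
        mu <- runif(1, 0.3, 4)
        sig <- runif(1, 0.5, 3)
        cv <- sample(0:1, 1)
        d1 <- c(1, 1, 1)
        rm1 <- new("ResidualModel", g = array(g, dim = c(d1, 3)),
                   it = array(it, dim = d1), sigma = sig,
                   valid = array(1L, dim = d1))
        out <- proxData(DisplacementField(array(v, dim = c(d1, 3))),
                        BinaryMask(array(cv, dim = d1)), rm1, mu)
        obj <- function(w)
            mu / 2 * sum((w - v)^2) +
                (1 - cv) / sig^2 * (sum(g * w) + it)^2
        ref <- optim(v, obj, method = "BFGS",
                     control = list(reltol = 1e-14))$par
        expect_lt(max(abs(as.vector(voxelData(out)) - ref)), 1e-6)
        ## prox never increases its own objective relative to the input
        expect_lte(obj(as.vector(voxelData(out))), obj(v) + 1e-12)
    }
})

test_that("data prox returns the input where the change map or mask voids it", {
    d <- c(4, 4, 4)
    rm1 <- new("ResidualModel",
               g = array(rnorm(prod(d) * 3), dim = c(d, 3)),
               it = array(rnorm(prod(d)), dim = d), sigma = 1,
               valid = array(1L, dim = d))
    v <- rand_field(d, seed = 4)
    allChange <- proxData(v, ones_mask(d), rm1, 1)
    expect_equal(voxelData(allChange), voxelData(v), tolerance = 1e-14)
    rm0 <- new("ResidualModel", g = array(0, dim = c(d, 3)),
               it = rm1@it, sigma = 1, valid = array(1L, dim = d))
    expect_equal(voxelData(proxData(v, zero_mask(d), rm0, 1)), voxelData(v),
                 tolerance = 1e-14)
})

test_that("Tikhonov prox solves the Neumann-Laplacian system exactly", {
    skip_if_not_installed("Matrix")
    set.seed(5)
    n <- c(8, 8, 8)
    N <- prod(n)
    lap1 <- function(m)
        Matrix::bandSparse(m, k = c(-1, 0, 1),
                           diag = list(rep(-1, m - 1),
                                       c(1, rep(2, m - 2), 1),
                                       rep(-1, m - 1)))
    Id <- function(m) Matrix::Diagonal(m)
    L <- kronecker(Id(n[3]), kronecker(Id(n[2]), lap1(n[1]))) +
        kronecker(Id(n[3]), kronecker(lap1(n[2]), Id(n[1]))) +
        kronecker(lap1(n[3]), kronecker(Id(n[2]), Id(n[1])))
    lambda1 <- 70; mu <- 1.3
    v <- rand_field(n, seed = 6)
    z <- proxTikhonov(v, lambda1, mu)
    for (k in 1:3) {
        ref <- Matrix::solve(Id(N) + (2 * lambda1 / mu) * L,
                             as.numeric(voxelData(v)[, , , k]))
        expect_lt(max(abs(fieldComponent(z, k) -
                          array(as.numeric(ref), dim = n))), 1e-8)
    }
    ## fixed points
    const <- DisplacementField(array(rep(c(1, 2, 3), each = N),
                                     dim = c(n, 3)))
    expect_equal(voxelData(proxTikhonov(const, 70, 1)), voxelData(const),
                 tolerance = 1e-10)
    expect_identical(voxelData(proxTikhonov(v, 0, 1)), voxelData(v))
})

test_that("ADMM reaches the generic sparse least-squares solution", {
    skip_if_not_installed("Matrix")
    set.seed(7)
    n <- c(8, 8, 8)
    N <- prod(n)
    I1 <- rand_volume(n, seed = 8)
    w0 <- rand_field(n, seed = 9, amp = 0.5)
    I2 <- Volume(voxelData(I1) + 0.3 *
                     array(rnorm(N), dim = n))
    rm0 <- linearize(I1, I2, zeroField(n))
    cmap <- BinaryMask(array(rbinom(N, 1, 0.2), dim = n))
    cfg <- solverConfig(lambda1 = 5, admmTol = 1e-8, admmMaxIter = 5000L)
    z <- admmSolve(rm0, cmap, zeroField(n), cfg)
    ## direct solve of the normal equations of
    ##   sum (1-c)/sig^2 (g'w + it)^2 + lambda1 * sum ||grad w||^2
    lap1 <- function(m)
        Matrix::bandSparse(m, k = c(-1, 0, 1),
                           diag = list(rep(-1, m - 1),
                                       c(1, rep(2, m - 2), 1),
                                       rep(-1, m - 1)))
    Id <- function(m) Matrix::Diagonal(m)
    L <- kronecker(Id(n[3]), kronecker(Id(n[2]), lap1(n[1]))) +
        kronecker(Id(n[3]), kronecker(lap1(n[2]), Id(n[1]))) +
        kronecker(lap1(n[3]), kronecker(Id(n[2]), Id(n[1])))
    a <- (1 - cmap@data) * rm0@valid / rm0@sigma^2
    g <- rm0@g
    blocks <- list()
    for (i in 1:3) for (j in 1:3)
        blocks[[paste(i, j)]] <- Matrix::Diagonal(
            x = as.numeric(a * g[, , , i] * g[, , , j]))
    A <- rbind(
        cbind(blocks[["1 1"]] + 5 * L, blocks[["1 2"]], blocks[["1 3"]]),
        cbind(blocks[["2 1"]], blocks[["2 2"]] + 5 * L, blocks[["2 3"]]),
        cbind(blocks[["3 1"]], blocks[["3 2"]], blocks[["3 3"]] + 5 * L))
    b <- -c(as.numeric(a * g[, , , 1] * rm0@it),
            as.numeric(a * g[, , , 2] * rm0@it),
            as.numeric(a * g[, , , 3] * rm0@it))
    ref <- as.numeric(Matrix::solve(A, b))
    objective <- function(wv) {
        w <- array(wv, dim = c(n, 3))
        r <- g[, , , 1] * w[, , , 1] + g[, , , 2] * w[, , , 2] +
            g[, , , 3] * w[, , , 3] + rm0@it
        sum(a * r^2) + 5 * jointchange:::.tikhonov_energy(w)
    }
    oADMM <- objective(as.numeric(voxelData(z)))
    oRef <- objective(ref)
    expect_lt(abs(oADMM - oRef) / abs(oRef), 1e-4)
})

test_that("ADMM trivia: zero data, all-change flow to Tikhonov limits", {
    n <- c(6, 6, 6)
    rmZero <- new("ResidualModel", g = array(0, dim = c(n, 3)),
                  it = array(0, dim = n), sigma = 1,
                  valid = array(1L, dim = n))
    cfg <- solverConfig()
    z <- admmSolve(rmZero, zero_mask(n), zeroField(n), cfg)
    expect_equal(max(abs(voxelData(z))), 0)
    ## c == 1 everywhere: pure Tikhonov flow contracts toward the mean
    wInit <- rand_field(n, seed = 10)
    cfgT <- solverConfig(admmTol = 1e-10, admmMaxIter = 2000L)
    zT <- admmSolve(rmZero, ones_mask(n), wInit, cfgT)
    for (k in 1:3) {
        comp <- fieldComponent(zT, k)
        expect_lt(max(abs(comp - mean(fieldComponent(wInit, k)))), 0.02)
    }
    expect_lt(jointchange:::.tikhonov_energy(voxelData(zT)),
              jointchange:::.tikhonov_energy(voxelData(wInit)))
})

test_that("registration recovers zero motion and known smooth fields", {
    ph <- makePhantom(c(32, 32, 32), seed = 11)
    c0 <- zero_mask(c(32, 32, 32))
    cfg <- solverConfig()
    ## identical pair: negligible field
    wId <- registerDeformable(ph$volume, ph$volume, c0, cfg, ph$mask)
    expect_lt(max(abs(voxelData(wId))), 0.1)
    ## known smooth field: baseline = reference warped by the true field,
    ## so the registration target field is exactly wTrue
    wTrue <- makeAtrophyField(c(32, 32, 32), 2.0, seed = 12)
    I1 <- warpBackward(ph$volume, wTrue)$volume
    w <- registerDeformable(I1, ph$volume, c0, cfg, ph$mask)
    err <- sqrt(rowSums((matrix(voxelData(w), ncol = 3) -
                         matrix(voxelData(wTrue), ncol = 3))^2))
    expect_lt(mean(err[voxelData(ph$mask) == 1]), 0.5)
})

test_that("registration is translation-equivariant in the interior", {
    ## brain content keeps a >= 4-voxel zero margin at 48^3, so a 4-voxel
    ## shift (integer at every pyramid level) translates it exactly
    d <- c(48, 48, 48)
    ph <- makePhantom(d, seed = 13)
    c0 <- zero_mask(d)
    cfg <- solverConfig()
    sh <- c(4, 0, 0)
    shiftVol <- function(V) warpBackward(
        V, DisplacementField(array(rep(sh, each = prod(d)),
                                   dim = c(d, 3))))$volume
    wTrue <- makeAtrophyField(d, 1.5, seed = 14)
    I1 <- warpBackward(ph$volume, wTrue)$volume
    I2 <- ph$volume
    wA <- registerDeformable(I1, I2, c0, cfg, ph$mask)
    mShift <- BinaryMask(voxelData(shiftVol(
        Volume(voxelData(ph$mask) + 0))) > 0.5)
    wB <- registerDeformable(shiftVol(I1), shiftVol(I2), c0, cfg, mShift)
    ## compare the shifted field against the field of the shifted pair
    shifted <- shiftVol(Volume(fieldComponent(wA, 1)))
    inner <- 13:36
    diffs <- (voxelData(shifted) -
              fieldComponent(wB, 1))[inner, inner, inner]
    expect_lt(max(abs(diffs)), 0.1)
})

test_that("all-change registration only descends the Tikhonov energy", {
    ph <- makePhantom(c(32, 32, 32), seed = 15)
    I2 <- Volume(voxelData(ph$volume) +
                     array(rnorm(32^3, sd = 5), dim = c(32, 32, 32)))
    w <- registerDeformable(ph$volume, I2, ones_mask(c(32, 32, 32)),
                            solverConfig(), ph$mask)
    ## initialization is the zero field (energy 0): the returned field must
    ## not pick up data-driven structure
    expect_lte(jointchange:::.tikhonov_energy(voxelData(w)), 1e-8)
})

test_that("coupled energy matches an explicit loop evaluation", {
    set.seed(16)
    n <- c(5, 5, 5)
    I1 <- rand_volume(n, seed = 17)
    I2 <- rand_volume(n, seed = 18)
    w <- rand_field(n, seed = 19, amp = 0.6)
    cmArr <- array(rbinom(prod(n), 1, 0.3), dim = n)
    cm <- BinaryMask(cmArr)
    cfg <- solverConfig(lambda1 = 2, lambda2 = 3, lambda3 = 0.5)
    sig <- 1.4
    e <- jointEnergy(I1, I2, w, cm, cfg, sigma = sig)
    ## explicit evaluation
    wb <- warpBackward(I2, w)
    rho <- (voxelData(wb$volume) - voxelData(I1))^2 / sig^2
    eData <- sum((1 - cmArr) * rho * voxelData(wb$valid)) + 3 * sum(cmArr)
    eReg <- 0
    f <- voxelData(w)
    for (comp in 1:3) for (ax in 1:3) {
        a <- f[, , , comp]
        idx1 <- slice.index(a, ax)
        eReg <- eReg + sum((apply(a, setdiff(1:3, ax), diff))^2)
    }
    ePotts <- 0
    for (ax in 1:3) {
        dd <- apply(cmArr, setdiff(1:3, ax), diff)
        ePotts <- ePotts + 2 * sum(dd != 0)
    }
    expect_equal(e, eData + 2 * eReg + 0.5 * ePotts, tolerance = 1e-8)
    ## analytic special cases
    expect_equal(jointEnergy(I1, I1, zeroField(n), zero_mask(n), cfg), 0)
    expect_equal(jointEnergy(I1, I1, zeroField(n), ones_mask(n), cfg),
                 3 * prod(n))
})
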