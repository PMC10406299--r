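# Shared fixtures: tiny deterministic volumes, a brute-force trilinear
# interpolation oracle, and a lazily-computed cache of the multi-seed
# synthetic experiment reused by several acceptance checks.

rand_volume <- function(shape = c(8, 8, 8), seed = 1, spacing = c(1, 1, 1)) {
    set.seed(seed)
    Volume(array(rnorm(prod(shape)), dim = shape), spacing = spacing)
}

rand_field <- function(shape = c(8, 8, 8), seed = 1, amp = 1) {
    set.seed(seed)
    DisplacementField(array(amp * runif(prod(shape) * 3, -1, 1),
                            dim = c(shape, 3L)))
}

zero_mask <- function(shape) BinaryMask(array(0L, dim = shape))
ones_mask <- function(shape) BinaryMask(array(1L, dim = shape))

# Independent per-voxel trilinear interpolation with border replication,
# written as an explicit scalar loop (oracle for the warping kernel).
naive_warp <- function(I, w) {
    a <- voxelData(I)
    f <- voxelData(w)
    d <- dim(a)
    out <- array(0, dim = d)
    valid <- array(1L, dim = d)
    for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
        sx <- (x - 1) - f[x, y, z, 1]
        sy <- (y - 1) - f[x, y, z, 2]
        sz <- (z - 1) - f[x, y, z, 3]
        if (sx < 0 || sx > d[1] - 1 || sy < 0 || sy > d[2] - 1 ||
            sz < 0 || sz > d[3] - 1) valid[x, y, z] <- 0L
        cx <- min(max(sx, 0), d[1] - 1)
        cy <- min(max(sy, 0), d[2] - 1)
        cz <- min(max(sz, 0), d[3] - 1)
        x0 <- min(floor(cx), d[1] - 2); x0 <- max(x0, 0)
        y0 <- min(floor(cy), d[2] - 2); y0 <- max(y0, 0)
        z0 <- min(floor(cz), d[3] - 2); z0 <- max(z0, 0)
        fx <- cx - x0; fy <- cy - y0; fz <- cz - z0
        acc <- 0
        for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
            wgt <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
                   (if (dz) fz else 1 - fz)
            acc <- acc + wgt * a[x0 + dx + 1, y0 + dy + 1, z0 + dz + 1]
        }
        out[x, y, z] <- acc
    }
    list(data = out, valid = valid)
}

# Exhaustive Potts minimum over all labelings of the in-mask voxels.
brute_force_potts <- function(rho, lambda2, lambda3, maskArr) {
    idx <- which(maskArr == 1L)
    n <- length(idx)
    stopifnot(n <= 16)
    best <- Inf
    bestLab <- NULL
    for (b in 0:(2^n - 1)) {
        lab <- array(0L, dim = dim(rho))
        lab[idx] <- as.integer(intToBits(b))[seq_len(n)]
        e <- jointchange:::.potts_label_energy(lab, rho, lambda2, lambda3,
                                               maskArr)
        if (e < best) { best <- e; bestLab <- lab }
    }
    list(energy = best, labels = bestLab)
}

# Cache for expensive multi-seed experiment results shared across tests.
.experiment_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
    if (!exists(key, envir = .experiment_cache))
        assign(key, force(expr), envir = .experiment_cache)
    get(key, envir = .experiment_cache)
}

# Preprocess a simulated pair the way the pipeline prescribes:
# median-100 normalization and differential bias correction (inputs are
# already 1 mm isotropic and aligned by construction).
preprocess_pair <- function(pair, kernel = 11L) {
    I1 <- normalizeMedianIntensity(pair$baseline, pair$mask)$volume
    I2 <- normalizeMedianIntensity(pair$followup, pair$mask)$volume
    I2 <- differentialBiasCorrection(I1, I2, pair$mask, kernel)
    list(I1 = I1, I2 = I2, mask = pair$mask, truth = pair$truth)
}

# Post-detection cleanup as the pipeline prescribes: discard components
# below 3 mm^3 and detections outside the parenchyma (GM + WM).
postprocess_change <- function(cm, labels) {
    par <- BinaryMask(labels == 1L | labels == 2L)
    applyParenchymaMask(filterSmallComponents(cm), par)
}

# One simulated study: all three methods on an appearance scenario,
# post-processed and scored against the ground truth.
run_study <- function(seed, atrophy = TRUE, shape = c(40, 40, 40),
                      cfg = solverConfig(), scenario = "appearance") {
    pair <- makePair(scenarioSpec(scenario, atrophy = atrophy,
                                  shape = shape, seed = seed))
    pp <- preprocess_pair(pair)
    out <- list(truth = pp$truth, mask = pp$mask)
    out$joint <- runJoint(pp$I1, pp$I2, pp$mask, cfg)
    out$sequential <- runSequential(pp$I1, pp$I2, pp$mask, cfg)
    out$affine <- runAffine(pp$I1, pp$I2, pp$mask, cfg)
    out$maps <- lapply(out[c("joint", "sequential", "affine")],
                       function(r) postprocess_change(changeMap(r),
                                                      pair$labels))
    out$metrics <- lapply(out$maps, function(m)
        voxelMetrics(m, pp$truth$change, pp$mask))
    out
}

study_seeds <- function() 101:105

atrophy_studies <- function()
    cached("atrophy_studies",
           lapply(study_seeds(), run_study, atrophy = TRUE))

noatrophy_study <- function()
    cached("noatrophy_study", run_study(111, atrophy = FALSE))

# Lesion-preservation experiment: register with c clamped to the true
# changed region vs unmasked, and measure how each treats lesion
# intensities.  The clamp is the lesion mask dilated by 2 voxels so it
# covers the partial-volume skirt, where intensity also changed; leaving
# the skirt exposed lets the data term pull the field there and Tikhonov
# smoothing carries that pull into the lesion core.
clamp_study <- function() cached("clamp_study", {
    d <- c(40, 40, 40)
    pair <- makePair(scenarioSpec("appearance", atrophy = FALSE,
                                  shape = d, seed = 3,
                                  noiseFrac = 0.02, biasAmp = 0))
    pp <- preprocess_pair(pair)
    cfg <- solverConfig()
    les <- voxelData(pp$truth$change) == 1L
    sigma0 <- estimateSigma(pp$I1, pp$I2, pp$mask)
    cClamp <- BinaryMask(array(
        jointchange:::c_dilate_ball(
            as.integer(voxelData(pp$truth$change)), as.integer(d), 2),
        dim = d))
    wClamp <- registerDeformable(pp$I1, pp$I2, cClamp, cfg, pp$mask)
    I2wClamp <- warpBackward(pp$I2, wClamp)$volume
    wFree <- registerDeformable(pp$I1, pp$I2, zero_mask(d), cfg, pp$mask)
    I2wFree <- warpBackward(pp$I2, wFree)$volume
    list(sigma0 = sigma0,
         changeClamp = mean(abs(voxelData(I2wClamp)[les] -
                                voxelData(pp$I2)[les])),
         changeFree = mean(abs(voxelData(I2wFree)[les] -
                               voxelData(pp$I2)[les])),
         residClamp = mean(abs(voxelData(I2wClamp)[les] -
                               voxelData(pp$I1)[les])),
         residFree = mean(abs(voxelData(I2wFree)[les] -
                              voxelData(pp$I1)[les])))
})
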