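## Seeded synthetic longitudinal pairs with known ground truth: a
## T2-like ellipsoid brain phantom, hyperintense white-matter lesions
## (appearance or growth), an optional smooth ventricle-expansion
## deformation standing in for atrophy, a 20% multiplicative bias field
## and additive Gaussian noise at 5% of the brightest-tissue mean.

## Evaluate code under a fixed seed without clobbering the caller's RNG.
.with_seed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(code)
}

#' Scenario specification for the synthetic generator
#'
#' Describes one simulated longitudinal acquisition: lesion appearance
#' (new hyperintense lesions absent at baseline) or lesion growth
#' (baseline lesions dilated at follow-up), with or without an
#' atrophy-like deformation.  Noise and bias defaults follow the study
#' conditions: additive Gaussian noise with sd equal to 5% of the mean
#' intensity of the brightest tissue (CSF on T2-like contrast) and a
#' multiplicative bias field of 20% amplitude.
#'
#' @param scenario "appearance" or "growth".
#' @param atrophy logical; apply the synthetic atrophy field to the
#'   follow-up.
#' @param shape grid dimensions (each axis >= 32).
#' @param nLesions number of lesions.
#' @param lesionRadius lesion sphere radius in voxels.
#' @param lesionContrast added lesion intensity in phantom units (WM is
#'   90, CSF 250); the default 150 makes lesions nearly CSF-bright, the
#'   typical appearance of demyelinating lesions on T2-weighted images.
#' @param growthVoxels radius increment for the growth scenario.
#' @param atrophyAmplitude peak displacement of the atrophy field in
#'   voxels (<= 5).  The default NULL scales with the grid,
#'   0.028 * min(shape): the anatomy-relative equivalent of a ~5-voxel
#'   peak displacement on a full-size (181-voxel) scan, so scaled-down
#'   phantoms carry the same relative deformation as a full-size study.
#' @param noiseFrac noise sd as a fraction of the brightest-tissue mean.
#' @param biasAmp bias-field amplitude (field spans [1-biasAmp, 1+biasAmp]).
#' @param seed integer seed fixing all randomness.
#' @return A named list of class "ScenarioSpec".
#' @export
scenarioSpec <- function(scenario = c("appearance", "growth"),
                         atrophy = FALSE, shape = c(64, 64, 64),
                         nLesions = 3L, lesionRadius = 3,
                         lesionContrast = 150, growthVoxels = 2,
                         atrophyAmplitude = NULL, noiseFrac = 0.05,
                         biasAmp = 0.20, seed = 1L) {
    scenario <- match.arg(scenario)
    if (is.null(atrophyAmplitude))
        atrophyAmplitude <- 0.028 * min(shape)
    stopifnot(all(shape >= 32), lesionRadius > 0, noiseFrac >= 0,
              biasAmp >= 0, atrophyAmplitude <= 5)
    structure(list(scenario = scenario, atrophy = isTRUE(atrophy),
                   shape = as.integer(shape), nLesions = as.integer(nLesions),
                   lesionRadius = lesionRadius,
                   lesionContrast = lesionContrast,
                   growthVoxels = growthVoxels,
                   atrophyAmplitude = atrophyAmplitude,
                   noiseFrac = noiseFrac, biasAmp = biasAmp,
                   seed = as.integer(seed)),
              class = "ScenarioSpec")
}

## Normalized [-1, 1] coordinate arrays for a grid.
.norm_coords <- function(shape) {
    vs <- lapply(1:3, function(k) {
        if (shape[k] > 1) 2 * (0:(shape[k] - 1)) / (shape[k] - 1) - 1 else 0
    })
    list(array(vs[[1]], dim = shape),
         array(rep(vs[[2]], each = shape[1]), dim = shape),
         array(rep(vs[[3]], each = shape[1] * shape[2]), dim = shape))
}

.T2_INTENSITY <- c(bg = 0, wm = 90, gm = 120, csf = 250)
.LAB <- c(bg = 0L, wm = 1L, gm = 2L, csf = 3L)

#' Generate a T2-like brain phantom
#'
#' Nested ellipsoids: a brain envelope whose outer shell is gray matter,
#' a white-matter interior and two ventricle ellipsoids of CSF, with the
#' T2 intensity ordering CSF > GM > WM and mild seeded intra-tissue
#' texture.  A geometric stand-in for a simulated brain volume, not an
#' anatomical atlas.
#'
#' @param shape grid dimensions (each axis >= 32).
#' @param seed integer seed.
#' @return list with `volume` ([Volume-class]), `labels` (3D integer
#'   array: 0 background, 1 WM, 2 GM, 3 CSF) and `mask` (brain
#'   [BinaryMask-class]).
#' @export
makePhantom <- function(shape = c(64, 64, 64), seed = 1L) {
    stopifnot(all(shape >= 32))
    shape <- as.integer(shape)
    .with_seed(seed, {
        co <- .norm_coords(shape)
        x <- co[[1]]; y <- co[[2]]; z <- co[[3]]
        rBrain <- (x / 0.80)^2 + (y / 0.85)^2 + (z / 0.75)^2
        brain <- rBrain <= 1
        labels <- array(.LAB["bg"], dim = shape)
        labels[brain] <- .LAB["gm"]
        labels[rBrain <= 0.72] <- .LAB["wm"]
        vent <- ((x - 0.16) / 0.10)^2 + (y / 0.34)^2 + (z / 0.12)^2 <= 1 |
                ((x + 0.16) / 0.10)^2 + (y / 0.34)^2 + (z / 0.12)^2 <= 1
        labels[vent & brain] <- .LAB["csf"]
        vol <- array(0, dim = shape)
        for (tis in c("wm", "gm", "csf"))
            vol[labels == .LAB[tis]] <- .T2_INTENSITY[tis]
        ## partial-volume / point-spread blur of the tissue boundaries
        vol <- .gaussian_smooth(vol, 0.5)
        ## mild smooth intra-tissue texture (~2% of WM intensity)
        tex <- .gaussian_smooth(array(rnorm(prod(shape)), dim = shape), 2)
        tex <- tex / stats::sd(tex) * 0.02 * .T2_INTENSITY["wm"]
        vol[brain] <- vol[brain] + tex[brain]
        list(volume = Volume(vol), labels = labels,
             mask = BinaryMask(brain))
    })
}

## Euclidean sphere mask around a voxel center (1-based center coords).
.sphere_mask <- function(shape, center, radius) {
    co <- lapply(1:3, function(k) (seq_len(shape[k]) - center[k])^2)
    d2 <- outer(outer(co[[1]], co[[2]], `+`), co[[3]], `+`)
    d2 <= radius^2
}

#' Add hyperintense lesions to a phantom
#'
#' Lesion centers are sampled in deep white matter.  In the "appearance"
#' scenario the baseline has no lesions and the follow-up gains spheres of
#' the configured radius; in the "growth" scenario the baseline carries
#' the spheres and the follow-up carries spheres enlarged by
#' `growthVoxels`.  Lesion edges receive the same partial-volume blur as
#' the tissue boundaries; the returned change map is the discrete lesion
#' extent (voxels where at least half the lesion contrast was added).
#'
#' @param I clean phantom [Volume-class].
#' @param labels tissue label array from [makePhantom].
#' @param spec a [scenarioSpec] (uses the current RNG state; seeded by the
#'   caller).
#' @return list with `baseline`, `followup` ([Volume-class]), `change`
#'   ([BinaryMask-class]) and `centers` (matrix of lesion centers).
#' @export
addLesions <- function(I, labels, spec) {
    stopifnot(is(I, "Volume"))
    shape <- dim(I@data)
    if (spec$nLesions == 0L)
        return(list(baseline = I, followup = I,
                    change = BinaryMask(array(0L, dim = shape)),
                    centers = matrix(numeric(0), 0, 3)))
    rMax <- spec$lesionRadius +
        if (spec$scenario == "growth") spec$growthVoxels else 0
    ## candidate centers: white matter eroded so lesions stay inside WM
    wm <- array(as.integer(labels == .LAB["wm"]), dim = shape)
    notWm <- 1L - wm
    forb <- c_dilate_ball(as.integer(notWm), as.integer(shape),
                          as.numeric(rMax))
    cand <- which(wm == 1L & array(forb, dim = shape) == 0L)
    if (length(cand) < spec$nLesions)
        stop("no white-matter room for the requested lesions",
             call. = FALSE)
    ## keep centers apart so lesions stay distinct components; relax the
    ## separation if the eroded white matter cannot host them that far
    ## apart (small grids), down to just-disjoint spheres
    centers <- NULL
    for (sep in c(2.5 * rMax + 2, 2 * rMax + 1)) {
        centers <- matrix(0, spec$nLesions, 3)
        ok <- TRUE
        for (i in seq_len(spec$nLesions)) {
            placed <- FALSE
            for (try in seq_len(200L)) {
                ci <- arrayInd(sample(cand, 1L), shape)
                if (i == 1L ||
                    min(sqrt(rowSums(sweep(centers[seq_len(i - 1L), ,
                                                   drop = FALSE],
                                           2, as.numeric(ci))^2))) > sep) {
                    centers[i, ] <- ci
                    placed <- TRUE
                    break
                }
            }
            if (!placed) { ok <- FALSE; break }
        }
        if (ok) break else centers <- NULL
    }
    if (is.null(centers))
        stop("no white-matter room for the requested lesions",
             call. = FALSE)
    small <- array(FALSE, dim = shape)
    large <- array(FALSE, dim = shape)
    for (i in seq_len(spec$nLesions)) {
        small <- small | .sphere_mask(shape, centers[i, ], spec$lesionRadius)
        large <- large | .sphere_mask(shape, centers[i, ], rMax)
    }
    ## lesions get the same partial-volume blur as the tissue boundaries;
    ## the ground-truth mask is the discrete lesion extent
    lesionAdd <- function(base, m)
        Volume(base@data +
                   spec$lesionContrast * .gaussian_smooth(m + 0, 0.5),
               spacing = base@spacing, affine = base@affine)
    if (spec$scenario == "appearance") {
        baseline <- I
        followup <- lesionAdd(I, small)
        change <- small
    } else {
        baseline <- lesionAdd(I, small)
        followup <- lesionAdd(I, large)
        change <- large & !small
    }
    list(baseline = baseline, followup = followup,
         change = BinaryMask(change), centers = centers)
}

#' Synthetic atrophy-like deformation field
#'
#' A smooth radial field that expands the ventricles and contracts the
#' cortex (peaked between ventricle wall and mid white matter, tapering
#' to zero at the brain edge), modulated by seeded low-frequency noise
#' and normalized so the maximum displacement equals `amplitude` voxels.
#' The Jacobian determinant of x - w(x) is verified positive everywhere;
#' on failure the field is regenerated at reduced amplitude (3 attempts).
#'
#' @param shape grid dimensions.
#' @param amplitude peak displacement in voxels (<= 5); 0 gives the zero
#'   field.
#' @param seed integer seed.
#' @return A [DisplacementField-class].
#' @export
makeAtrophyField <- function(shape, amplitude, seed = 1L) {
    stopifnot(amplitude <= 5, amplitude >= 0)
    shape <- as.integer(shape)
    if (amplitude == 0) return(zeroField(shape))
    .with_seed(seed, {
        co <- .norm_coords(shape)
        x <- co[[1]]; y <- co[[2]]; z <- co[[3]]
        r <- sqrt((x / 0.80)^2 + (y / 0.85)^2 + (z / 0.75)^2)
        amp <- amplitude
        for (attempt in 1:3) {
            prof <- exp(-((r - 0.45) / 0.28)^2)
            prof <- prof * pmax(0, 1 - pmax(r - 0.75, 0) / 0.25)
            mod <- .gaussian_smooth(array(rnorm(prod(shape)), dim = shape),
                                    min(shape) / 8)
            mod <- 1 + 0.3 * mod / max(abs(mod))
            mag <- prof * mod
            rr <- pmax(sqrt(x^2 + y^2 + z^2), 1e-6)
            f <- array(0, dim = c(shape, 3L))
            f[, , , 1] <- mag * x / rr
            f[, , , 2] <- mag * y / rr
            f[, , , 3] <- mag * z / rr
            mmax <- max(sqrt(f[, , , 1]^2 + f[, , , 2]^2 + f[, , , 3]^2))
            f <- f * (amp / mmax)
            w <- DisplacementField(f)
            if (min(jacobianDet(w)) > 0) return(w)
            amp <- amp * 0.7
        }
        stop("could not generate a diffeomorphic atrophy field",
             call. = FALSE)
    })
}

#' Jacobian determinant of the mapping x - w(x)
#'
#' Central-difference Jacobian of the backward-warp sample locations;
#' values below 1 indicate local expansion of the warped image content,
#' values above 1 local contraction.
#'
#' @param w a [DisplacementField-class].
#' @return 3D array of determinants.
#' @export
jacobianDet <- function(w) {
    d <- dim(w@field)[1:3]
    J <- array(0, dim = c(d, 3, 3))
    for (comp in 1:3) {
        g <- spatialGradient(Volume(w@field[, , , comp]))
        for (ax in 1:3) J[, , , comp, ax] <- g[, , , ax]
    }
    ## det(I - dw/dx)
    a11 <- 1 - J[, , , 1, 1]; a12 <- -J[, , , 1, 2]; a13 <- -J[, , , 1, 3]
    a21 <- -J[, , , 2, 1]; a22 <- 1 - J[, , , 2, 2]; a23 <- -J[, , , 2, 3]
    a31 <- -J[, , , 3, 1]; a32 <- -J[, , , 3, 2]; a33 <- 1 - J[, , , 3, 3]
    a11 * (a22 * a33 - a23 * a32) - a12 * (a21 * a33 - a23 * a31) +
        a13 * (a21 * a32 - a22 * a31)
}

#' Corrupt a clean volume with bias field and noise
#'
#' Multiplies by a smooth low-order polynomial bias field spanning
#' [1 - biasAmp, 1 + biasAmp], then adds Gaussian noise with sd equal to
#' `noiseFrac` times the mean intensity of the brightest tissue class.
#' Uses the current RNG state (seeded by the caller).
#'
#' @param I clean [Volume-class].
#' @param spec a [scenarioSpec] (noiseFrac, biasAmp).
#' @param labels tissue label array locating the brightest tissue; when
#'   NULL the top-decile mean intensity is used as reference.
#' @return The corrupted [Volume-class].
#' @export
corrupt <- function(I, spec, labels = NULL) {
    stopifnot(is(I, "Volume"))
    shape <- dim(I@data)
    dat <- I@data
    if (spec$biasAmp > 0) {
        co <- .norm_coords(shape)
        x <- co[[1]]; y <- co[[2]]; z <- co[[3]]
        cf <- rnorm(9)
        p <- cf[1] * x + cf[2] * y + cf[3] * z + cf[4] * x * y +
            cf[5] * x * z + cf[6] * y * z + cf[7] * x^2 + cf[8] * y^2 +
            cf[9] * z^2
        bias <- 1 + spec$biasAmp * p / max(abs(p))
        dat <- dat * bias
    }
    if (spec$noiseFrac > 0) {
        bright <- if (is.null(labels)) {
            mean(I@data[I@data >= stats::quantile(I@data, 0.9)])
        } else {
            means <- vapply(unique(labels[labels > 0L]),
                            function(l) mean(I@data[labels == l]), 0)
            max(means)
        }
        dat <- dat + rnorm(length(dat), sd = spec$noiseFrac * bright)
    }
    Volume(array(dat, dim = shape), spacing = I@spacing, affine = I@affine)
}

#' Generate a seeded synthetic longitudinal pair with ground truth
#'
#' Baseline = corrupted phantom (with baseline lesions in the growth
#' scenario); follow-up = corrupted backward-warp of the lesioned phantom
#' by the atrophy field (zero field when `atrophy` is FALSE).  Noise and
#' bias draws are independent between the two timepoints.  The
#' ground-truth change map lives in baseline coordinates, where the
#' residual of a perfectly registered pair is evaluated.
#'
#' @param spec a [scenarioSpec].
#' @return list with `baseline`, `followup` ([Volume-class]), `mask`
#'   (brain [BinaryMask-class]), `labels`, and `truth` (list: `change`
#'   [BinaryMask-class], `field` the atrophy [DisplacementField-class]
#'   used to deform the follow-up, `centers`).
#' @export
makePair <- function(spec) {
    stopifnot(inherits(spec, "ScenarioSpec"))
    .with_seed(spec$seed, {
        ph <- makePhantom(spec$shape, seed = spec$seed)
        les <- addLesions(ph$volume, ph$labels, spec)
        field <- if (spec$atrophy)
            makeAtrophyField(spec$shape, spec$atrophyAmplitude,
                             seed = spec$seed + 1000L)
        else zeroField(spec$shape)
        fuClean <- if (spec$atrophy)
            warpBackward(les$followup, field)$volume
        else les$followup
        I1 <- corrupt(les$baseline, spec, ph$labels)
        I2 <- corrupt(fuClean, spec, ph$labels)
        list(baseline = I1, followup = I2, mask = ph$mask,
             labels = ph$labels,
             truth = list(change = les$change, field = field,
                          centers = les$centers))
    })
}
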