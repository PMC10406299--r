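# Core volumetric types, NIfTI round trips, warping, gradients, pyramids.

test_that("NIfTI round trip preserves data, spacing and dimensionality", {
    vol <- Volume(array(0, dim = c(10, 10, 10)))
    f <- tempfile(fileext = ".nii.gz")
    writeVolume(vol, f)
    back <- readVolume(f)
    expect_equal(voxelData(back), voxelData(vol))
    expect_equal(spacing(back), c(1, 1, 1))

    vol2 <- rand_volume(c(7, 6, 5), seed = 3, spacing = c(1, 1.5, 2))
    f2 <- tempfile(fileext = ".nii.gz")
    writeVolume(vol2, f2)
    back2 <- readVolume(f2)
    expect_equal(voxelData(back2), voxelData(vol2), tolerance = 1e-7)
    expect_equal(spacing(back2), c(1, 1.5, 2), tolerance = 1e-6)

    ## field round trip (4D, last axis = component)
    w <- rand_field(c(6, 5, 4), seed = 4)
    fw <- tempfile(fileext = ".nii.gz")
    writeField(w, fw)
    expect_equal(voxelData(readField(fw)), voxelData(w), tolerance = 1e-12)
})

test_that("reading a 4D image as a volume is a format error", {
    img <- RNifti::asNifti(array(0, dim = c(4, 4, 4, 2)))
    f <- tempfile(fileext = ".nii.gz")
    RNifti::writeNifti(img, f)
    expect_error(readVolume(f), "3D")
    expect_error(readVolume(tempfile(fileext = ".nii")), "readable")
})

test_that("volume and mask validity invariants are enforced", {
    expect_error(Volume(array(NA_real_, dim = c(2, 2, 2))), "finite")
    expect_error(Volume(array(0, dim = c(2, 2)), spacing = 1), "3D")
    expect_error(Volume(array(0, dim = c(2, 2, 2)), spacing = c(1, -1, 1)),
                 "spacing")
    expect_error(new("BinaryMask", data = array(2L, dim = c(2, 2, 2))),
                 "0 or 1")
})

test_that("zero-field warp is the identity at bit level", {
    I <- rand_volume(c(9, 8, 7), seed = 5)
    res <- warpBackward(I, zeroField(c(9, 8, 7)))
    expect_identical(voxelData(res$volume), voxelData(I))
    expect_true(all(voxelData(res$valid) == 1L))
})

test_that("unit shift of a linear ramp warps analytically", {
    d <- c(10, 8, 8)
    ramp <- Volume(array(rep(0:(d[1] - 1), times = prod(d[2:3])), dim = d))
    w <- DisplacementField(array(rep(c(1, 0, 0), each = prod(d)),
                                 dim = c(d, 3)))
    res <- warpBackward(ramp, w)
    interior <- voxelData(res$volume)[2:d[1], , ]
    expected <- voxelData(ramp)[2:d[1], , ] - 1
    expect_equal(interior, expected, tolerance = 1e-12)
    ## first x-slab sampled outside the grid -> flagged invalid
    expect_true(all(voxelData(res$valid)[1, , ] == 0L))
    expect_true(all(voxelData(res$valid)[2:d[1], , ] == 1L))
})

test_that("warp matches the per-voxel scalar interpolation oracle", {
    for (seed in 1:3) {
        I <- rand_volume(c(8, 8, 8), seed = seed)
        w <- rand_field(c(8, 8, 8), seed = seed + 10, amp = 2.5)
        res <- warpBackward(I, w)
        ref <- naive_warp(I, w)
        expect_lt(max(abs(voxelData(res$volume) - ref$data)), 1e-10)
        expect_identical(as.vector(voxelData(res$valid)),
                         as.vector(ref$valid))
    }
})

test_that("spatial gradient is exact on constants and linear ramps", {
    expect_true(all(spatialGradient(Volume(array(5, dim = c(4, 4, 4)))) == 0))
    d <- c(8, 6, 6)
    I <- Volume(array(rep(2 * (0:(d[1] - 1)), times = prod(d[2:3])), dim = d))
    g <- spatialGradient(I)
    expect_equal(g[, , , 1], array(2, dim = d), tolerance = 1e-12)
    expect_equal(g[, , , 2], array(0, dim = d))
})

test_that("spatial gradient matches an explicit finite-difference loop", {
    I <- rand_volume(c(6, 5, 4), seed = 7)
    a <- voxelData(I)
    g <- spatialGradient(I)
    d <- dim(a)
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
        xp <- min(x + 1, d[1]); xm <- max(x - 1, 1)
        expect_equal(g[x, y, z, 1],
                     (a[xp, y, z] - a[xm, y, z]) / (xp - xm))
        zp <- min(z + 1, d[3]); zm <- max(z - 1, 1)
        expect_equal(g[x, y, z, 3],
                     (a[x, y, zp] - a[x, y, zm]) / (zp - zm))
    }
})

test_that("pyramid shapes, degenerate cases and smoothing invariance", {
    I <- rand_volume(c(64, 64, 64), seed = 2)
    p <- buildPyramid(I, 3, 2)
    shapes <- lapply(p@levels, function(v) dim(voxelData(v)))
    expect_equal(shapes, list(c(16L, 16L, 16L), c(32L, 32L, 32L),
                              c(64L, 64L, 64L)))
    ## levels = 1 returns the source untouched
    p1 <- buildPyramid(I, 1, 2)
    expect_identical(voxelData(p1@levels[[1]]), voxelData(I))
    ## constant volume stays constant at every level
    pc <- buildPyramid(Volume(array(3, dim = c(32, 32, 32))), 3, 2)
    for (lv in pc@levels)
        expect_equal(range(voxelData(lv)), c(3, 3), tolerance = 1e-12)
    ## too-deep pyramid is a configuration error
    expect_error(buildPyramid(rand_volume(c(16, 16, 16)), 4, 2), "coarsest")
})

test_that("field prolongation scales values by the shape ratio", {
    d <- c(8, 8, 8)
    w <- DisplacementField(array(rep(c(1, 0, 0), each = prod(d)),
                                 dim = c(d, 3)))
    up <- prolongField(w, c(16, 16, 16))
    expect_equal(fieldComponent(up, 1), array(2, dim = c(16, 16, 16)),
                 tolerance = 1e-12)
    expect_equal(max(abs(fieldComponent(up, 2))), 0)
    ## zero field stays zero
    expect_true(all(voxelData(prolongField(zeroField(d), c(16, 16, 16))) == 0))
})

test_that("downsample-then-prolong approximately preserves smooth fields", {
    d <- c(16, 16, 16)
    co <- seq(0, 2, length.out = d[1])
    u <- outer(outer(sin(co), cos(co / 2)), rep(1, d[3]))
    w <- DisplacementField(u, u * 0.5, u * 0)
    down <- jointchange:::.resize_field(w, c(8, 8, 8))
    back <- prolongField(down, d)
    amp <- max(abs(u))
    ## voxel-unit rescaling cancels on the round trip
    expect_lt(max(abs(fieldComponent(back, 1) - u)), 0.1 * amp)
    ## constant fields survive the round trip exactly up to float error
    wc <- DisplacementField(array(rep(c(2, -1, 0.5), each = prod(d)),
                                  dim = c(d, 3)))
    rt <- prolongField(jointchange:::.resize_field(wc, c(8, 8, 8)), d)
    expect_equal(voxelData(rt), voxelData(wc), tolerance = 1e-12)
})
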