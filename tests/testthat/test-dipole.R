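test_that("dipole kernel matches the analytic expression on anisotropic oblique grids", {
    g <- volumeGrid(c(6, 8, 10), voxelSize = c(0.8, 1.0, 1.3),
                    b0Dir = c(0.2, -0.3, 0.9))
    D <- dipoleKernel(g)
    ref <- bruteKernel(c(6, 8, 10), c(0.8, 1.0, 1.3), c(0.2, -0.3, 0.9))
    expect_equal(values(D), ref, tolerance = 1e-12)
})

test_that("kernel hits the forced values: -2/3 on the B0 axis, 1/3 transverse, 0 at DC and on the magic-angle cone", {
    g <- volumeGrid(c(16, 16, 16))
    D <- values(dipoleKernel(g))
    expect_equal(D[1, 1, 2], -2 / 3)    # k parallel to B0
    expect_equal(D[1, 1, 9], -2 / 3)    # Nyquist along B0
    expect_equal(D[2, 1, 1], 1 / 3)     # k orthogonal to B0
    expect_equal(D[1, 5, 1], 1 / 3)
    expect_identical(D[1, 1, 1], 0)     # DC, by convention
    ## on an isotropic grid k = (1,1,1) satisfies kz^2/|k|^2 = 1/3 exactly
    expect_equal(D[2, 2, 2], 0)
})

test_that("kernel range and symmetries hold by exhaustive scan", {
    for (sh in list(c(16, 16, 16), c(12, 10, 8))) {
        D <- values(dipoleKernel(volumeGrid(sh)))
        expect_gte(min(D), -2 / 3)
        expect_lte(max(D), 1 / 3)
        ## even symmetry under negation of each frequency axis
        flip <- function(n) c(1, n:2)
        expect_equal(D, D[flip(sh[1]), , ])
        expect_equal(D, D[, flip(sh[2]), ])
        expect_equal(D, D[, , flip(sh[3])])
    }
    ## with B0 = z, the two transverse axes are exchangeable
    D <- values(dipoleKernel(volumeGrid(c(12, 12, 8))))
    expect_equal(D, aperm(D, c(2, 1, 3)))
})

test_that("invalid grids are rejected", {
    expect_error(new("VolumeGrid", shape = c(1L, 4L, 4L),
                     voxelSize = c(1, 1, 1), b0Dir = c(0, 0, 1)), "shape")
    expect_error(new("VolumeGrid", shape = c(4L, 4L, 4L),
                     voxelSize = c(1, 1, 1), b0Dir = c(0, 0, 2)), "unit")
    expect_error(new("VolumeGrid", shape = c(4L, 4L, 4L),
                     voxelSize = c(1, -1, 1), b0Dir = c(0, 0, 1)), "positive")
})

test_that("forward field of zero and of uniform susceptibility is zero", {
    g <- volumeGrid(c(12, 12, 12))
    D <- dipoleKernel(g)
    z <- forwardField(susceptibilityMap(array(0, c(12, 12, 12)), g), D)
    expect_true(all(values(z) == 0))
    u <- forwardField(susceptibilityMap(array(3.7, c(12, 12, 12)), g), D)
    expect_lt(max(abs(values(u))), 1e-12)
})

test_that("forward field is linear and grid mismatch is rejected", {
    g <- volumeGrid(c(10, 10, 10))
    D <- dipoleKernel(g)
    set.seed(11)
    c1 <- susceptibilityMap(array(rnorm(1000), c(10, 10, 10)), g)
    c2 <- susceptibilityMap(array(rnorm(1000), c(10, 10, 10)), g)
    lin <- susceptibilityMap(2 * values(c1) - 0.5 * values(c2), g)
    expect_equal(values(forwardField(lin, D)),
                 2 * values(forwardField(c1, D)) - 0.5 * values(forwardField(c2, D)),
                 tolerance = 1e-12)
    g2 <- volumeGrid(c(8, 8, 8))
    expect_error(forwardField(susceptibilityMap(array(0, c(8, 8, 8)), g2), D),
                 "grid mismatch")
})

test_that("spectrum division recovers F chi where the kernel is well-conditioned", {
    g <- volumeGrid(c(12, 14, 16))
    D <- dipoleKernel(g)
    set.seed(3)
    chi <- susceptibilityMap(array(rnorm(prod(gridShape(g))), gridShape(g)), g)
    b <- forwardField(chi, D)
    Fb <- fft(values(b))
    Fchi <- fft(values(chi))
    sel <- abs(values(D)) > 0.05
    expect_lt(max(Mod(Fb[sel] / values(D)[sel] - Fchi[sel])) / max(Mod(Fchi[sel])),
              1e-8)
})

test_that("uniform-sphere field matches the closed-form solution on the grid", {
    sh <- rep(64L, 3)
    g <- volumeGrid(sh)
    ctr <- (sh + 1) / 2
    X <- array(seq_len(sh[1]), dim = sh)
    Y <- array(rep(seq_len(sh[2]), each = sh[1]), dim = sh)
    Z <- array(rep(seq_len(sh[3]), each = sh[1] * sh[2]), dim = sh)
    r <- sqrt((X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2)
    R <- 8
    chi <- susceptibilityMap(array(as.numeric(r <= R), sh), g)
    b <- values(forwardField(chi, dipoleKernel(g)))
    ana <- sphereFieldAnalytic(sh, ctr, R)
    ## interior field vanishes; the discrete field agrees with the closed form
    ## away from the 2-voxel discretisation shell at the surface
    expect_lt(abs(b[ctr[1], ctr[2], ctr[3]]), 1e-6)
    interior <- r <= R - 2
    expect_lt(sqrt(mean((b[interior] - ana[interior])^2)), 0.01)
    expect_lt(max(abs(b[interior] - ana[interior])), 0.025)
    outside <- r > R + 2
    expect_lt(sqrt(mean((b[outside] - ana[outside])^2)), 0.005)
})
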