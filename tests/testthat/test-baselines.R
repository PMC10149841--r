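test_that("TKD divides exactly where the kernel exceeds the threshold", {
    g <- volumeGrid(c(12, 12, 12))
    D <- dipoleKernel(g)
    set.seed(51)
    b <- localFieldMap(array(rnorm(12^3, sd = 0.01), c(12, 12, 12)), g)
    delta <- 0.2
    chi <- tkdReconstruct(b, D, tkdConfig(delta = delta, psfCorrect = FALSE))
    Fchi <- fft(values(chi))
    Fb <- fft(values(b))
    keep <- abs(values(D)) >= delta
    expect_lt(max(Mod(Fchi[keep] - Fb[keep] / values(D)[keep])) /
                  max(Mod(Fchi[keep])), 1e-10)
})

test_that("at the 2/3 threshold every kernel value is replaced by the signed threshold", {
    D <- values(dipoleKernel(volumeGrid(c(16, 16, 16))))
    delta <- 2 / 3
    sgn <- ifelse(D >= 0, 1, -1)
    Dd <- ifelse(abs(D) >= delta, D, sgn * delta)
    ## exhaustive: |D| <= 2/3 everywhere with equality only on the B0 axis
    expect_true(all(abs(Dd) == delta))
    onAxis <- abs(D) == delta
    expect_true(all(Dd[onAxis] == D[onAxis]))
    expect_equal(sum(onAxis), 15)   # the nonzero k_z axis: N - 1 samples
})

test_that("the PSF correction factor is 1 when no nonzero frequency is thresholded", {
    ## 5^3 grid with anisotropic voxels: no frequency lands exactly on the
    ## magic-angle cone, so a small enough delta thresholds nothing but DC
    g <- volumeGrid(c(5, 5, 5), voxelSize = c(1.0, 1.3, 0.7))
    D <- dipoleKernel(g)
    expect_true(all(values(D)[-1] != 0))   # DC is the only zero
    minNZ <- min(abs(values(D))[values(D) != 0])
    delta <- 0.9 * minNZ
    set.seed(52)
    chi <- susceptibilityMap(array(rnorm(125, sd = 0.1), c(5, 5, 5)), g)
    b <- forwardField(chi, D)
    raw <- tkdReconstruct(b, D, tkdConfig(delta = delta, psfCorrect = FALSE))
    cor <- tkdReconstruct(b, D, tkdConfig(delta = delta, psfCorrect = TRUE))
    expect_equal(values(cor), values(raw), tolerance = 1e-12)
    ## and the output equals direct inversion on the well-conditioned spectrum
    Fraw <- fft(values(raw))
    Fchi <- fft(values(chi))
    nz <- values(D) != 0
    expect_lt(max(Mod(Fraw[nz] - Fchi[nz])), 1e-8 * max(Mod(Fchi[nz])))
})

test_that("TKD is linear in the field and PSF correction is a global positive scalar", {
    g <- volumeGrid(c(10, 10, 10))
    D <- dipoleKernel(g)
    set.seed(53)
    b1 <- localFieldMap(array(rnorm(1000), c(10, 10, 10)), g)
    b2 <- localFieldMap(array(rnorm(1000), c(10, 10, 10)), g)
    cfg <- tkdConfig(delta = 0.3, psfCorrect = FALSE)
    lin <- localFieldMap(1.5 * values(b1) - 2 * values(b2), g)
    expect_equal(values(tkdReconstruct(lin, D, cfg)),
                 1.5 * values(tkdReconstruct(b1, D, cfg)) -
                     2 * values(tkdReconstruct(b2, D, cfg)),
                 tolerance = 1e-10)
    raw <- values(tkdReconstruct(b1, D, tkdConfig(0.3, FALSE)))
    cor <- values(tkdReconstruct(b1, D, tkdConfig(0.3, TRUE)))
    ratio <- cor[raw != 0] / raw[raw != 0]
    expect_lt(diff(range(ratio)), 1e-9)
    expect_gt(mean(ratio), 0)
    expect_error(tkdConfig(delta = 0.8), "2/3")
})

test_that("unregularized CS with an invertible band equals the direct inverse transform", {
    ## synthetic no-cone kernel: 1/3 at every nonzero frequency
    g <- volumeGrid(c(8, 8, 8))
    kv <- array(1 / 3, c(8, 8, 8)); kv[1, 1, 1] <- 0
    K <- new("DipoleKernelSpectrum", grid = g, values = kv)
    sk <- bandLimit(K, 0.2)            # everything except DC
    set.seed(54)
    b <- localFieldMap(array(rnorm(512, sd = 0.1), c(8, 8, 8)), g)
    rec <- csReconstruct(b, K, sk, lambdaL1 = 0, maxIter = 50, tol = 1e-12)
    nu <- computeNu(b, K, sk)
    direct <- Re(fft(values(nu), inverse = TRUE)) / 512
    expect_equal(values(reconChi(rec)), direct, tolerance = 1e-8)
})

test_that("CS objective is non-increasing and huge lambda drives chi to zero", {
    fx <- phantomFixture()
    ph <- fx$phantom
    sk <- bandLimit(fx$kernel, 0.25)
    rec <- csReconstruct(ph@field, fx$kernel, sk, lambdaL1 = 0.1, maxIter = 25)
    expect_true(all(diff(objectiveHistory(rec)) <= 1e-9))
    big <- csReconstruct(ph@field, fx$kernel, sk, lambdaL1 = 1e3, maxIter = 5)
    expect_true(all(values(reconChi(big)) == 0))
})

test_that("with an all-ones mask the regularized IS and CS solvers coincide", {
    g <- volumeGrid(c(8, 8, 8))
    D <- dipoleKernel(g)
    ones <- imageSupport(array(1, c(8, 8, 8)), g)
    set.seed(55)
    b <- localFieldMap(array(rnorm(512, sd = 0.05), c(8, 8, 8)), g)
    lam <- 1e-3
    ris <- isReconstructRegularized(b, ones, D,
        solverConfig(tWell = 0.25, lambdaL1 = lam, maxIter = 60, tol = 1e-12))
    cs <- csReconstruct(b, D, bandLimit(D, 0.25), lambdaL1 = lam,
                        maxIter = 60, tol = 1e-12)
    ## identical objectives => identical iterates, voxel for voxel
    expect_equal(values(reconChi(ris)), values(reconChi(cs)), tolerance = 1e-10)
})
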