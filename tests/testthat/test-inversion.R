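test_that("nu is the deconvolved spectrum on the support and exactly zero off it", {
    g <- volumeGrid(c(12, 12, 12))
    D <- dipoleKernel(g)
    sk <- bandLimit(D, 0.2)
    ## zero field gives zero nu
    z <- computeNu(localFieldMap(array(0, c(12, 12, 12)), g), D, sk)
    expect_true(all(values(z) == 0))
    ## algebraic round trip: nu = F chi on the support for b = forward(chi)
    set.seed(14)
    chi <- susceptibilityMap(array(rnorm(12^3), c(12, 12, 12)), g)
    b <- forwardField(chi, D)
    nu <- computeNu(b, D, sk)
    Fchi <- fft(values(chi))
    on <- values(sk) == 1
    expect_lt(max(Mod(values(nu)[on] - Fchi[on])) / max(Mod(Fchi[on])), 1e-8)
    expect_true(all(values(nu)[!on] == 0))
})

test_that("a support touching kernel zeros is rejected by the division guard", {
    g <- volumeGrid(c(8, 8, 8))
    D <- dipoleKernel(g)
    badVals <- values(bandLimit(D, 0.2))
    badVals[1, 1, 1] <- 1   # DC has D = 0
    bad <- new("KSpaceSupport", grid = g, values = badVals, tWell = 0)
    f <- localFieldMap(array(1, c(8, 8, 8)), g)
    expect_error(computeNu(f, D, bad), "machine epsilon")
})

test_that("zero field reconstructs to zero in at most one iteration", {
    g <- volumeGrid(c(10, 10, 10))
    D <- dipoleKernel(g)
    mask <- boxMask(g, c(3, 3, 3), c(8, 8, 8))
    rec <- isReconstruct(localFieldMap(array(0, c(10, 10, 10)), g), mask, D)
    expect_true(all(values(reconChi(rec)) == 0))
    expect_lte(iterations(rec), 1L)
    expect_true(converged(rec))
})

test_that("the CGLS solution matches the dense minimum-norm least-squares oracle", {
    set.seed(33)
    for (case in 1:3) {
        sh <- list(c(8, 8, 8), c(6, 7, 8), c(10, 6, 8))[[case]]
        g <- volumeGrid(sh)
        D <- dipoleKernel(g)
        mv <- array(as.numeric(array(runif(prod(sh)), sh) > 0.55), sh)
        truth <- array(rnorm(prod(sh)), sh) * mv
        b <- forwardField(susceptibilityMap(truth, g), D)
        rec <- isReconstruct(b, imageSupport(mv, g), D,
                             solverConfig(tWell = 0.25, tol = 1e-12, maxIter = 600))
        ref <- denseMinNormIS(values(b), mv, values(D), values(bandLimit(D, 0.25)))
        expect_lt(sqrt(sum((values(reconChi(rec)) - ref)^2)) / sqrt(sum(ref^2)),
                  1e-6)
    }
})

test_that("reconstruction respects the mask support and its residual decreases", {
    fx <- phantomFixture()
    ph <- fx$phantom
    rec <- isReconstruct(ph@field, ph@mask, fx$kernel,
                         solverConfig(tWell = 0.25, maxIter = 40))
    chiv <- values(reconChi(rec))
    expect_true(all(chiv[values(ph@mask) == 0] == 0))      # S_chi chi = chi
    expect_true(all(diff(residualHistory(rec)) <= 1e-9))   # monotone residual
})

test_that("the reconstruction fills in spectral energy inside the excluded cone", {
    fx <- phantomFixture()
    ph <- fx$phantom
    rec <- isReconstruct(ph@field, ph@mask, fx$kernel,
                         solverConfig(tWell = 0.25, maxIter = 40))
    sk <- values(bandLimit(fx$kernel, 0.25))
    Frec <- fft(values(reconChi(rec)))
    exEnergy <- sum(Mod(Frec[sk == 0])^2)
    expect_gt(exEnergy, 0)
    ## and a substantial fraction of total energy lies in the filled-in region
    expect_gt(exEnergy / sum(Mod(Frec)^2), 0.01)
})

test_that("degenerate configurations are rejected", {
    g <- volumeGrid(c(8, 8, 8))
    D <- dipoleKernel(g)
    f <- localFieldMap(array(0, c(8, 8, 8)), g)
    empty <- imageSupport(array(0, c(8, 8, 8)), g)
    expect_error(isReconstruct(f, empty, D), "mask is empty")
    mask <- boxMask(g, c(3, 3, 3), c(6, 6, 6))
    expect_error(isReconstruct(f, mask, D, solverConfig(tWell = 0.7)),
                 "band limit is empty")
    expect_error(isReconstruct(f, mask, D, solverConfig(tWell = 0)), "tWell")
})

test_that("with lambda = 0 the proximal solver minimises the same data term as CGLS", {
    g <- volumeGrid(c(16, 16, 16))
    D <- dipoleKernel(g)
    mask <- boxMask(g, c(5, 5, 5), c(12, 12, 12))
    set.seed(19)
    truth <- array(rnorm(16^3, sd = 0.05), c(16, 16, 16)) * values(mask)
    b <- forwardField(susceptibilityMap(truth, g), D)
    cg <- isReconstruct(b, mask, D, solverConfig(tWell = 0.25, tol = 1e-12,
                                                 maxIter = 500))
    px <- isReconstructRegularized(b, mask, D,
        solverConfig(tWell = 0.25, lambdaL1 = 0, tol = 1e-14, maxIter = 1500))
    ## identical objectives: the proximal iterate's data residual approaches
    ## the CGLS least-squares optimum (iterate-level identity would need full
    ## convergence of plain gradient descent on an ill-conditioned system)
    dataResid <- function(chi) {
        sk <- values(bandLimit(D, 0.25))
        n <- sqrt(length(sk))
        nu <- computeNu(applySupport(b, mask), D, bandLimit(D, 0.25))
        sqrt(sum(Mod(sk * fft(values(chi)) / n - values(nu) / n)^2))
    }
    rCG <- dataResid(reconChi(cg))
    rPX <- dataResid(reconChi(px))
    expect_lt(rPX, rCG * 1.05 + 1e-9)
    expect_gt(rPX, rCG * 0.999)   # CGLS is the optimum; prox cannot beat it
})

test_that("very large lambda shrinks the regularized solution to zero", {
    fx <- phantomFixture()
    ph <- fx$phantom
    rec <- isReconstructRegularized(ph@field, ph@mask, fx$kernel,
        solverConfig(tWell = 0.25, lambdaL1 = 1e3, maxIter = 10))
    expect_true(all(values(reconChi(rec)) == 0))
})

test_that("the regularized objective is non-increasing (monotone scheme)", {
    fx <- phantomFixture()
    ph <- fx$phantom
    rec <- isReconstructRegularized(ph@field, ph@mask, fx$kernel,
        solverConfig(tWell = 0.25, lambdaL1 = 0.1, maxIter = 30))
    expect_true(all(diff(objectiveHistory(rec)) <= 1e-9))
})

test_that("threshold sweep reports one row per threshold and consistent optima", {
    g <- volumeGrid(c(16, 16, 16))
    D <- dipoleKernel(g)
    mask <- boxMask(g, c(4, 4, 4), c(13, 13, 13))
    set.seed(23)
    truth <- susceptibilityMap(
        array(rnorm(16^3, sd = 0.05), c(16, 16, 16)) * values(mask), g)
    b <- forwardField(truth, D)
    one <- thresholdSweep(b, mask, D, truth, 0.25,
                          solverConfig(maxIter = 30))
    expect_identical(nrow(one), 1L)
    tab <- thresholdSweep(b, mask, D, truth, c(0.1, 0.25, 0.4),
                          solverConfig(maxIter = 30))
    expect_identical(nrow(tab), 3L)
    expect_equal(attr(tab, "optXsim")$xsim, max(tab$xsim))
    expect_equal(attr(tab, "optPsnr")$psnr, max(tab$psnr))
    expect_error(thresholdSweep(b, mask, D, truth, numeric(0)), "non-empty")
    expect_error(thresholdSweep(b, mask, D, truth, c(0.4, 0.1)), "sorted")
})
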