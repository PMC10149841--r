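## Independent reference implementations used as oracles. These deliberately
## avoid the package's code paths (direct loops and dense algebra instead of
## FFT-based operators).

## Dipole kernel by direct evaluation at every voxel.
bruteKernel <- function(shape, voxelSize = c(1, 1, 1), b0 = c(0, 0, 1)) {
    b0 <- b0 / sqrt(sum(b0^2))
    freqs <- function(n, d) c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1)) / (n * d)
    out <- array(0, dim = shape)
    kx <- freqs(shape[1], voxelSize[1])
    ky <- freqs(shape[2], voxelSize[2])
    kz <- freqs(shape[3], voxelSize[3])
    for (i in seq_len(shape[1])) for (j in seq_len(shape[2]))
        for (l in seq_len(shape[3])) {
            k <- c(kx[i], ky[j], kz[l])
            k2 <- sum(k^2)
            out[i, j, l] <- if (k2 == 0) 0 else 1 / 3 - sum(k * b0)^2 / k2
        }
    out
}

## Minimum-norm least-squares solution of the space-limited band-limited
## system by explicit dense build (unitary DFT columns) and pseudoinverse of
## the stacked real representation.
denseMinNormIS <- function(fieldVals, maskVals, Dvals, skVals) {
    sh <- dim(maskVals)
    n <- prod(sh)
    midx <- which(maskVals == 1)
    kidx <- which(skVals == 1)
    Amat <- matrix(0 + 0i, length(kidx), length(midx))
    for (j in seq_along(midx)) {
        e <- array(0, sh)
        e[midx[j]] <- 1
        Amat[, j] <- (stats::fft(e) / sqrt(n))[kidx]
    }
    fm <- fieldVals * maskVals
    nu <- (stats::fft(fm) / sqrt(n))[kidx] / Dvals[kidx]
    Astack <- rbind(Re(Amat), Im(Amat))
    bstack <- c(Re(nu), Im(nu))
    x <- MASS::ginv(Astack, tol = 1e-10) %*% bstack
    out <- array(0, sh)
    out[midx] <- x
    out
}

## Closed-form field of a uniform sphere (chi = 1 ppm, B0 along z), evaluated
## at the grid's voxel centres: zero inside, dipole-like decay outside.
sphereFieldAnalytic <- function(shape, centre, radius) {
    X <- array(seq_len(shape[1]), dim = shape)
    Y <- array(rep(seq_len(shape[2]), each = shape[1]), dim = shape)
    Z <- array(rep(seq_len(shape[3]), each = shape[1] * shape[2]), dim = shape)
    dx <- X - centre[1]; dy <- Y - centre[2]; dz <- Z - centre[3]
    r <- sqrt(dx^2 + dy^2 + dz^2)
    cth2 <- ifelse(r > 0, (dz / pmax(r, 1e-12))^2, 0)
    ifelse(r <= radius, 0, (radius^3 / 3) * (3 * cth2 - 1) / pmax(r, 1e-12)^3)
}

## PSNR by direct evaluation (second implementation).
directPSNR <- function(xv, refv, roiv) {
    sel <- roiv == 1
    peak <- max(refv[sel]) - min(refv[sel])
    10 * log10(peak^2 / mean((xv[sel] - refv[sel])^2))
}

## Small box mask helper.
boxMask <- function(grid, lo, hi) {
    m <- array(0, gridShape(grid))
    m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1
    imageSupport(m, grid)
}

## Cached default phantom (64^3, SNR 100) shared by the heavier tests.
phantomFixture <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            ph <- makePhantom(shape = 64, seed = 42)
            D <- dipoleKernel(voxelGrid(ph@chiTruth))
            cache <<- list(phantom = simulateField(ph, D, snr = 100), kernel = D)
        }
        cache
    }
})
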