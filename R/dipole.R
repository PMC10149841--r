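## Fourier convention used throughout: F = stats::fft (unnormalised forward),
## F^H = fft(..., inverse = TRUE)/N, so that F^H F = identity exactly.
fwdFFT <- function(x) stats::fft(x)
invFFT <- function(X) stats::fft(X, inverse = TRUE) / length(X)

## FFT-layout frequency coordinates (cycles/mm) along one axis.
fftFreq <- function(n, delta) {
    idx <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
    idx / (n * delta)
}

stopIfGridMismatch <- function(a, b) {
    ga <- if (is(a, "VolumeGrid")) a else voxelGrid(a)
    gb <- if (is(b, "VolumeGrid")) b else voxelGrid(b)
    if (!all(ga@shape == gb@shape))
        stop("grid mismatch: shapes ", paste(ga@shape, collapse = "x"), " vs ",
             paste(gb@shape, collapse = "x"), call. = FALSE)
    invisible(TRUE)
}

#' Construct typed volumes on a grid
#'
#' @param values 3D numeric array matching the grid shape. For
#'   \code{imageSupport} the array is binarised with the convention
#'   value > 0.5 is inside.
#' @param grid a \linkS4class{VolumeGrid}; defaults to an isotropic 1 mm grid
#'   of the array's shape with B0 along the third axis.
#' @return A \linkS4class{SusceptibilityMap}, \linkS4class{LocalFieldMap} or
#'   \linkS4class{ImageSupport}.
#' @name volume-constructors
NULL

defaultGrid <- function(values) volumeGrid(dim(values))

#' @rdname volume-constructors
#' @export
susceptibilityMap <- function(values, grid = defaultGrid(values))
    new("SusceptibilityMap", grid = grid, values = values)

#' @rdname volume-constructors
#' @export
localFieldMap <- function(values, grid = defaultGrid(values))
    new("LocalFieldMap", grid = grid, values = values)

#' @rdname volume-constructors
#' @export
imageSupport <- function(values, grid = defaultGrid(values)) {
    v <- array(as.numeric(values > 0.5), dim = dim(values))
    new("ImageSupport", grid = grid, values = v)
}

#' Frequency-domain dipole kernel
#'
#' Evaluates the continuous dipole kernel D(k) = 1/3 - (k . h)^2 / |k|^2 at the
#' discrete frequencies k_i = n_i / (N_i * delta_i) of the grid (anisotropic
#' voxel sizes enter through delta_i), with h the unit B0 direction. The
#' expression is undefined at k = 0; the zero-frequency value is set to 0, so
#' forward-simulated fields have zero mean over the periodic domain. The array
#' is in FFT layout (DC at [1,1,1]).
#'
#' D vanishes on the cone at the magic angle, (k . h)^2 / |k|^2 = 1/3, which is
#' what makes direct dipole inversion ill-posed.
#'
#' @param grid a \linkS4class{VolumeGrid}.
#' @return A \linkS4class{DipoleKernelSpectrum}.
#' @examples
#' D <- dipoleKernel(volumeGrid(c(32, 32, 32)))
#' range(values(D))   # within [-2/3, 1/3]
#' @export
dipoleKernel <- function(grid) {
    stopifnot(is(grid, "VolumeGrid"))
    validObject(grid)
    sh <- grid@shape
    kx <- fftFreq(sh[1], grid@voxelSize[1])
    ky <- fftFreq(sh[2], grid@voxelSize[2])
    kz <- fftFreq(sh[3], grid@voxelSize[3])
    h <- grid@b0Dir
    ## outer sums via recycling: arrays indexed [x, y, z]
    KX <- array(kx, dim = sh)
    KY <- array(rep(ky, each = sh[1]), dim = sh)
    KZ <- array(rep(kz, each = sh[1] * sh[2]), dim = sh)
    k2 <- KX^2 + KY^2 + KZ^2
    kdh <- KX * h[1] + KY * h[2] + KZ * h[3]
    D <- 1 / 3 - kdh^2 / k2
    D[1, 1, 1] <- 0
    D <- pmin(pmax(D, -2 / 3), 1 / 3)   # clamp float noise at the bounds
    new("DipoleKernelSpectrum", grid = grid, values = D)
}

#' Forward susceptibility-to-field model
#'
#' Computes the local field b = Re(F^H (D . F chi)) generated by a
#' susceptibility distribution: elementwise multiplication by the dipole kernel
#' in the frequency domain. Because D is real and even, the imaginary residue
#' is float noise only and is discarded. Output is in ppm, like the input.
#'
#' @param chi a \linkS4class{SusceptibilityMap}.
#' @param kernel a \linkS4class{DipoleKernelSpectrum} on the same grid.
#' @return A \linkS4class{LocalFieldMap}.
#' @examples
#' g <- volumeGrid(c(16, 16, 16))
#' chi <- susceptibilityMap(array(0, gridShape(g)), g)
#' b <- forwardField(chi, dipoleKernel(g))   # identically zero
#' @export
forwardField <- function(chi, kernel) {
    stopifnot(is(chi, "SusceptibilityMap"), is(kernel, "DipoleKernelSpectrum"))
    stopIfGridMismatch(chi, kernel)
    b <- Re(invFFT(kernel@values * fwdFFT(chi@values)))
    localFieldMap(b, chi@grid)
}
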