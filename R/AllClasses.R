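#' @import methods
NULL

## Central data objects are lightweight S4 wrappers around 3D arrays: QSM works
## on single volumes (field, susceptibility, masks, spectra) that share a
## sampling grid, so the grid is carried explicitly and checked on every
## operation rather than trusted implicitly.

#' Sampling grid of a 3D volume
#'
#' Describes the discretisation shared by all volumes in a reconstruction:
#' matrix size, voxel size in mm, and the unit vector of the main magnetic
#' field (B0) expressed in the image frame.
#'
#' @slot shape integer vector of length 3, voxels per axis (each >= 2).
#' @slot voxelSize numeric vector of length 3, voxel edge lengths in mm.
#' @slot b0Dir numeric unit vector of length 3, direction of B0.
#' @export
setClass("VolumeGrid",
    representation(shape = "integer", voxelSize = "numeric", b0Dir = "numeric"),
    validity = function(object) {
        msg <- character()
        if (length(object@shape) != 3L || any(object@shape < 2L))
            msg <- c(msg, "shape must be three integers, each >= 2")
        if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
            any(object@voxelSize <= 0))
            msg <- c(msg, "voxelSize must be three positive lengths (mm)")
        if (length(object@b0Dir) != 3L || any(!is.finite(object@b0Dir)) ||
            abs(sqrt(sum(object@b0Dir^2)) - 1) > 1e-9)
            msg <- c(msg, "b0Dir must be a unit 3-vector (|b0Dir| = 1 within 1e-9)")
        if (length(msg)) msg else TRUE
    })

#' Construct a VolumeGrid
#'
#' @param shape three positive integers (voxels per axis).
#' @param voxelSize three voxel edge lengths in mm (default isotropic 1 mm).
#' @param b0Dir B0 direction vector; normalised to unit length. Default is the
#'   third image axis.
#' @return A \linkS4class{VolumeGrid}.
#' @examples
#' g <- volumeGrid(c(64, 64, 64))
#' @export
volumeGrid <- function(shape, voxelSize = c(1, 1, 1), b0Dir = c(0, 0, 1)) {
    b0Dir <- as.numeric(b0Dir)
    nrm <- sqrt(sum(b0Dir^2))
    if (is.finite(nrm) && nrm > 0) b0Dir <- b0Dir / nrm
    new("VolumeGrid", shape = as.integer(shape),
        voxelSize = as.numeric(voxelSize), b0Dir = b0Dir)
}

## Virtual parent for grid-attached real volumes.
setClass("Volume3D",
    representation(grid = "VolumeGrid", values = "array", "VIRTUAL"),
    validity = function(object) {
        if (!identical(dim(object@values), NULL) &&
            !all(dim(object@values) == object@grid@shape))
            return("values shape does not match grid shape")
        TRUE
    })

finiteRealValidity <- function(object) {
    if (!is.numeric(object@values)) return("values must be a real array")
    if (any(!is.finite(object@values))) return("values must be finite")
    TRUE
}

#' Magnetic susceptibility map (chi, ppm)
#' @slot grid the \linkS4class{VolumeGrid}.
#' @slot values 3D real array of susceptibility in ppm.
#' @export
setClass("SusceptibilityMap", contains = "Volume3D", validity = finiteRealValidity)

#' Local field map (fractional field shift, ppm)
#'
#' The B0 perturbation attributable to sources inside the mask, after
#' background-field removal, expressed as a fractional shift in ppm.
#' @slot grid the \linkS4class{VolumeGrid}.
#' @slot values 3D real array in ppm.
#' @export
setClass("LocalFieldMap", contains = "Volume3D", validity = finiteRealValidity)

#' Binary image-space support (mask)
#'
#' The mask S_chi containing the support of the susceptibility sources; the
#' method's key assumption is S_chi * chi = chi.
#' @slot grid the \linkS4class{VolumeGrid}.
#' @slot values 3D array with values in {0, 1}.
#' @export
setClass("ImageSupport", contains = "Volume3D",
    validity = function(object) {
        v <- object@values
        if (!all(v == 0 | v == 1)) return("mask values must be 0 or 1")
        TRUE
    })

#' Frequency-domain dipole kernel D
#'
#' The Fourier-domain response 1/3 - (k . h)^2 / |k|^2 relating susceptibility
#' to field, sampled on the grid in FFT layout (DC at index [1,1,1]).
#' @slot grid the \linkS4class{VolumeGrid}.
#' @slot values 3D real array, dimensionless, in [-2/3, 1/3]; 0 at DC.
#' @export
setClass("DipoleKernelSpectrum", contains = "Volume3D",
    validity = function(object) {
        v <- object@values
        msg <- character()
        if (any(!is.finite(v))) msg <- c(msg, "kernel values must be finite")
        else {
            if (min(v) < -2 / 3 - 1e-12 || max(v) > 1 / 3 + 1e-12)
                msg <- c(msg, "kernel values must lie in [-2/3, 1/3]")
            if (abs(v[1, 1, 1]) > 0)
                msg <- c(msg, "kernel value at zero frequency must be 0")
        }
        if (length(msg)) msg else TRUE
    })

#' Binary frequency-domain support (band limit)
#'
#' The band limit S_k retaining the well-posed region |D| > tWell of k-space,
#' in FFT layout.
#' @slot grid the \linkS4class{VolumeGrid}.
#' @slot values 3D array with values in {0, 1}, FFT layout.
#' @slot tWell the threshold that generated the support (dimensionless).
#' @export
setClass("KSpaceSupport", contains = "Volume3D",
    representation(tWell = "numeric"),
    validity = function(object) {
        v <- object@values
        msg <- character()
        if (!all(v == 0 | v == 1)) msg <- c(msg, "support values must be 0 or 1")
        if (length(object@tWell) != 1L || !is.finite(object@tWell) ||
            object@tWell < 0)
            msg <- c(msg, "tWell must be a single non-negative number")
        else if (object@tWell > 0 && length(v) && v[1, 1, 1] != 0)
            msg <- c(msg, "zero-frequency voxel must be excluded when tWell > 0")
        if (length(msg)) msg else TRUE
    })

#' Band-limited frequency-domain input data (nu)
#'
#' The directly deconvolved spectrum nu = (F b) / D, defined only on the band
#' limit and exactly zero elsewhere.
#' @slot grid the \linkS4class{VolumeGrid}.
#' @slot values 3D complex array (ppm), FFT layout.
#' @slot support the \linkS4class{KSpaceSupport} on which nu is defined.
#' @export
setClass("KSpaceInput",
    representation(grid = "VolumeGrid", values = "array", support = "KSpaceSupport"),
    validity = function(object) {
        msg <- character()
        if (!all(dim(object@values) == object@grid@shape))
            msg <- c(msg, "values shape does not match grid shape")
        if (!is.complex(object@values))
            msg <- c(msg, "values must be a complex array")
        else if (any(!is.finite(Re(object@values))) || any(!is.finite(Im(object@values))))
            msg <- c(msg, "values must be finite")
        else if (any(object@values[object@support@values == 0] != 0))
            msg <- c(msg, "values must be exactly 0 outside the support")
        if (length(msg)) msg else TRUE
    })

#' Solver configuration for incomplete-spectrum reconstruction
#'
#' @slot tWell band-limit threshold on |D| (dimensionless).
#' @slot tol relative residual tolerance for the iterative solver.
#' @slot maxIter iteration cap.
#' @slot lambdaL1 weight of the l1 wavelet penalty (0 disables regularization).
#' @slot waveletName sparsifying wavelet ("db2" or "haar").
#' @slot waveletLevels decomposition depth.
#' @export
setClass("SolverConfig",
    representation(tWell = "numeric", tol = "numeric", maxIter = "integer",
                   lambdaL1 = "numeric", waveletName = "character",
                   waveletLevels = "integer"),
    validity = function(object) {
        msg <- character()
        if (object@tol <= 0) msg <- c(msg, "tol must be > 0")
        if (object@maxIter < 1L) msg <- c(msg, "maxIter must be >= 1")
        if (object@lambdaL1 < 0) msg <- c(msg, "lambdaL1 must be >= 0")
        if (object@waveletLevels < 1L) msg <- c(msg, "waveletLevels must be >= 1")
        if (length(msg)) msg else TRUE
    })

#' Construct a SolverConfig
#'
#' Defaults match the settings used throughout: tWell = 0.25 (the XSIM-optimal
#' band limit), tol = 1e-6 relative, 100 iterations, Daubechies-2 wavelet with
#' 3 levels for the regularized variant.
#'
#' @param tWell,tol,maxIter,lambdaL1,waveletName,waveletLevels see slots.
#' @return A \linkS4class{SolverConfig}.
#' @export
solverConfig <- function(tWell = 0.25, tol = 1e-6, maxIter = 100L, lambdaL1 = 0,
                         waveletName = "db2", waveletLevels = 3L) {
    new("SolverConfig", tWell = as.numeric(tWell), tol = as.numeric(tol),
        maxIter = as.integer(maxIter), lambdaL1 = as.numeric(lambdaL1),
        waveletName = waveletName, waveletLevels = as.integer(waveletLevels))
}

#' TKD configuration
#' @slot delta kernel threshold in (0, 2/3]; default 2/3, the theoretical
#'   optimum for thresholded k-space division.
#' @slot psfCorrect apply the global point-spread-function scaling correction.
#' @export
setClass("TKDConfig",
    representation(delta = "numeric", psfCorrect = "logical"),
    validity = function(object) {
        if (object@delta <= 0 || object@delta > 2 / 3 + 1e-12)
            return("delta must lie in (0, 2/3]")
        TRUE
    })

#' Construct a TKDConfig
#' @param delta threshold in (0, 2/3].
#' @param psfCorrect logical; apply the global PSF scaling correction.
#' @return A \linkS4class{TKDConfig}.
#' @export
tkdConfig <- function(delta = 2 / 3, psfCorrect = TRUE)
    new("TKDConfig", delta = as.numeric(delta), psfCorrect = isTRUE(psfCorrect))

#' XSIM configuration
#'
#' Stabilisation constants are folded in the SSIM-standard way,
#' C_i = (K_i * L)^2 with L the dynamic range; the susceptibility-tuned
#' defaults are K1 = 0.01, K2 = 0.001.
#'
#' @slot k1,k2 stabilisation constants (> 0).
#' @slot windowSize odd edge length of the cubic sliding window (voxels).
#' @slot windowSigma standard deviation of the Gaussian window weights (voxels).
#' @slot dynamicRange L; NA means "max - min of the reference within the ROI".
#' @export
setClass("XsimConfig",
    representation(k1 = "numeric", k2 = "numeric", windowSize = "integer",
                   windowSigma = "numeric", dynamicRange = "numeric"),
    validity = function(object) {
        msg <- character()
        if (object@k1 <= 0 || object@k2 <= 0) msg <- c(msg, "k1 and k2 must be > 0")
        if (object@windowSize < 1L || object@windowSize %% 2L == 0L)
            msg <- c(msg, "windowSize must be odd and >= 1")
        if (object@windowSigma <= 0) msg <- c(msg, "windowSigma must be > 0")
        if (length(msg)) msg else TRUE
    })

#' Construct an XsimConfig
#' @param k1,k2,windowSize,windowSigma,dynamicRange see slots.
#' @return An \linkS4class{XsimConfig}.
#' @export
xsimConfig <- function(k1 = 0.01, k2 = 0.001, windowSize = 7L, windowSigma = 1.5,
                       dynamicRange = NA_real_)
    new("XsimConfig", k1 = as.numeric(k1), k2 = as.numeric(k2),
        windowSize = as.integer(windowSize), windowSigma = as.numeric(windowSigma),
        dynamicRange = as.numeric(dynamicRange))

#' Reconstruction result with solver diagnostics
#'
#' @slot chi the reconstructed \linkS4class{SusceptibilityMap}.
#' @slot residualHistory per-iteration data-term residual norm ||A chi_i - S_k nu||.
#' @slot objectiveHistory per-iteration objective value (regularized solvers;
#'   length 0 otherwise).
#' @slot iterations iterations performed.
#' @slot converged whether the stopping tolerance was reached before the cap.
#' @slot config echo of the effective solver settings.
#' @export
setClass("ReconResult",
    representation(chi = "SusceptibilityMap", residualHistory = "numeric",
                   objectiveHistory = "numeric", iterations = "integer",
                   converged = "logical", config = "list"),
    validity = function(object) {
        if (any(!is.finite(object@residualHistory)) ||
            any(object@residualHistory < 0))
            return("residualHistory must be finite and non-negative")
        TRUE
    })

#' Synthetic phantom bundle
#'
#' Ground-truth susceptibility with deep grey-matter nuclei and a focal
#' calcification, head mask, ROI label volume, and (after
#' \code{\link{simulateField}}) a forward-simulated noisy local field.
#'
#' @slot chiTruth ground-truth \linkS4class{SusceptibilityMap} (zero outside mask).
#' @slot mask head \linkS4class{ImageSupport}.
#' @slot labels 3D integer array; 0 = background, positive codes per ROI.
#' @slot labelNames named integer vector mapping ROI names to label codes.
#' @slot field \linkS4class{LocalFieldMap} or NULL before field simulation.
#' @slot noiseSigma standard deviation of the added field noise (ppm).
#' @slot seed the seed the phantom was generated with.
#' @export
setClass("PhantomData",
    representation(chiTruth = "SusceptibilityMap", mask = "ImageSupport",
                   labels = "array", labelNames = "integer", field = "ANY",
                   noiseSigma = "numeric", seed = "integer"),
    validity = function(object) {
        msg <- character()
        m <- object@mask@values
        if (any(object@chiTruth@values[m == 0] != 0))
            msg <- c(msg, "chiTruth must be exactly 0 outside the mask")
        if (any(object@labels[m == 0] != 0))
            msg <- c(msg, "all labelled voxels must lie inside the mask")
        if (length(msg)) msg else TRUE
    })
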