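#' Thresholded k-space division (TKD)
#'
#' Direct dipole inversion with the small kernel values replaced by the signed
#' threshold: chi = Re(F^H (F b / D_delta)) with D_delta(k) = D(k) where
#' |D(k)| >= delta and sign(D(k)) * delta elsewhere (sign(0) taken as +1, which
#' covers the cone zeros and the DC voxel). Thresholding rescales part of the
#' spectrum and biases the susceptibility low; the optional point-spread-
#' function correction divides the map by the global scalar c, the central PSF
#' value of the effective operator: c = mean over nonzero frequencies of
#' D / D_delta, normalised so that c = 1 when no nonzero frequency is
#' thresholded.
#'
#' @param field a \linkS4class{LocalFieldMap}.
#' @param kernel a \linkS4class{DipoleKernelSpectrum} on the same grid.
#' @param cfg a \linkS4class{TKDConfig} (default: delta = 2/3, PSF-corrected).
#' @return A \linkS4class{SusceptibilityMap}.
#' @export
tkdReconstruct <- function(field, kernel, cfg = tkdConfig()) {
    stopifnot(is(field, "LocalFieldMap"), is(kernel, "DipoleKernelSpectrum"),
              is(cfg, "TKDConfig"))
    stopIfGridMismatch(field, kernel)
    validObject(cfg)
    D <- kernel@values
    sgn <- ifelse(D >= 0, 1, -1)   # sign(0) := +1
    keep <- abs(D) >= cfg@delta
    Dd <- ifelse(keep, D, sgn * cfg@delta)
    chi <- Re(invFFT(fwdFFT(field@values) / Dd))
    if (cfg@psfCorrect) {
        ratio <- D / Dd
        ratio[1, 1, 1] <- NA   # DC excluded from the normalisation
        cfac <- mean(ratio, na.rm = TRUE)
        chi <- chi / cfac
    }
    susceptibilityMap(chi, field@grid)
}

#' Compressed-sensing dipole inversion
#'
#' Minimises ||S_k nu - S_k F chi||^2 + lambda ||Psi chi||_1 over the full
#' field of view: the same band-limited data term as the incomplete-spectrum
#' method but with no image-space support operator inside it — sparsity of the
#' wavelet coefficients replaces the support constraint. Solved by the same
#' monotone proximal-gradient scheme as
#' \code{\link{isReconstructRegularized}}; at sufficiently high lambda the two
#' reconstructions coincide.
#'
#' @param field a \linkS4class{LocalFieldMap}.
#' @param kernel a \linkS4class{DipoleKernelSpectrum}.
#' @param support the shared \linkS4class{KSpaceSupport} (tWell > 0).
#' @param lambdaL1 l1 penalty weight (default 1e-5, the PSNR-tuned value).
#' @param waveletName,waveletLevels sparsifying transform settings.
#' @param tol,maxIter solver settings.
#' @return A \linkS4class{ReconResult} with full-FOV chi (evaluate metrics
#'   within a mask).
#' @export
csReconstruct <- function(field, kernel, support, lambdaL1 = 1e-5,
                          waveletName = "db2", waveletLevels = 3L,
                          tol = 1e-6, maxIter = 100L) {
    stopifnot(is(field, "LocalFieldMap"), is(support, "KSpaceSupport"))
    stopIfGridMismatch(field, kernel)
    if (sum(support@values) == 0) stop("band limit is empty", call. = FALSE)
    nu <- computeNu(field, kernel, support)
    ones <- array(1, dim = dim(nu@values))
    ops <- makeUnitaryOperators(ones, support@values)
    rhs <- nu@values / sqrt(length(nu@values))
    sol <- proxGradSolve(ops$A, ops$AH, rhs, lambdaL1, waveletName,
                         as.integer(waveletLevels), tol, as.integer(maxIter))
    chi <- susceptibilityMap(Re(sol$x), field@grid)
    new("ReconResult", chi = chi, residualHistory = sol$residualHistory,
        objectiveHistory = sol$objectiveHistory, iterations = sol$iterations,
        converged = sol$converged,
        config = list(method = "cs", tWell = support@tWell, tol = tol,
                      maxIter = as.integer(maxIter), lambdaL1 = lambdaL1,
                      wavelet = waveletName, levels = as.integer(waveletLevels)))
}
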