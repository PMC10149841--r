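cnorm <- function(x) sqrt(sum(Mod(x)^2))

## Deterministic pseudo-random probe of a given shape (avoids touching the
## global RNG inside the solver).
probeLike <- function(template, phase = 1) {
    n <- length(template)
    v <- sin((seq_len(n)) * 0.7311 * phase + 0.237) + 0.5 * cos(seq_len(n) * 1.934)
    if (is.null(dim(template))) v else array(v, dim = dim(template))
}

#' Conjugate-gradient least squares on a matrix-free operator
#'
#' Solves min ||rhs - A x|| by CGLS from a zero start, given matrix-free
#' implementations of A and its adjoint. Starting from zero guarantees the
#' iterates stay in the row space of A, so on singular systems the solver
#' converges to the minimum-norm least-squares solution. The adjoint pairing
#' is verified on deterministic probes (<Ax, y> = <x, A^H y> within 1e-6
#' relative) before iterating.
#'
#' @param applyA function mapping a domain array to a range array.
#' @param applyAH function implementing the adjoint map.
#' @param rhs right-hand side (range array; may be complex).
#' @param tol relative residual tolerance ||rhs - A x|| / ||rhs||.
#' @param maxIter iteration cap.
#' @param checkAdjoint verify the adjoint contract before solving.
#' @return list with \code{x} (solution), \code{residualHistory} (norm of the
#'   residual after each iteration), \code{iterations}, \code{converged}.
#' @examples
#' a <- c(2, 0, 1)  # singular diagonal system
#' sol <- cglsSolve(function(x) a * x, function(y) a * y, c(4, 1, 3))
#' sol$x            # (2, 0, 3): zero on the null direction
#' @export
cglsSolve <- function(applyA, applyAH, rhs, tol = 1e-6, maxIter = 100L,
                      checkAdjoint = TRUE) {
    s0 <- applyAH(rhs)
    if (checkAdjoint) {
        px <- probeLike(s0, 1)
        py <- probeLike(rhs, 2) * (1 + 0i)
        lhs <- Re(sum(Conj(py) * applyA(px)))
        rhsIP <- Re(sum(Conj(applyAH(py)) * px))
        den <- max(abs(lhs), abs(rhsIP), .Machine$double.eps)
        if (abs(lhs - rhsIP) / den > 1e-6)
            stop("applyA/applyAH are not an adjoint pair (<Ax,y> = ",
                 signif(lhs, 8), " vs <x,A^H y> = ", signif(rhsIP, 8), ")",
                 call. = FALSE)
    }
    x <- s0 * 0
    r <- rhs
    s <- s0
    p <- s
    gamma <- sum(Mod(s)^2)
    gamma0 <- gamma
    bnorm <- cnorm(rhs)
    hist <- numeric(0)
    converged <- FALSE
    iter <- 0L
    if (bnorm == 0 || gamma == 0)
        return(list(x = x, residualHistory = numeric(0), iterations = 0L,
                    converged = TRUE))
    for (iter in seq_len(maxIter)) {
        q <- applyA(p)
        qn <- sum(Mod(q)^2)
        if (qn == 0) { iter <- iter - 1L; break }
        alpha <- gamma / qn
        x <- x + alpha * p
        r <- r - alpha * q
        res <- cnorm(r)
        if (!is.finite(res))
            stop("CGLS diverged (non-finite residual at iteration ", iter, ")",
                 call. = FALSE)
        if (length(hist) && res >= hist[length(hist)]) {
            ## numerical floor reached: undo the step and stop
            x <- x - alpha * p
            iter <- iter - 1L
            break
        }
        hist <- c(hist, res)
        if (res / bnorm <= tol) { converged <- TRUE; break }
        s <- applyAH(r)
        gammaNew <- sum(Mod(s)^2)
        ## least-squares convergence: the normal-equation residual A^H r has
        ## vanished (the data residual itself need not, on inconsistent
        ## systems); iterating past this point only accumulates rounding drift
        if (sqrt(gammaNew / gamma0) <= tol) { converged <- TRUE; break }
        if (gammaNew == 0) break
        beta <- gammaNew / gamma
        gamma <- gammaNew
        p <- s + beta * p
    }
    list(x = x, residualHistory = hist, iterations = iter, converged = converged)
}

#' Band-limited frequency-domain input data
#'
#' Computes nu = (F b) / D on the band limit (the "input data" of the
#' incomplete-spectrum method: the directly deconvolved spectrum) and exactly 0
#' on excluded frequencies. The division is safe because the support only
#' contains frequencies with |D| > tWell > 0.
#'
#' @param field a \linkS4class{LocalFieldMap}.
#' @param kernel a \linkS4class{DipoleKernelSpectrum} on the same grid.
#' @param support a \linkS4class{KSpaceSupport} with tWell > 0.
#' @return A \linkS4class{KSpaceInput}.
#' @export
computeNu <- function(field, kernel, support) {
    stopifnot(is(field, "LocalFieldMap"), is(kernel, "DipoleKernelSpectrum"),
              is(support, "KSpaceSupport"))
    stopIfGridMismatch(field, kernel)
    stopIfGridMismatch(field, support)
    sk <- support@values
    if (any(abs(kernel@values[sk == 1]) <= .Machine$double.eps))
        stop("support contains a frequency with |D| at machine epsilon; ",
             "division by D is unsafe (use tWell > 0)", call. = FALSE)
    nu <- array(0 + 0i, dim = dim(sk))
    idx <- sk == 1
    Fb <- fwdFFT(field@values)
    nu[idx] <- Fb[idx] / kernel@values[idx]
    new("KSpaceInput", grid = field@grid, values = nu, support = support)
}

## Matrix-free A = S_k F S_chi and its adjoint, in the unnormalised-F scaling
## (the LS minimiser is invariant to a common scaling of A and rhs).
makeOperators <- function(maskVals, skVals) {
    list(
        A = function(x) skVals * fwdFFT(maskVals * x),
        AH = function(y) maskVals * Re(stats::fft(skVals * y, inverse = TRUE)))
}

#' Incomplete-spectrum dipole inversion
#'
#' The core reconstruction: removes the ill-posed region of k-space (where the
#' dipole kernel is small) with a band limit S_k, and solves the space-limited,
#' band-limited normal equation A^H A chi = A^H nu, A = S_k F S_chi, by CGLS
#' from a zero start. Knowledge of the image support (the mask, available in
#' QSM from background-field removal) is what makes reconstruction from the
#' incomplete spectrum well posed; no sparsity prior is needed.
#'
#' The input field is masked with the reconstruction mask first (the method's
#' assumption S_chi chi = chi requires it), and the output is exactly zero
#' outside the mask.
#'
#' @param field a \linkS4class{LocalFieldMap} (ppm, background-removed).
#' @param mask an \linkS4class{ImageSupport} containing the sources.
#' @param kernel a \linkS4class{DipoleKernelSpectrum} on the same grid.
#' @param cfg a \linkS4class{SolverConfig}; \code{tWell} must be > 0. If
#'   \code{lambdaL1 > 0} the call is dispatched to
#'   \code{\link{isReconstructRegularized}}.
#' @return A \linkS4class{ReconResult}.
#' @examples
#' g <- volumeGrid(c(16, 16, 16))
#' D <- dipoleKernel(g)
#' m <- array(0, gridShape(g)); m[5:12, 5:12, 5:12] <- 1
#' mask <- imageSupport(m, g)
#' chi <- susceptibilityMap(m * 0.1, g)
#' b <- forwardField(chi, D)
#' rec <- isReconstruct(b, mask, D, solverConfig(tWell = 0.25))
#' @export
isReconstruct <- function(field, mask, kernel, cfg = solverConfig()) {
    stopifnot(is(cfg, "SolverConfig"))
    if (cfg@lambdaL1 > 0)
        return(isReconstructRegularized(field, mask, kernel, cfg))
    if (cfg@tWell <= 0)
        stop("tWell must be > 0 for incomplete-spectrum reconstruction",
             call. = FALSE)
    if (sum(mask@values) == 0) stop("mask is empty", call. = FALSE)
    sk <- bandLimit(kernel, cfg@tWell)
    if (sum(sk@values) == 0)
        stop("band limit is empty (tWell >= max |D|)", call. = FALSE)
    field <- applySupport(field, mask)
    nu <- computeNu(field, kernel, sk)
    ops <- makeOperators(mask@values, sk@values)
    sol <- cglsSolve(ops$A, ops$AH, nu@values, tol = cfg@tol,
                     maxIter = cfg@maxIter, checkAdjoint = FALSE)
    chi <- susceptibilityMap(Re(sol$x) * mask@values, field@grid)
    new("ReconResult", chi = chi, residualHistory = sol$residualHistory,
        objectiveHistory = numeric(0), iterations = sol$iterations,
        converged = sol$converged,
        config = list(method = "is", tWell = cfg@tWell, tol = cfg@tol,
                      maxIter = cfg@maxIter))
}

## Monotone proximal-gradient (ISTA with backtracking) for
## min ||rhs - A x||^2 + lambda ||Psi x||_1, with unitary-scaled operators so
## ||A|| <= 1 and the initial step 1/(2 L) = 0.5 is almost always accepted.
proxGradSolve <- function(applyA, applyAH, rhs, lambda, wavelet, levels,
                          tol, maxIter) {
    x <- applyAH(rhs) * 0
    dataTerm <- function(z) sum(Mod(rhs - applyA(z))^2)
    obj <- function(z, fz) fz + lambda * waveletL1(z, wavelet, levels)
    fx <- dataTerm(x)
    objHist <- numeric(0)
    resHist <- numeric(0)
    t <- 0.5
    converged <- FALSE
    iter <- 0L
    for (iter in seq_len(maxIter)) {
        g <- 2 * applyAH(applyA(x) - rhs)
        repeat {
            z <- waveletShrink(x - t * g, lambda * t, wavelet, levels)
            fz <- dataTerm(z)
            dx <- z - x
            if (fz <= fx + sum(g * dx) + sum(dx^2) / (2 * t) + 1e-12) break
            t <- t / 2
            if (t < 1e-12) { z <- x; fz <- fx; break }
        }
        x <- z
        fxNew <- fz
        objHist <- c(objHist, obj(x, fxNew))
        resHist <- c(resHist, sqrt(fxNew))
        fx <- fxNew
        if (iter > 1L &&
            abs(objHist[iter - 1L] - objHist[iter]) /
                max(objHist[iter], .Machine$double.eps) <= tol) {
            converged <- TRUE
            break
        }
    }
    list(x = x, objectiveHistory = objHist, residualHistory = resHist,
         iterations = iter, converged = converged)
}

## Unitary-scaled operators (||F/sqrt(N)|| = 1): the lambda scale then matches
## the formulation in which F^H = F^{-1}.
makeUnitaryOperators <- function(maskVals, skVals) {
    n <- sqrt(length(skVals))
    list(
        A = function(x) skVals * fwdFFT(maskVals * x) / n,
        AH = function(y) maskVals * Re(stats::fft(skVals * y, inverse = TRUE)) / n)
}

#' Wavelet-regularized incomplete-spectrum inversion
#'
#' Adds a sparsity-promoting penalty to the incomplete-spectrum data term,
#' minimising ||S_k nu - S_k F S_chi chi||^2 + lambda ||Psi chi||_1 with a
#' monotone proximal-gradient scheme (backtracking line search; the l1 prox is
#' soft thresholding in the orthonormal wavelet domain). With lambda = 0 this
#' minimises the same objective as \code{\link{isReconstruct}}.
#'
#' @inheritParams isReconstruct
#' @return A \linkS4class{ReconResult} with a per-iteration
#'   \code{objectiveHistory}.
#' @export
isReconstructRegularized <- function(field, mask, kernel, cfg = solverConfig(lambdaL1 = 1e-5)) {
    stopifnot(is(cfg, "SolverConfig"))
    if (cfg@tWell <= 0) stop("tWell must be > 0", call. = FALSE)
    if (sum(mask@values) == 0) stop("mask is empty", call. = FALSE)
    sk <- bandLimit(kernel, cfg@tWell)
    if (sum(sk@values) == 0) stop("band limit is empty", call. = FALSE)
    field <- applySupport(field, mask)
    nu <- computeNu(field, kernel, sk)
    ops <- makeUnitaryOperators(mask@values, sk@values)
    rhs <- nu@values / sqrt(length(nu@values))
    sol <- proxGradSolve(ops$A, ops$AH, rhs, cfg@lambdaL1, cfg@waveletName,
                         cfg@waveletLevels, cfg@tol, cfg@maxIter)
    chi <- susceptibilityMap(Re(sol$x) * mask@values, field@grid)
    new("ReconResult", chi = chi, residualHistory = sol$residualHistory,
        objectiveHistory = sol$objectiveHistory, iterations = sol$iterations,
        converged = sol$converged,
        config = list(method = "isreg", tWell = cfg@tWell, tol = cfg@tol,
                      maxIter = cfg@maxIter, lambdaL1 = cfg@lambdaL1,
                      wavelet = cfg@waveletName, levels = cfg@waveletLevels))
}

#' Band-limit threshold sweep
#'
#' Runs the incomplete-spectrum reconstruction over a list of band-limit
#' thresholds and scores each against a known ground truth with XSIM and PSNR
#' (both evaluated within the mask). The returned table carries the arg-max
#' rows for each metric as attributes \code{optXsim} and \code{optPsnr} (the
#' two optima may differ).
#'
#' @param field,mask,kernel as in \code{\link{isReconstruct}}.
#' @param truth ground-truth \linkS4class{SusceptibilityMap}.
#' @param thresholds strictly positive, sorted vector of tWell values.
#' @param cfg base \linkS4class{SolverConfig} (tWell is overridden per row).
#' @return data.frame with columns tWell, xsim, psnr.
#' @export
thresholdSweep <- function(field, mask, kernel, truth, thresholds,
                           cfg = solverConfig()) {
    if (length(thresholds) == 0)
        stop("thresholds must be a non-empty vector", call. = FALSE)
    if (any(thresholds <= 0) || is.unsorted(thresholds))
        stop("thresholds must be strictly positive and sorted", call. = FALSE)
    rows <- lapply(thresholds, function(tw) {
        c1 <- cfg; c1@tWell <- tw
        rec <- isReconstruct(field, mask, kernel, c1)
        data.frame(tWell = tw,
                   xsim = xsim(reconChi(rec), truth, mask),
                   psnr = psnr(reconChi(rec), truth, mask))
    })
    tab <- do.call(rbind, rows)
    attr(tab, "optXsim") <- tab[which.max(tab$xsim), , drop = FALSE]
    attr(tab, "optPsnr") <- tab[which.max(tab$psnr), , drop = FALSE]
    tab
}
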