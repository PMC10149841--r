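## Orthonormal periodized discrete wavelet transform in 3D, used as the
## sparsifying transform Psi of the l1-regularized solvers. Periodization (as
## opposed to symmetric extension) keeps the transform exactly orthonormal,
## so soft thresholding in the coefficient domain is the exact proximal
## operator of lambda * ||Psi x||_1.

waveletFilter <- function(name) {
    switch(name,
        haar = c(1, 1) / sqrt(2),
        db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
        stop("unknown wavelet '", name, "' (supported: haar, db2)", call. = FALSE))
}

## Analysis along the first axis of a matrix (n x m), periodic, one level.
## Returns rbind(approx, detail), each n/2 x m.
dwtAxis1 <- function(M, h) {
    n <- nrow(M)
    stopifnot(n %% 2L == 0L)
    L <- length(h)
    g <- rev(h) * (-1)^(seq_len(L) - 1)   # g[n] = (-1)^n h[L-1-n], 0-based
    ks <- 2L * (seq_len(n / 2L) - 1L)     # 0-based even shifts
    A <- matrix(0, n / 2L, ncol(M))
    D <- matrix(0, n / 2L, ncol(M))
    for (j in seq_len(L)) {
        idx <- ((ks + j - 1L) %% n) + 1L
        A <- A + h[j] * M[idx, , drop = FALSE]
        D <- D + g[j] * M[idx, , drop = FALSE]
    }
    rbind(A, D)
}

## Synthesis along the first axis (transpose of dwtAxis1; exact inverse).
idwtAxis1 <- function(M, h) {
    n <- nrow(M)
    half <- n / 2L
    L <- length(h)
    g <- rev(h) * (-1)^(seq_len(L) - 1)
    A <- M[seq_len(half), , drop = FALSE]
    D <- M[half + seq_len(half), , drop = FALSE]
    out <- matrix(0, n, ncol(M))
    ks <- 2L * (seq_len(half) - 1L)
    for (j in seq_len(L)) {
        idx <- ((ks + j - 1L) %% n) + 1L
        out[idx, ] <- out[idx, ] + h[j] * A + g[j] * D
    }
    out
}

## Apply the one-level transform along a given axis of a 3D array.
dwtAlong <- function(x, axis, h, inverse = FALSE) {
    d <- dim(x)
    perm <- c(axis, setdiff(1:3, axis))
    xp <- aperm(x, perm)
    M <- matrix(xp, nrow = d[axis])
    M <- if (inverse) idwtAxis1(M, h) else dwtAxis1(M, h)
    xp <- array(M, dim = d[perm])
    aperm(xp, order(perm))
}

#' 3D orthonormal discrete wavelet transform
#'
#' Multi-level separable 3D DWT with periodic boundary handling, packed in
#' place (the approximation block of each level occupies the low-index corner).
#' The transform is orthonormal: \code{idwt3d(dwt3d(x))} reconstructs exactly
#' and coefficient and signal energies agree (Parseval). Each array dimension
#' must be divisible by \code{2^levels}.
#'
#' @param x 3D numeric array.
#' @param wavelet "db2" (Daubechies, 2 vanishing moments; default) or "haar".
#' @param levels decomposition depth.
#' @return Coefficient array of the same shape (for \code{dwt3d}); the
#'   reconstructed array (for \code{idwt3d}).
#' @examples
#' x <- array(rnorm(8^3), c(8, 8, 8))
#' w <- dwt3d(x, "db2", 2)
#' max(abs(idwt3d(w, "db2", 2) - x))   # ~1e-15
#' @export
dwt3d <- function(x, wavelet = "db2", levels = 3L) {
    h <- waveletFilter(wavelet)
    d <- dim(x)
    if (any(d %% 2^levels != 0))
        stop("array dimensions must be divisible by 2^levels", call. = FALSE)
    out <- x
    for (lev in seq_len(levels)) {
        sub <- d %/% 2^(lev - 1L)
        blk <- out[seq_len(sub[1]), seq_len(sub[2]), seq_len(sub[3]), drop = FALSE]
        for (ax in 1:3) blk <- dwtAlong(blk, ax, h)
        out[seq_len(sub[1]), seq_len(sub[2]), seq_len(sub[3])] <- blk
    }
    out
}

#' @rdname dwt3d
#' @export
idwt3d <- function(x, wavelet = "db2", levels = 3L) {
    h <- waveletFilter(wavelet)
    d <- dim(x)
    if (any(d %% 2^levels != 0))
        stop("array dimensions must be divisible by 2^levels", call. = FALSE)
    out <- x
    for (lev in rev(seq_len(levels))) {
        sub <- d %/% 2^(lev - 1L)
        blk <- out[seq_len(sub[1]), seq_len(sub[2]), seq_len(sub[3]), drop = FALSE]
        for (ax in 3:1) blk <- dwtAlong(blk, ax, h, inverse = TRUE)
        out[seq_len(sub[1]), seq_len(sub[2]), seq_len(sub[3])] <- blk
    }
    out
}

softThreshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

## Largest level count compatible with the shape (at most `levels`).
compatibleLevels <- function(d, levels) {
    j <- 0L
    while (j < levels && all(d %% 2^(j + 1L) == 0)) j <- j + 1L
    j
}

## Exact prox of t * ||Psi x||_1 for the orthonormal periodized DWT. If the
## shape does not admit the requested depth the depth is reduced to the
## largest compatible one (odd dimensions fall back to identity + plain soft
## thresholding in image space, the levels = 0 limit).
waveletShrink <- function(x, t, wavelet, levels) {
    j <- compatibleLevels(dim(x), levels)
    if (j == 0L) return(softThreshold(x, t))
    idwt3d(softThreshold(dwt3d(x, wavelet, j), t), wavelet, j)
}

## l1 norm of the coefficients, consistent with waveletShrink.
waveletL1 <- function(x, wavelet, levels) {
    j <- compatibleLevels(dim(x), levels)
    if (j == 0L) return(sum(abs(x)))
    sum(abs(dwt3d(x, wavelet, j)))
}
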