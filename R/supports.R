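#' Frequency-domain band limit from the dipole kernel
#'
#' Splits k-space into well-posed and ill-posed regions by thresholding the
#' dipole kernel magnitude: a frequency is retained iff |D| > tWell (strict,
#' no transition band). At the maximum of |D| (2/3) the support is therefore
#' empty, and for any tWell > 0 the zero-frequency voxel is excluded because
#' D(0) = 0 — the reconstruction recovers the volume mean through the
#' image-space support constraint instead.
#'
#' @param kernel a \linkS4class{DipoleKernelSpectrum}.
#' @param tWell non-negative threshold on |D| (dimensionless).
#' @return A \linkS4class{KSpaceSupport}.
#' @examples
#' D <- dipoleKernel(volumeGrid(c(16, 16, 16)))
#' sk <- bandLimit(D, 0.25)
#' mean(values(sk))   # fraction of k-space retained
#' @export
bandLimit <- function(kernel, tWell) {
    stopifnot(is(kernel, "DipoleKernelSpectrum"))
    if (length(tWell) != 1L || !is.finite(tWell) || tWell < 0)
        stop("tWell must be a single non-negative number", call. = FALSE)
    v <- array(as.numeric(abs(kernel@values) > tWell), dim = dim(kernel@values))
    new("KSpaceSupport", grid = kernel@grid, values = v, tWell = as.numeric(tWell))
}

## Integer offsets of the discrete ball |o| <= diameter/2 (Euclidean, voxels).
ballOffsets <- function(diameter) {
    r <- diameter / 2
    ri <- floor(r)
    g <- as.matrix(expand.grid(x = -ri:ri, y = -ri:ri, z = -ri:ri))
    g[rowSums(g^2) <= r^2 + 1e-12, , drop = FALSE]
}

## Shift a 3D array by integer offset o, zero-filling; out(v) = a(v - o).
shiftArray <- function(a, o) {
    d <- dim(a)
    out <- array(0, dim = d)
    src <- dst <- vector("list", 3)
    for (i in 1:3) {
        if (o[i] >= 0) { dst[[i]] <- (1 + o[i]):d[i]; src[[i]] <- 1:(d[i] - o[i]) }
        else           { dst[[i]] <- 1:(d[i] + o[i]); src[[i]] <- (1 - o[i]):d[i] }
        if (abs(o[i]) >= d[i]) return(out)
    }
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
}

#' Morphological erosion or dilation of a mask
#'
#' Erodes or dilates a binary mask with a discrete ball structuring element:
#' the set of integer offsets o with Euclidean norm |o| <= diameter/2 in voxel
#' units. Diameter 1 is the single-voxel ball, i.e. the identity. Boundaries
#' are zero-padded (the volume does not wrap).
#'
#' @param mask an \linkS4class{ImageSupport}.
#' @param diameter ball diameter in voxels (positive integer).
#' @param mode "erode" or "dilate".
#' @return An \linkS4class{ImageSupport}. An erosion that empties the mask
#'   returns the empty mask with a warning rather than failing.
#' @export
morphMask <- function(mask, diameter, mode = c("erode", "dilate")) {
    stopifnot(is(mask, "ImageSupport"))
    mode <- match.arg(mode)
    if (length(diameter) != 1L || diameter < 1 || diameter != round(diameter))
        stop("diameter must be a positive integer (voxels)", call. = FALSE)
    offs <- ballOffsets(diameter)
    m <- mask@values
    acc <- NULL
    for (i in seq_len(nrow(offs))) {
        s <- shiftArray(m, if (mode == "erode") -offs[i, ] else offs[i, ])
        acc <- if (is.null(acc)) s
               else if (mode == "erode") pmin(acc, s) else pmax(acc, s)
    }
    if (mode == "erode" && sum(acc) == 0)
        warning("erosion produced an empty mask", call. = FALSE)
    imageSupport(acc, mask@grid)
}

#' Enforce the support assumption on an input field
#'
#' The incomplete-spectrum method assumes the field it inverts is zero outside
#' the image support (S_chi chi = chi, guaranteed in practice by mask-based
#' background-field removal). This helper masks the field with the same mask
#' used by the reconstruction and records, as attribute
#' \code{outsideEnergyFraction}, the fraction of squared field energy that lay
#' outside the mask before masking.
#'
#' @param field a \linkS4class{LocalFieldMap}.
#' @param mask an \linkS4class{ImageSupport} on the same grid.
#' @return The masked \linkS4class{LocalFieldMap} with attribute
#'   \code{outsideEnergyFraction}.
#' @export
applySupport <- function(field, mask) {
    stopifnot(is(field, "LocalFieldMap"), is(mask, "ImageSupport"))
    stopIfGridMismatch(field, mask)
    total <- sum(field@values^2)
    outside <- if (total > 0) sum((field@values * (1 - mask@values))^2) / total else 0
    out <- localFieldMap(field@values * mask@values, field@grid)
    attr(out, "outsideEnergyFraction") <- outside
    out
}
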