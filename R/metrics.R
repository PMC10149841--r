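## Separable windowed local mean with zero-padded boundaries (filter weights
## normalised to sum 1).
gaussWindow <- function(size, sigma) {
    half <- (size - 1) / 2
    w <- exp(-((-half:half)^2) / (2 * sigma^2))
    w / sum(w)
}

convAxis <- function(a, w, axis) {
    half <- (length(w) - 1) / 2
    out <- array(0, dim = dim(a))
    for (j in seq_along(w)) {
        off <- c(0, 0, 0)
        off[axis] <- j - 1 - half
        out <- out + w[j] * shiftArray(a, off)
    }
    out
}

## Windows overhanging the volume edge are renormalised by the in-volume
## weight mass, so constant inputs have exactly constant local means.
localMeanFactory <- function(shape, w) {
    wsum <- array(1, dim = shape)
    for (ax in 1:3) wsum <- convAxis(wsum, w, ax)
    function(a) {
        for (ax in 1:3) a <- convAxis(a, w, ax)
        a / wsum
    }
}

#' Susceptibility-tuned structural similarity (XSIM)
#'
#' SSIM-family index with stabilisation constants tuned for susceptibility
#' maps: the local index
#' (2 mu_x mu_y + C1)(2 sigma_xy + C2) /
#' ((mu_x^2 + mu_y^2 + C1)(sigma_x^2 + sigma_y^2 + C2))
#' with C_i = (K_i L)^2, K1 = 0.01, K2 = 0.001, averaged over the ROI voxels.
#' Local moments come from a 3D Gaussian sliding window (7^3, sigma 1.5 by
#' default). L is the dynamic range: by default the combined max - min of the
#' two maps within the ROI (which keeps the index symmetric in its arguments);
#' set \code{dynamicRange} in the config to fix it.
#'
#' @param x,y \linkS4class{SusceptibilityMap}s on the same grid.
#' @param roi an \linkS4class{ImageSupport}; the index is averaged over its
#'   voxels. Must be nonempty.
#' @param cfg an \linkS4class{XsimConfig}.
#' @return A single value in (-1, 1]; 1 iff the maps agree.
#' @examples
#' g <- volumeGrid(c(12, 12, 12))
#' x <- susceptibilityMap(array(rnorm(12^3), c(12, 12, 12)), g)
#' roi <- imageSupport(array(1, c(12, 12, 12)), g)
#' xsim(x, x, roi)   # exactly 1
#' @export
xsim <- function(x, y, roi, cfg = xsimConfig()) {
    stopifnot(is(x, "SusceptibilityMap"), is(y, "SusceptibilityMap"),
              is(roi, "ImageSupport"), is(cfg, "XsimConfig"))
    stopIfGridMismatch(x, y)
    stopIfGridMismatch(x, roi)
    inROI <- roi@values == 1
    if (!any(inROI)) stop("ROI is empty", call. = FALSE)
    xv <- x@values
    yv <- y@values
    L <- if (is.finite(cfg@dynamicRange)) cfg@dynamicRange
         else diff(range(c(xv[inROI], yv[inROI])))
    C1 <- (cfg@k1 * L)^2
    C2 <- (cfg@k2 * L)^2
    w <- gaussWindow(cfg@windowSize, cfg@windowSigma)
    localMean <- localMeanFactory(dim(xv), w)
    mx <- localMean(xv)
    my <- localMean(yv)
    sxx <- localMean(xv * xv) - mx^2
    syy <- localMean(yv * yv) - my^2
    sxy <- localMean(xv * yv) - mx * my
    num <- (2 * mx * my + C1) * (2 * sxy + C2)
    den <- (mx^2 + my^2 + C1) * (sxx + syy + C2)
    mean((num / den)[inROI])
}

#' Peak signal-to-noise ratio (dB)
#'
#' 10 log10(peak^2 / MSE) with the MSE over the ROI voxels and
#' peak = max - min of the reference within the ROI. Identical inputs return
#' +Inf.
#'
#' @param x the map under evaluation.
#' @param ref the reference \linkS4class{SusceptibilityMap}.
#' @param roi nonempty \linkS4class{ImageSupport}.
#' @return PSNR in dB (+Inf when x equals ref on the ROI).
#' @export
psnr <- function(x, ref, roi) {
    stopifnot(is(x, "SusceptibilityMap"), is(ref, "SusceptibilityMap"),
              is(roi, "ImageSupport"))
    stopIfGridMismatch(x, ref)
    stopIfGridMismatch(x, roi)
    inROI <- roi@values == 1
    if (!any(inROI)) stop("ROI is empty", call. = FALSE)
    refROI <- ref@values[inROI]
    peak <- max(refROI) - min(refROI)
    if (peak == 0)
        stop("reference is constant within the ROI (peak = 0)", call. = FALSE)
    mse <- mean((x@values[inROI] - refROI)^2)
    if (mse == 0) return(Inf)
    10 * log10(peak^2 / mse)
}

#' Region-of-interest statistics
#'
#' Per-label mean, standard error of the mean (sample SD / sqrt(n)) and voxel
#' count of a susceptibility map over an integer label volume (0 = background;
#' absent labels are simply omitted).
#'
#' @param chi a \linkS4class{SusceptibilityMap}.
#' @param labels 3D integer array of the same shape, or a
#'   \linkS4class{PhantomData} (whose labels and names are used).
#' @param labelNames optional named integer vector mapping ROI names to codes.
#' @return data.frame with columns label, name, mean, se, n.
#' @export
roiStats <- function(chi, labels, labelNames = NULL) {
    stopifnot(is(chi, "SusceptibilityMap"))
    if (is(labels, "PhantomData")) {
        labelNames <- labels@labelNames
        labels <- labels@labels
    }
    if (!all(dim(labels) == dim(chi@values)))
        stop("labels shape does not match the map", call. = FALSE)
    codes <- sort(unique(as.integer(labels[labels > 0])))
    rows <- lapply(codes, function(code) {
        v <- chi@values[labels == code]
        nm <- if (!is.null(labelNames) && code %in% labelNames)
            names(labelNames)[match(code, labelNames)] else as.character(code)
        data.frame(label = code, name = nm, mean = mean(v),
                   se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0,
                   n = length(v), stringsAsFactors = FALSE)
    })
    if (!length(rows))
        return(data.frame(label = integer(0), name = character(0),
                          mean = numeric(0), se = numeric(0), n = integer(0)))
    do.call(rbind, rows)
}
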