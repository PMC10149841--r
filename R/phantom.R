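## Geometry of the synthetic head: every structure is an ellipsoid placed at a
## fixed fraction of the grid (bilateral nuclei mirrored in the first axis),
## so the phantom scales with grid size. Fractions are relative to the volume
## centre; semi-axes are fractions of the grid extent.
phantomGeometry <- function() {
    list(
        head = list(centre = c(0, 0, 0), semi = c(0.42, 0.45, 0.40)),
        tissue = list(
            white_matter = list(centre = c(0, 0, 0.02), semi = c(0.30, 0.34, 0.28)),
            ventricle_l  = list(centre = c(0.06, 0.03, 0.06), semi = c(0.035, 0.10, 0.05)),
            ventricle_r  = list(centre = c(-0.06, 0.03, 0.06), semi = c(0.035, 0.10, 0.05))),
        rois = list(
            caudate          = list(centre = c(0.11, 0.06, 0.10), semi = c(0.045, 0.090, 0.060)),
            putamen          = list(centre = c(0.20, 0.02, 0.02), semi = c(0.055, 0.085, 0.055)),
            globus_pallidus  = list(centre = c(0.13, 0.00, 0.00), semi = c(0.040, 0.055, 0.040)),
            thalamus         = list(centre = c(0.08, -0.08, 0.02), semi = c(0.055, 0.075, 0.055)),
            red_nucleus      = list(centre = c(0.045, -0.12, -0.06), semi = c(0.025, 0.030, 0.025)),
            substantia_nigra = list(centre = c(0.085, -0.16, -0.10), semi = c(0.030, 0.045, 0.025))),
        calcification = list(centre = c(0.10, 0.12, 0.22), semi = c(0.035, 0.035, 0.035)))
}

#' Default phantom susceptibility values (ppm)
#'
#' Plausible order-of-magnitude settings for the deep grey-matter nuclei
#' (globus pallidus highest, thalamus lowest) and a strongly diamagnetic focal
#' calcification. These are generator defaults, not literature measurements.
#'
#' Susceptibility contrasts are relative to peripheral grey matter at
#' +0.02 ppm, with diamagnetic white matter and near-zero CSF, so the truth is
#' piecewise constant but has tissue structure throughout the head (as real
#' brains do), not a flat background.
#'
#' @return Named numeric vector of chi values in ppm.
#' @export
phantomDefaultValues <- function() c(
    globus_pallidus = 0.15, substantia_nigra = 0.12, red_nucleus = 0.10,
    putamen = 0.09, caudate = 0.06, thalamus = 0.02, calcification = -1.0,
    grey_matter = 0.02, white_matter = -0.03, csf = -0.01)

ellipsoidMask <- function(shape, centreFrac, semiFrac) {
    ctr <- (shape + 1) / 2 + centreFrac * shape
    ax <- pmax(semiFrac * shape, 0.5)
    X <- array(seq_len(shape[1]), dim = shape)
    Y <- array(rep(seq_len(shape[2]), each = shape[1]), dim = shape)
    Z <- array(rep(seq_len(shape[3]), each = shape[1] * shape[2]), dim = shape)
    ((X - ctr[1]) / ax[1])^2 + ((Y - ctr[2]) / ax[2])^2 +
        ((Z - ctr[3]) / ax[3])^2 <= 1
}

#' Synthetic brain-like susceptibility phantom
#'
#' Builds a piecewise-constant ground-truth susceptibility distribution with
#' an ellipsoidal head mask, the six bilateral deep grey-matter nuclei used in
#' QSM ROI analyses (globus pallidus, caudate, putamen, red nucleus, thalamus,
#' substantia nigra), surrounding tissue compartments (peripheral grey
#' matter, diamagnetic deep white matter, CSF ventricles — so the truth has
#' piecewise-constant structure throughout the head rather than a flat
#' background) and one small spherical calcification (a strong
#' diamagnetic source whose streaking artifacts stress dipole inversion). All
#' structures lie inside the mask, so the support assumption S_chi chi = chi
#' holds exactly. Output is deterministic given the seed (the seed feeds the
#' field-noise simulation in \code{\link{simulateField}}).
#'
#' Label codes: 1 caudate, 2 putamen, 3 globus pallidus, 4 thalamus,
#' 5 red nucleus, 6 substantia nigra (each bilateral), 7 calcification.
#'
#' @param shape grid shape (one integer for a cube, or three); default 64.
#' @param voxelSize voxel size in mm (default isotropic 1 mm).
#' @param seed integer seed stored with the phantom.
#' @param roiValues named chi values in ppm (see
#'   \code{\link{phantomDefaultValues}}); names must cover the six nuclei and
#'   the calcification.
#' @param backgroundValue chi of masked tissue outside the ROIs (ppm).
#' @return A \linkS4class{PhantomData} without a field (see
#'   \code{\link{simulateField}}).
#' @examples
#' ph <- makePhantom(shape = 32, seed = 7)
#' @export
makePhantom <- function(shape = 64, voxelSize = c(1, 1, 1), seed = 42L,
                        roiValues = phantomDefaultValues(),
                        backgroundValue = 0) {
    if (length(shape) == 1L) shape <- rep(shape, 3)
    shape <- as.integer(shape)
    grid <- volumeGrid(shape, voxelSize)
    geo <- phantomGeometry()
    need <- c(names(geo$rois), "calcification")
    if (!all(need %in% names(roiValues)))
        stop("roiValues must name: ", paste(need, collapse = ", "), call. = FALSE)
    headMask <- ellipsoidMask(shape, geo$head$centre, geo$head$semi)
    chi <- array(0, dim = shape)
    ## tissue compartments: peripheral grey matter, deep white matter, CSF
    chi[headMask] <- if ("grey_matter" %in% names(roiValues))
        roiValues[["grey_matter"]] else backgroundValue
    if ("white_matter" %in% names(roiValues))
        chi[ellipsoidMask(shape, geo$tissue$white_matter$centre,
                          geo$tissue$white_matter$semi)] <- roiValues[["white_matter"]]
    if ("csf" %in% names(roiValues)) for (v in c("ventricle_l", "ventricle_r"))
        chi[ellipsoidMask(shape, geo$tissue[[v]]$centre,
                          geo$tissue[[v]]$semi)] <- roiValues[["csf"]]
    labels <- array(0L, dim = shape)
    labelNames <- integer(0)
    code <- 0L
    for (nm in names(geo$rois)) {
        code <- code + 1L
        labelNames[nm] <- code
        for (side in c(1, -1)) {
            ctr <- geo$rois[[nm]]$centre * c(side, 1, 1)
            e <- ellipsoidMask(shape, ctr, geo$rois[[nm]]$semi)
            if (!all(headMask[e]))
                stop("structure '", nm, "' exceeds the head mask on this grid",
                     call. = FALSE)
            chi[e] <- roiValues[[nm]]
            labels[e] <- code
        }
    }
    code <- code + 1L
    labelNames["calcification"] <- code
    calc <- ellipsoidMask(shape, geo$calcification$centre, geo$calcification$semi)
    if (!all(headMask[calc]))
        stop("calcification exceeds the head mask on this grid", call. = FALSE)
    chi[calc] <- roiValues[["calcification"]]
    labels[calc] <- code
    new("PhantomData",
        chiTruth = susceptibilityMap(chi, grid),
        mask = imageSupport(array(as.numeric(headMask), dim = shape), grid),
        labels = labels, labelNames = labelNames, field = NULL,
        noiseSigma = 0, seed = as.integer(seed))
}

#' Forward-simulate the phantom's noisy local field
#'
#' Computes the noiseless field with the dipole forward model and adds
#' zero-mean Gaussian noise with standard deviation
#' sigma = rms(noiseless field within mask) / snr, then masks the field with
#' the phantom mask (consistent with the reconstruction's input-masking rule).
#' The global RNG state is saved and restored.
#'
#' @param phantom a \linkS4class{PhantomData}.
#' @param kernel optional precomputed \linkS4class{DipoleKernelSpectrum}.
#' @param snr positive signal-to-noise ratio, or Inf for a noiseless field.
#' @param seed seed for the noise draw (default: the phantom's seed).
#' @return The \linkS4class{PhantomData} with the \code{field} slot filled and
#'   \code{noiseSigma} recorded (ppm).
#' @export
simulateField <- function(phantom, kernel = NULL, snr = 100, seed = phantom@seed) {
    stopifnot(is(phantom, "PhantomData"), snr > 0)
    if (is.null(kernel)) kernel <- dipoleKernel(phantom@chiTruth@grid)
    clean <- forwardField(phantom@chiTruth, kernel)
    m <- phantom@mask@values
    vals <- clean@values
    sigma <- 0
    if (is.finite(snr)) {
        sigma <- sqrt(mean(vals[m == 1]^2)) / snr
        haveSeed <- exists(".Random.seed", envir = globalenv())
        if (haveSeed) old <- get(".Random.seed", envir = globalenv())
        set.seed(seed)
        vals <- vals + array(stats::rnorm(length(vals), sd = sigma), dim = dim(vals))
        if (haveSeed) assign(".Random.seed", old, envir = globalenv())
        else rm(".Random.seed", envir = globalenv())
    }
    phantom@field <- localFieldMap(vals * m, phantom@chiTruth@grid)
    phantom@noiseSigma <- sigma
    phantom
}
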