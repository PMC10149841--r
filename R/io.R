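#' Read a NIfTI volume as a typed object
#'
#' Reads a 3D NIfTI volume (4D with a singleton trailing dimension is
#' accepted) and wraps it in the requested type. Voxel size is taken from the
#' header; the B0 direction is not carried by NIfTI headers reliably and is
#' supplied by the caller. Masks are binarised with the convention
#' value > 0.5 is inside; label volumes are rounded to integers.
#'
#' @param path path to a .nii or .nii.gz file.
#' @param type one of "field", "chi", "mask", "labels".
#' @param b0Dir B0 direction for the grid (default third axis).
#' @return A \linkS4class{LocalFieldMap}, \linkS4class{SusceptibilityMap},
#'   \linkS4class{ImageSupport}, or (for labels) a list with \code{labels}
#'   (integer array) and \code{grid}.
#' @export
readVolume <- function(path, type = c("field", "chi", "mask", "labels"),
                       b0Dir = c(0, 0, 1)) {
    type <- match.arg(type)
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    arr <- array(as.numeric(arr), dim = dim(arr))
    d <- dim(arr)
    if (length(d) == 4L && d[4] == 1L) { arr <- arr[, , , 1]; d <- dim(arr) }
    if (length(d) != 3L)
        stop("expected 3D data (or 4D with singleton trailing dim), got ",
             length(dim(as.array(img))), "D: ", path, call. = FALSE)
    vox <- RNifti::pixdim(img)[1:3]
    if (any(!is.finite(vox)) || any(vox <= 0)) vox <- c(1, 1, 1)
    grid <- volumeGrid(d, vox, b0Dir)
    switch(type,
        field = localFieldMap(arr, grid),
        chi = susceptibilityMap(arr, grid),
        mask = imageSupport(arr, grid),
        labels = list(labels = array(as.integer(round(arr)), dim = d), grid = grid))
}

#' Write a volume to NIfTI
#'
#' @param volume a \linkS4class{Volume3D} (map, field or mask) or a plain 3D
#'   array.
#' @param path output path (.nii or .nii.gz).
#' @param grid the \linkS4class{VolumeGrid} supplying the voxel size when
#'   \code{volume} is a plain array.
#' @return The path, invisibly.
#' @export
writeVolume <- function(volume, path, grid = NULL) {
    if (is(volume, "Volume3D")) {
        grid <- volume@grid
        arr <- volume@values
    } else arr <- volume
    img <- RNifti::asNifti(arr)
    if (!is.null(grid)) RNifti::pixdim(img) <- grid@voxelSize
    RNifti::writeNifti(img, path)
    invisible(path)
}

resolveConfig <- function(config) {
    defaults <- list(method = "is", tWell = 0.25, tol = 1e-6, maxIter = 100L,
                     lambdaL1 = 1e-5, wavelet = "db2", waveletLevels = 3L,
                     delta = 2 / 3, psfCorrect = TRUE, b0Dir = c(0, 0, 1),
                     seed = 42L, thresholds = NULL, methods = NULL,
                     outputDir = NULL)
    unknown <- setdiff(names(config), c(names(defaults), "field", "mask",
                                        "truth", "labels", "mode"))
    if (length(unknown))
        stop("unknown config entries: ", paste(unknown, collapse = ", "),
             call. = FALSE)
    utils::modifyList(defaults, config)
}

reconByMethod <- function(method, field, mask, kernel, cfg) {
    sc <- solverConfig(tWell = cfg$tWell, tol = cfg$tol, maxIter = cfg$maxIter,
                       lambdaL1 = if (method == "isreg") cfg$lambdaL1 else 0,
                       waveletName = cfg$wavelet, waveletLevels = cfg$waveletLevels)
    switch(method,
        is = isReconstruct(field, mask, kernel, sc),
        isreg = isReconstructRegularized(field, mask, kernel, sc),
        tkd = {
            chi <- tkdReconstruct(applySupport(field, mask), kernel,
                                  tkdConfig(cfg$delta, cfg$psfCorrect))
            new("ReconResult", chi = chi, residualHistory = numeric(0),
                objectiveHistory = numeric(0), iterations = 0L,
                converged = TRUE,
                config = list(method = "tkd", delta = cfg$delta,
                              psfCorrect = cfg$psfCorrect))
        },
        cs = csReconstruct(applySupport(field, mask), kernel,
                           bandLimit(kernel, cfg$tWell), cfg$lambdaL1,
                           cfg$wavelet, cfg$waveletLevels, cfg$tol, cfg$maxIter),
        stop("unknown method '", method, "'", call. = FALSE))
}

#' Run a reconstruction experiment from a configuration
#'
#' Drives reconstructions, threshold sweeps and method comparisons from a
#' single configuration list; a reproducible-run entry point used by the
#' command-line script. Inputs may be in-memory objects or NIfTI paths. When
#' \code{outputDir} is given, reconstructions are written as NIfTI, sweep and
#' comparison tables as CSV, and a JSON sidecar records the full effective
#' configuration (defaults resolved), so runs are replayable from the sidecar
#' alone.
#'
#' @param config list with entries: \code{mode} ("recon", "sweep-twell",
#'   "sweep-mask" or "compare"); \code{field} and \code{mask}
#'   (objects or NIfTI paths); optional \code{truth} and \code{labels};
#'   \code{method} (is, isreg, tkd, cs) or \code{methods} for compare;
#'   \code{thresholds} for sweep-twell (erosion/dilation steps -n..n for
#'   sweep-mask come from \code{thresholds} too, as signed voxel counts);
#'   solver settings as in \code{\link{solverConfig}} and
#'   \code{\link{tkdConfig}}; \code{b0Dir}; \code{seed}; \code{outputDir}.
#' @return For "recon": a list with the \linkS4class{ReconResult} and (when
#'   truth is given) metrics. For sweeps: the table. For "compare": one
#'   metrics entry per method.
#' @export
runExperiment <- function(config) {
    mode <- if (is.null(config$mode)) "recon" else config$mode
    cfg <- resolveConfig(config)
    loadAs <- function(x, type) if (is.character(x)) readVolume(x, type, cfg$b0Dir) else x
    field <- loadAs(cfg$field, "field")
    mask <- loadAs(cfg$mask, "mask")
    truth <- if (!is.null(cfg$truth)) loadAs(cfg$truth, "chi")
    stopIfGridMismatch(field, mask)
    kernel <- dipoleKernel(field@grid)
    outDir <- cfg$outputDir
    if (!is.null(outDir) && !dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)
    sidecar <- function(extra) {
        if (is.null(outDir)) return(invisible(NULL))
        eff <- cfg[!vapply(cfg, is.null, logical(1))]
        eff$field <- if (is.character(config$field)) config$field else "<in-memory>"
        eff$mask <- if (is.character(config$mask)) config$mask else "<in-memory>"
        eff$truth <- if (is.character(config$truth)) config$truth
                     else if (!is.null(truth)) "<in-memory>"
        jsonlite::write_json(c(eff, extra), file.path(outDir, "run.json"),
                             auto_unbox = TRUE, digits = NA, null = "null")
    }
    metricsFor <- function(rec) {
        if (is.null(truth)) return(NULL)
        list(xsim = xsim(reconChi(rec), truth, mask),
             psnr = psnr(reconChi(rec), truth, mask))
    }
    if (mode == "recon") {
        rec <- reconByMethod(cfg$method, field, mask, kernel, cfg)
        met <- metricsFor(rec)
        if (!is.null(outDir)) {
            writeVolume(reconChi(rec), file.path(outDir, "chi.nii.gz"))
            sidecar(list(metrics = met, iterations = iterations(rec),
                         converged = converged(rec),
                         residualHistory = residualHistory(rec)))
        }
        return(list(result = rec, metrics = met))
    }
    if (mode == "sweep-twell") {
        if (is.null(truth)) stop("sweep requires a ground truth", call. = FALSE)
        tab <- thresholdSweep(field, mask, kernel, truth, cfg$thresholds,
                              solverConfig(tWell = cfg$tWell, tol = cfg$tol,
                                           maxIter = cfg$maxIter))
        if (!is.null(outDir)) {
            utils::write.csv(tab, file.path(outDir, "sweep_twell.csv"),
                             row.names = FALSE)
            sidecar(list(optXsim = as.list(attr(tab, "optXsim")),
                         optPsnr = as.list(attr(tab, "optPsnr"))))
        }
        return(tab)
    }
    if (mode == "sweep-mask") {
        if (is.null(truth)) stop("sweep requires a ground truth", call. = FALSE)
        steps <- cfg$thresholds
        rows <- lapply(steps, function(s) {
            m <- if (s == 0) mask
                 else morphMask(mask, abs(s), if (s < 0) "erode" else "dilate")
            rec <- isReconstruct(field, m, kernel,
                                 solverConfig(tWell = cfg$tWell, tol = cfg$tol,
                                              maxIter = cfg$maxIter))
            data.frame(step = s, xsim = xsim(reconChi(rec), truth, mask),
                       psnr = psnr(reconChi(rec), truth, mask),
                       converged = converged(rec))
        })
        tab <- do.call(rbind, rows)
        if (!is.null(outDir)) {
            utils::write.csv(tab, file.path(outDir, "sweep_mask.csv"),
                             row.names = FALSE)
            sidecar(NULL)
        }
        return(tab)
    }
    if (mode == "compare") {
        methods <- if (is.null(cfg$methods)) c("is", "tkd", "cs") else cfg$methods
        out <- lapply(methods, function(m) {
            rec <- reconByMethod(m, field, mask, kernel, cfg)
            c(list(method = m), metricsFor(rec))
        })
        names(out) <- methods
        if (!is.null(outDir)) {
            tab <- do.call(rbind, lapply(out, function(o)
                data.frame(method = o$method,
                           xsim = if (is.null(o$xsim)) NA else o$xsim,
                           psnr = if (is.null(o$psnr)) NA else o$psnr)))
            utils::write.csv(tab, file.path(outDir, "compare.csv"),
                             row.names = FALSE)
            sidecar(NULL)
        }
        return(out)
    }
    stop("unknown mode '", mode, "'", call. = FALSE)
}
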