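#' Extract the voxel values of a volume
#' @param x a volume object.
#' @return The underlying 3D array.
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @describeIn values values of a real volume.
#' @export
setMethod("values", "Volume3D", function(x) x@values)

#' @describeIn values values of a complex k-space input.
#' @export
setMethod("values", "KSpaceInput", function(x) x@values)

#' Extract the sampling grid of a volume
#' @param x a volume object.
#' @return The \linkS4class{VolumeGrid}.
#' @export
setGeneric("voxelGrid", function(x) standardGeneric("voxelGrid"))

#' @describeIn voxelGrid grid of a real volume.
#' @export
setMethod("voxelGrid", "Volume3D", function(x) x@grid)

#' @describeIn voxelGrid grid of a complex k-space input.
#' @export
setMethod("voxelGrid", "KSpaceInput", function(x) x@grid)

#' @describeIn voxelGrid grid of a reconstruction result.
#' @export
setMethod("voxelGrid", "ReconResult", function(x) x@chi@grid)

#' Grid accessors
#'
#' @param x a \linkS4class{VolumeGrid}.
#' @return \code{gridShape}: integer matrix size; \code{voxelSize}: voxel edge
#'   lengths in mm; \code{b0Dir}: the unit B0 direction vector.
#' @name grid-accessors
NULL

#' @rdname grid-accessors
#' @export
gridShape <- function(x) x@shape

#' @rdname grid-accessors
#' @export
voxelSize <- function(x) x@voxelSize

#' @rdname grid-accessors
#' @export
b0Dir <- function(x) x@b0Dir

#' Accessors for reconstruction results
#'
#' @param x a \linkS4class{ReconResult}.
#' @return \code{reconChi}: the reconstructed \linkS4class{SusceptibilityMap};
#'   \code{residualHistory}: per-iteration residual norms;
#'   \code{objectiveHistory}: per-iteration objective values (regularized
#'   solvers); \code{iterations}: iteration count; \code{converged}: logical.
#' @name recon-accessors
NULL

#' @rdname recon-accessors
#' @export
reconChi <- function(x) x@chi

#' @rdname recon-accessors
#' @export
residualHistory <- function(x) x@residualHistory

#' @rdname recon-accessors
#' @export
objectiveHistory <- function(x) x@objectiveHistory

#' @rdname recon-accessors
#' @export
iterations <- function(x) x@iterations

#' @rdname recon-accessors
#' @export
converged <- function(x) x@converged

#' @export
setMethod("dim", "Volume3D", function(x) dim(x@values))

#' @export
setMethod("show", "VolumeGrid", function(object) {
    cat("VolumeGrid:", paste(object@shape, collapse = " x "),
        "voxels,", paste(signif(object@voxelSize, 4), collapse = " x "),
        "mm, B0 dir (", paste(signif(object@b0Dir, 4), collapse = ", "), ")\n")
})

showVolume <- function(object, what, unit) {
    v <- object@values
    cat(what, ": ", paste(dim(v), collapse = " x "), " voxels",
        if (nzchar(unit)) paste0(" [", unit, "]"), "\n", sep = "")
    cat("  range: [", signif(min(v), 4), ", ", signif(max(v), 4), "]\n", sep = "")
    show(object@grid)
}

#' @export
setMethod("show", "SusceptibilityMap", function(object)
    showVolume(object, "SusceptibilityMap", "ppm"))

#' @export
setMethod("show", "LocalFieldMap", function(object)
    showVolume(object, "LocalFieldMap", "ppm"))

#' @export
setMethod("show", "ImageSupport", function(object) {
    cat("ImageSupport:", paste(dim(object@values), collapse = " x "),
        "voxels,", sum(object@values), "inside\n")
    show(object@grid)
})

#' @export
setMethod("show", "KSpaceSupport", function(object) {
    cat("KSpaceSupport (tWell = ", signif(object@tWell, 4), "): ",
        sum(object@values), " of ", length(object@values),
        " frequencies retained (", signif(100 * mean(object@values), 3),
        "%)\n", sep = "")
})

#' @export
setMethod("show", "DipoleKernelSpectrum", function(object)
    showVolume(object, "DipoleKernelSpectrum", ""))

#' @export
setMethod("show", "ReconResult", function(object) {
    cat("ReconResult:", object@iterations, "iterations,",
        if (object@converged) "converged" else "not converged", "\n")
    if (length(object@residualHistory))
        cat("  final residual:",
            signif(object@residualHistory[length(object@residualHistory)], 4), "\n")
    show(object@chi)
})

#' @export
setMethod("show", "PhantomData", function(object) {
    cat("PhantomData: seed", object@seed, "\n")
    cat("  ROIs:", paste(names(object@labelNames), collapse = ", "), "\n")
    cat("  field:", if (is.null(object@field)) "not simulated" else
        paste0("simulated (noise sigma ", signif(object@noiseSigma, 3), " ppm)"), "\n")
    show(object@chiTruth@grid)
})
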