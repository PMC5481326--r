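## Accessor and show() methods.

#' @rdname accessors
#' @export
setMethod("epochs", "StimulusSchedule", function(object) object@epochs)

#' @rdname accessors
#' @export
setMethod("totalDuration", "StimulusSchedule",
          function(object) object@totalDuration)

#' @rdname accessors
#' @export
setMethod("depths", "TrajectorySet", function(object) object@depth)

#' @rdname accessors
#' @export
setMethod("rateHz", "TrajectorySet", function(object) object@rateHz)

#' @rdname accessors
#' @export
setMethod("nFish", "TrajectorySet", function(object) nrow(object@depth))

#' @rdname accessors
#' @export
setMethod("calibration", "TrajectorySet", function(object) object@calibration)

#' @rdname accessors
#' @export
setMethod("sourceIds", "TrajectorySet", function(object) object@sourceIds)

#' @rdname accessors
#' @export
setMethod("interpFlags", "TrajectorySet", function(object) object@flags)

#' @rdname accessors
#' @export
setMethod("corMatrix", "CorrelationMatrix", function(object) object@R)

#' @rdname accessors
#' @export
setMethod("nSamples", "CorrelationMatrix", function(object) object@nSamples)

#' @rdname accessors
#' @export
setMethod("spatialMaps", "ICADecomposition",
          function(object) object@spatialMaps)

#' @rdname accessors
#' @export
setMethod("temporalSignals", "ICADecomposition",
          function(object) object@temporalSignals)

#' @rdname accessors
#' @export
setMethod("varianceExplained", "PCAReduction",
          function(object) object@varianceExplained)

#' @rdname accessors
#' @export
setMethod("varianceExplained", "ICADecomposition",
          function(object) object@varianceExplained)

#' @rdname accessors
#' @export
setMethod("movieDim", "PCAReduction", function(object) object@movieDim)

#' @rdname accessors
#' @export
setMethod("movieDim", "ICADecomposition", function(object) object@movieDim)

#' @rdname accessors
#' @export
setMethod("labelImage", "ROISet", function(object) object@labelImage)

#' @rdname accessors
#' @export
setMethod("roiPixels", "ROISet", function(object) object@pixels)

#' @rdname accessors
#' @export
setMethod("provenance", "ROISet", function(object) object@provenance)

#' @rdname accessors
#' @export
setMethod("templates", "ResponseTemplateBank",
          function(object) object@templates)

#' @rdname accessors
#' @export
setMethod("categoryAverages", "ClassifiedMaps",
          function(object) object@averages)

#' @rdname accessors
#' @export
setMethod("memberMaps", "ClassifiedMaps", function(object) object@members)

#' Number of ROIs in a set
#' @param x a \linkS4class{ROISet}.
#' @return Integer ROI count.
#' @export
setMethod("length", "ROISet", function(x) length(x@pixels))

#' Reshape one ICA spatial map to image form
#'
#' @param decomp an \linkS4class{ICADecomposition}.
#' @param i component index.
#' @return Y x X numeric matrix of component weights.
#' @examples
#' # see ?spatialICA for a full decomposition example
#' @export
componentImage <- function(decomp, i) {
    stopifnot(is(decomp, "ICADecomposition"),
              i >= 1L, i <= nrow(decomp@spatialMaps))
    matrix(decomp@spatialMaps[i, ], decomp@movieDim[1L], decomp@movieDim[2L])
}

setMethod("show", "StimulusSchedule", function(object) {
    e <- object@epochs
    cat(sprintf("StimulusSchedule: %d epochs, %.0f s total\n",
                nrow(e), object@totalDuration))
    tab <- table(e$channel)
    cat("  channels:",
        paste(sprintf("%s x%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
})

setMethod("show", "TrajectorySet", function(object) {
    cat(sprintf(
        "TrajectorySet: %d fish x %d samples at %.1f Hz (%.0f s)\n",
        nrow(object@depth), ncol(object@depth), object@rateHz,
        ncol(object@depth) / object@rateHz))
    if (any(object@flags))
        cat(sprintf("  %d interpolated samples\n", sum(object@flags)))
})

setMethod("show", "CorrelationMatrix", function(object) {
    cat(sprintf("CorrelationMatrix: %d x %d (n = %d samples)%s\n",
                nrow(object@R), ncol(object@R), object@nSamples,
                if (length(object@group) && nzchar(object@group[1L]))
                    paste0(", group '", object@group[1L], "'") else ""))
})

setMethod("show", "ICADecomposition", function(object) {
    cat(sprintf(
        "ICADecomposition: %d components from %d PCs (mu = %.2f)%s\n",
        nrow(object@spatialMaps), object@retainedPCs, object@mu,
        if (object@converged) "" else " [not converged]"))
})

setMethod("show", "ROISet", function(object) {
    cat(sprintf("ROISet: %d ROIs over a %d x %d field\n",
                length(object@pixels), nrow(object@labelImage),
                ncol(object@labelImage)))
})

setMethod("show", "ResponseTemplateBank", function(object) {
    avail <- vapply(object@templates, length, integer(1L)) > 0L
    cat(sprintf("ResponseTemplateBank: %.2f Hz, tau = %.1f s\n",
                object@rateHz, object@tau))
    cat("  available:", paste(names(object@templates)[avail], collapse = ", "),
        "\n")
})

setMethod("show", "ClassifiedMaps", function(object) {
    cat(sprintf("ClassifiedMaps: %d categories, reference fish '%s'\n",
                length(object@averages), object@reference))
    for (k in names(object@averages))
        cat(sprintf("  %s: %d maps\n", k,
                    sum(object@members$category == k)))
})
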