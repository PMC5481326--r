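#' @name accessors
#' @title Accessors for lightmask containers
#' @description Slot accessors for the S4 containers: epoch tables, depth
#'   matrices, sampling rates, spatial maps and temporal signals, ROI labels,
#'   templates and averaged category maps.
#' @param object an S4 object from this package.
#' @return The corresponding slot value; see the class documentation.
NULL

#' @rdname accessors
#' @export
setGeneric("epochs", function(object) standardGeneric("epochs"))

#' @rdname accessors
#' @export
setGeneric("totalDuration", function(object) standardGeneric("totalDuration"))

#' @rdname accessors
#' @export
setGeneric("depths", function(object) standardGeneric("depths"))

#' @rdname accessors
#' @export
setGeneric("rateHz", function(object) standardGeneric("rateHz"))

#' @rdname accessors
#' @export
setGeneric("nFish", function(object) standardGeneric("nFish"))

#' @rdname accessors
#' @export
setGeneric("calibration", function(object) standardGeneric("calibration"))

#' @rdname accessors
#' @export
setGeneric("sourceIds", function(object) standardGeneric("sourceIds"))

#' @rdname accessors
#' @export
setGeneric("interpFlags", function(object) standardGeneric("interpFlags"))

#' @rdname accessors
#' @export
setGeneric("corMatrix", function(object) standardGeneric("corMatrix"))

#' @rdname accessors
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' @rdname accessors
#' @export
setGeneric("spatialMaps", function(object) standardGeneric("spatialMaps"))

#' @rdname accessors
#' @export
setGeneric("temporalSignals",
           function(object) standardGeneric("temporalSignals"))

#' @rdname accessors
#' @export
setGeneric("varianceExplained",
           function(object) standardGeneric("varianceExplained"))

#' @rdname accessors
#' @export
setGeneric("movieDim", function(object) standardGeneric("movieDim"))

#' @rdname accessors
#' @export
setGeneric("labelImage", function(object) standardGeneric("labelImage"))

#' @rdname accessors
#' @export
setGeneric("roiPixels", function(object) standardGeneric("roiPixels"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("templates", function(object) standardGeneric("templates"))

#' @rdname accessors
#' @export
setGeneric("categoryAverages",
           function(object) standardGeneric("categoryAverages"))

#' @rdname accessors
#' @export
setGeneric("memberMaps", function(object) standardGeneric("memberMaps"))
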