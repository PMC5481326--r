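## Central S4 containers shared by the behavior and imaging arms.

## Light channels and their peak emission wavelengths (nm). "dark" is the
## absence of stimulus light and carries no wavelength.
.CHANNEL_WAVELENGTHS <- c(dark = NA_real_, blue470 = 470, green525 = 525,
                          red660 = 660, uv375 = 375)

## Chamber geometry: 3.0 cm x 1.0 cm footprint, 5.0 cm water column.
## Depth convention everywhere: 0 cm at the water surface, increasing downward.
.CHAMBER_HEIGHT_CM <- 5.0
.HALF_DEPTH_CM <- .CHAMBER_HEIGHT_CM / 2

#' Supported light channels
#'
#' Names of the light channels understood by the schedule generator and the
#' simulators, with their peak wavelengths in nanometres (\code{NA} for dark).
#'
#' @return Named numeric vector of wavelengths, one per channel.
#' @examples
#' lightChannels()
#' @export
lightChannels <- function() .CHANNEL_WAVELENGTHS

#' Chamber height
#'
#' Height of the behavioral chamber water column in cm. Depth 0 is the water
#' surface and increases downward; all trajectories live in
#' \code{[0, chamberHeight()]}.
#'
#' @return Numeric scalar (cm).
#' @examples
#' chamberHeight()
#' @export
chamberHeight <- function() .CHAMBER_HEIGHT_CM

#' StimulusSchedule: ordered light epochs
#'
#' An ordered, contiguous tiling of the recording time by light epochs. Each
#' epoch has a start (s), a duration (s), a channel (see
#' \code{\link{lightChannels}}) and an irradiance (uW/cm^2; 0 for dark).
#'
#' @slot epochs data.frame with columns \code{start_s}, \code{duration_s},
#'   \code{channel}, \code{irradiance}.
#' @slot totalDuration total schedule duration in seconds.
#' @slot seed integer seed the schedule was generated from (NA if built by
#'   hand).
#' @seealso \code{\link{makeSchedule}}
#' @exportClass StimulusSchedule
setClass("StimulusSchedule",
         representation(epochs = "data.frame",
                        totalDuration = "numeric",
                        seed = "integer"))

setValidity("StimulusSchedule", function(object) {
    e <- object@epochs
    req <- c("start_s", "duration_s", "channel", "irradiance")
    if (!all(req %in% names(e)))
        return(paste("epochs must have columns", paste(req, collapse = ", ")))
    if (nrow(e) < 1L) return("schedule must contain at least one epoch")
    if (!all(e$channel %in% names(.CHANNEL_WAVELENGTHS)))
        return("unknown channel in schedule")
    if (abs(e$start_s[1L]) > 1e-9) return("first epoch must start at 0")
    if (any(e$duration_s <= 0)) return("epoch durations must be positive")
    if (nrow(e) > 1L) {
        gaps <- e$start_s[-1L] - (e$start_s[-nrow(e)] + e$duration_s[-nrow(e)])
        if (any(abs(gaps) > 1e-9))
            return("epochs must be contiguous and non-overlapping")
    }
    if (abs(sum(e$duration_s) - object@totalDuration) > 1e-9)
        return("totalDuration must equal the sum of epoch durations")
    TRUE
})

#' TrajectorySet: per-fish vertical depth time series
#'
#' Depth traces for one or more fish, sampled at a fixed rate. Depth is in cm,
#' 0 at the surface, bounded by \code{\link{chamberHeight}}.
#'
#' @slot depth numeric matrix, fish x time (cm).
#' @slot rateHz sampling rate (frames per second).
#' @slot calibration list with \code{cm_per_px} and \code{row_offset} when the
#'   trajectories came from video, empty list otherwise.
#' @slot sourceIds character vector of per-fish identifiers.
#' @slot flags logical matrix, same shape as \code{depth}; TRUE marks samples
#'   filled by interpolation (tracking) rather than measured.
#' @seealso \code{\link{simulateTrajectories}}, \code{\link{trackPositions}}
#' @exportClass TrajectorySet
setClass("TrajectorySet",
         representation(depth = "matrix",
                        rateHz = "numeric",
                        calibration = "list",
                        sourceIds = "character",
                        flags = "matrix"))

setValidity("TrajectorySet", function(object) {
    d <- object@depth
    if (!is.numeric(d)) return("depth must be numeric")
    if (length(object@rateHz) != 1L || object@rateHz <= 0)
        return("rateHz must be a positive scalar")
    if (any(!is.finite(d))) return("depth must be finite")
    if (any(d < -1e-6 | d > .CHAMBER_HEIGHT_CM + 1e-6))
        return(sprintf("depth must lie in [0, %.1f] cm", .CHAMBER_HEIGHT_CM))
    if (length(object@sourceIds) != nrow(d))
        return("one sourceId per fish is required")
    if (!identical(dim(object@flags), dim(d)))
        return("flags must have the same shape as depth")
    TRUE
})

#' CorrelationMatrix: inter-individual synchrony
#'
#' Pearson correlation matrix of the depth traces of a group of fish, plus the
#' number of time samples it was computed from.
#'
#' @slot R symmetric p x p correlation matrix, unit diagonal, entries in
#'   [-1, 1] (NA rows/columns mark excluded zero-variance traces).
#' @slot nSamples number of time points used.
#' @slot group character group label.
#' @seealso \code{\link{pairwiseCorrelation}}, \code{\link{jennrichTest}}
#' @exportClass CorrelationMatrix
setClass("CorrelationMatrix",
         representation(R = "matrix",
                        nSamples = "integer",
                        group = "character"))

setValidity("CorrelationMatrix", function(object) {
    R <- object@R
    if (nrow(R) != ncol(R)) return("R must be square")
    ok <- !is.na(R)
    if (any(abs(R[ok]) > 1 + 1e-9)) return("correlations must lie in [-1, 1]")
    if (max(abs(R - t(R)), na.rm = TRUE) > 1e-9) return("R must be symmetric")
    dg <- diag(R)
    if (any(abs(dg[!is.na(dg)] - 1) > 1e-9)) return("diagonal must be 1")
    TRUE
})

#' PlantedSource: ground-truth source for the calcium-movie simulator
#'
#' A spatial footprint together with its temporal response class, response
#' amplitude (dF/F) and indicator kinetics.
#'
#' @slot footprint non-negative Y x X weight image with finite support.
#' @slot responseClass one of \code{blue_onset_sustained}, \code{red_onset},
#'   \code{mixed_onset_transient}, \code{mixed_offset_transient},
#'   \code{blue_offset}.
#' @slot amplitude positive response amplitude (dF/F units).
#' @slot tauRise,tauDecay indicator rise and decay time constants (s).
#' @seealso \code{\link{plantedSource}}, \code{\link{simulateCalciumMovie}}
#' @exportClass PlantedSource
setClass("PlantedSource",
         representation(footprint = "matrix",
                        responseClass = "character",
                        amplitude = "numeric",
                        tauRise = "numeric",
                        tauDecay = "numeric"))

.RESPONSE_CLASSES <- c("blue_onset_sustained", "red_onset",
                       "mixed_onset_transient", "mixed_offset_transient",
                       "blue_offset")

setValidity("PlantedSource", function(object) {
    if (any(object@footprint < 0)) return("footprint weights must be >= 0")
    if (sum(object@footprint) <= 0) return("footprint must have support")
    if (!object@responseClass %in% .RESPONSE_CLASSES)
        return(paste("responseClass must be one of",
                     paste(.RESPONSE_CLASSES, collapse = ", ")))
    if (object@amplitude <= 0) return("amplitude must be positive")
    if (object@tauRise <= 0 || object@tauDecay <= 0)
        return("time constants must be positive")
    TRUE
})

#' PCAReduction: truncated principal-component factorisation of a movie
#'
#' @slot scores T x k temporal scores (mean-subtracted pixel-time matrix times
#'   loadings).
#' @slot loadings P x k orthonormal spatial loadings (P = Y*X).
#' @slot varianceExplained fraction of total variance per component.
#' @slot center per-pixel temporal means removed before factorisation.
#' @slot movieDim integer c(Y, X).
#' @seealso \code{\link{pcaReduce}}
#' @exportClass PCAReduction
setClass("PCAReduction",
         representation(scores = "matrix",
                        loadings = "matrix",
                        varianceExplained = "numeric",
                        center = "numeric",
                        movieDim = "integer"))

#' ICADecomposition: paired spatial maps and temporal signals
#'
#' Result of fixed-point skewness-contrast ICA applied to a PCA-reduced movie.
#' The mixing parameter mu weights the spatial (mu = 0) versus temporal
#' (mu = 1) view in the contrast.
#'
#' @slot spatialMaps k x P component weight images (rows; reshape with
#'   \code{movieDim}).
#' @slot temporalSignals k x T component time courses, each zero-mean.
#' @slot retainedPCs number of principal components the ICA ran on.
#' @slot varianceExplained per-PC variance fractions, from the PCA stage.
#' @slot mu spatiotemporal weighting in [0, 1].
#' @slot converged logical; FALSE when the fixed-point iteration hit maxIter.
#' @slot iterations iterations used.
#' @slot movieDim integer c(Y, X).
#' @seealso \code{\link{spatialICA}}
#' @exportClass ICADecomposition
setClass("ICADecomposition",
         representation(spatialMaps = "matrix",
                        temporalSignals = "matrix",
                        retainedPCs = "integer",
                        varianceExplained = "numeric",
                        mu = "numeric",
                        converged = "logical",
                        iterations = "integer",
                        movieDim = "integer"))

setValidity("ICADecomposition", function(object) {
    if (nrow(object@spatialMaps) != nrow(object@temporalSignals))
        return("spatialMaps and temporalSignals must pair component-wise")
    if (nrow(object@spatialMaps) > object@retainedPCs)
        return("cannot have more components than retained PCs")
    if (object@mu < 0 || object@mu > 1) return("mu must lie in [0, 1]")
    TRUE
})

#' ROISet: segmented regions of interest
#'
#' @slot labelImage Y x X integer label image; 0 is background, labels are
#'   disjoint.
#' @slot pixels list of integer vectors of linear pixel indices, one per ROI.
#' @slot provenance integer vector: the ICA component each ROI came from.
#' @seealso \code{\link{segmentROIs}}, \code{\link{roiTraces}}
#' @exportClass ROISet
setClass("ROISet",
         representation(labelImage = "matrix",
                        pixels = "list",
                        provenance = "integer"))

setValidity("ROISet", function(object) {
    if (length(object@pixels) != length(object@provenance))
        return("one provenance entry per ROI is required")
    if (length(object@pixels) > 1L &&
        anyDuplicated(unlist(object@pixels)) > 0L)
        return("ROI pixel sets must be disjoint")
    TRUE
})

#' ResponseTemplateBank: the five stimulus-locked templates
#'
#' Unit-amplitude regressors derived solely from a fish's own stimulus
#' schedule: square waves for the sustained responses (\code{blue_onset},
#' \code{red_onset}) and exponential-decay sawtooth waves for the transient
#' ones (\code{mixed_onset}, \code{mixed_offset}, \code{blue_offset}).
#' Templates whose driving color is absent from the schedule are empty
#' (length 0) and excluded from matching.
#'
#' @slot templates named list of numeric vectors, one per category.
#' @slot kinds named character vector, \code{"square"} or \code{"sawtooth"}.
#' @slot rateHz sampling rate of the templates (Hz).
#' @slot tau sawtooth decay constant (s).
#' @seealso \code{\link{buildTemplates}}, \code{\link{classifyComponents}}
#' @exportClass ResponseTemplateBank
setClass("ResponseTemplateBank",
         representation(templates = "list",
                        kinds = "character",
                        rateHz = "numeric",
                        tau = "numeric"))

.TEMPLATE_KEYS <- c("blue_onset", "red_onset", "mixed_onset",
                    "mixed_offset", "blue_offset")

setValidity("ResponseTemplateBank", function(object) {
    if (!identical(names(object@templates), .TEMPLATE_KEYS))
        return(paste("templates must be named",
                     paste(.TEMPLATE_KEYS, collapse = ", "), "in that order"))
    if (object@tau <= 0) return("tau must be positive")
    for (k in .TEMPLATE_KEYS) {
        tm <- object@templates[[k]]
        if (length(tm) && (min(tm) < -1e-9 || max(tm) > 1 + 1e-9))
            return("templates must lie in [0, 1]")
    }
    TRUE
})

#' ClassifiedMaps: per-category registered, averaged spatial maps
#'
#' @slot members data.frame with one row per contributing (fish, component)
#'   map: \code{category}, \code{fish}, \code{component}, \code{maxCorr},
#'   \code{offsetY}, \code{offsetX}.
#' @slot averages named list of category-average spatial maps (Y x X), in the
#'   reference fish's coordinates.
#' @slot reference id of the reference fish used for registration.
#' @seealso \code{\link{registerAndAverage}}
#' @exportClass ClassifiedMaps
setClass("ClassifiedMaps",
         representation(members = "data.frame",
                        averages = "list",
                        reference = "character"))
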