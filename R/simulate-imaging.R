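#' Construct a planted source for the calcium-movie simulator
#'
#' @param footprint non-negative Y x X weight image, or \code{NULL} to build a
#'   Gaussian blob from \code{center}/\code{sigma}/\code{dim}.
#' @param responseClass one of the five response classes (see
#'   \linkS4class{PlantedSource}).
#' @param amplitude response amplitude (dF/F), > 0.
#' @param tauRise,tauDecay indicator kinetics, seconds (GCaMP6f-like defaults
#'   0.1 s rise, 0.7 s decay).
#' @param center c(y, x) blob center in pixels (when building a blob).
#' @param sigma blob SD in pixels.
#' @param dim image c(Y, X) (when building a blob).
#' @param cutoff blob support cutoff: weights below
#'   \code{cutoff * max} are zeroed so the footprint has finite support.
#' @return A \linkS4class{PlantedSource}.
#' @examples
#' src <- plantedSource(responseClass = "blue_onset_sustained",
#'                      center = c(10, 10), sigma = 2, dim = c(32, 32))
#' sum(src@footprint > 0)
#' @export
plantedSource <- function(footprint = NULL, responseClass, amplitude = 1,
                          tauRise = 0.1, tauDecay = 0.7,
                          center = NULL, sigma = 2.5, dim = NULL,
                          cutoff = 0.05) {
    if (is.null(footprint)) {
        stopifnot(!is.null(center), !is.null(dim))
        y <- seq_len(dim[1L]); x <- seq_len(dim[2L])
        footprint <- outer(exp(-(y - center[1L])^2 / (2 * sigma^2)),
                           exp(-(x - center[2L])^2 / (2 * sigma^2)))
        footprint[footprint < cutoff * max(footprint)] <- 0
    }
    new("PlantedSource", footprint = footprint,
        responseClass = responseClass, amplitude = amplitude,
        tauRise = tauRise, tauDecay = tauDecay)
}

#' One source per response class, laid out on a grid
#'
#' Convenience generator used by tests and the imaging pipeline: five
#' non-overlapping Gaussian sources, one per response class, with optional
#' seeded positional jitter (emulating anatomical variation across fish).
#'
#' @param dim image c(Y, X).
#' @param amplitude response amplitude shared by the sources.
#' @param jitterPx maximum absolute integer jitter (pixels) applied to each
#'   center, drawn uniformly per fish.
#' @param seed seed for the jitter.
#' @param sigma blob SD in pixels.
#' @return List of five \linkS4class{PlantedSource} objects (one per class)
#'   with a \code{centers} attribute giving the jittered c(y, x) centers.
#' @examples
#' srcs <- defaultSources(dim = c(40, 60))
#' vapply(srcs, function(s) s@responseClass, character(1))
#' @export
defaultSources <- function(dim = c(40L, 60L), amplitude = 1, jitterPx = 0L,
                           seed = 1L, sigma = 2.5) {
    base <- rbind(c(0.25, 0.20), c(0.25, 0.55), c(0.50, 0.85),
                  c(0.75, 0.20), c(0.75, 0.60))
    centers <- cbind(round(base[, 1L] * dim[1L]), round(base[, 2L] * dim[2L]))
    if (jitterPx > 0L) {
        jit <- .withSeed(seed, matrix(
            sample(seq(-jitterPx, jitterPx), 10L, replace = TRUE), 5L, 2L))
        centers <- centers + jit
    }
    srcs <- lapply(seq_len(5L), function(i)
        plantedSource(responseClass = .RESPONSE_CLASSES[i],
                      amplitude = amplitude, center = centers[i, ],
                      sigma = sigma, dim = dim))
    attr(srcs, "centers") <- centers
    srcs
}

## Discrete indicator kernel for h(t) = exp(-t/tauDecay) - exp(-t/tauRise).
## Each tap integrates h over one frame interval (the camera integrates over
## the exposure), so a transient lands on its event frame even when dt is
## much coarser than the kinetics. Returned with unit-area and unit-peak
## normalisations.
.calciumKernel <- function(tauRise, tauDecay, dt, durFactor = 8) {
    nTap <- max(2L, ceiling(durFactor * max(tauDecay, dt) / dt))
    j <- seq_len(nTap) - 1L
    intExp <- function(tau)
        tau * (exp(-j * dt / tau) - exp(-(j + 1L) * dt / tau))
    h <- intExp(tauDecay) - intExp(tauRise)
    h <- pmax(h, 0)
    if (max(h) <= 0) h[1L] <- 1
    list(area = h / sum(h), peak = h / max(h))
}

## Stimulus-locked driving signal for a response class: a 0/1 square over the
## relevant epochs (sustained classes) or a unit impulse train at the
## relevant light edges (transient classes).
.classDrive <- function(responseClass, schedule, times) {
    e <- epochs(schedule)
    drive <- numeric(length(times))
    dt <- times[2L] - times[1L]
    edgeIdx <- function(ts) {
        k <- round(ts / dt) + 1L
        k[k >= 1L & k <= length(times)]
    }
    lit <- e$channel != "dark"
    switch(responseClass,
        blue_onset_sustained = {
            idx <- .epochIndexAt(schedule, times)
            drive[e$channel[idx] == "blue470"] <- 1
        },
        red_onset = {
            idx <- .epochIndexAt(schedule, times)
            drive[e$channel[idx] == "red660"] <- 1
        },
        mixed_onset_transient =
            drive[edgeIdx(e$start_s[lit])] <- 1,
        mixed_offset_transient =
            drive[edgeIdx(e$start_s[lit] + e$duration_s[lit])] <- 1,
        blue_offset = {
            b <- e$channel == "blue470"
            drive[edgeIdx(e$start_s[b] + e$duration_s[b])] <- 1
        },
        stop("unknown response class: ", responseClass))
    drive
}

## Noise-free unit-amplitude response of a class: drive convolved with the
## indicator kernel. Sustained classes use the unit-area kernel (plateau 1),
## transient classes the unit-peak kernel (peak 1 per event).
.classResponse <- function(responseClass, schedule, times, tauRise, tauDecay) {
    dt <- times[2L] - times[1L]
    drive <- .classDrive(responseClass, schedule, times)
    kern <- .calciumKernel(tauRise, tauDecay, dt)
    h <- if (responseClass %in% c("blue_onset_sustained", "red_onset"))
        kern$area else kern$peak
    out <- stats::convolve(drive, rev(h), type = "open")
    out[seq_along(times)]
}

#' Simulate a calcium-imaging movie with planted sources
#'
#' Renders a T x Y x X single-plane fluorescence movie over a stimulus
#' schedule. Each pixel's trace is
#' \code{baseline + sum_s footprint_s * amplitude_s * response_s(t) + noise},
#' where each source's unit response is its class's stimulus-locked driving
#' signal convolved with a single-exponential-rise/decay indicator kernel.
#' Ground truth (masks, classes, responses) is returned for every source.
#'
#' @param schedule a \linkS4class{StimulusSchedule} (imaging layout: dark
#'   epochs alternating with blue/red pulses).
#' @param sources list of \linkS4class{PlantedSource} objects fitting in
#'   \code{dim}.
#' @param dim image c(Y, X).
#' @param rateHz movie frame rate (default 1 Hz, approximately the per-plane
#'   rate of a 7.1 Hz, 10-plane volumetric acquisition).
#' @param noiseSd per-pixel Gaussian noise SD (same units as amplitude).
#' @param baseline constant baseline fluorescence.
#' @param seed integer seed for the noise.
#' @return List: \code{movie} (T x Y x X array), \code{rateHz},
#'   \code{masks} (Y x X integer label image, one label per source),
#'   \code{classes} (character per source), \code{responses} (sources x T
#'   noise-free unit responses), \code{footprints} (list of Y x X matrices),
#'   \code{schedule}.
#' @examples
#' sch <- makeSchedule("imaging_random", nCycles = 2, seed = 3)
#' src <- defaultSources(dim = c(20, 30), sigma = 1.5)[1:2]
#' sim <- simulateCalciumMovie(sch, src, dim = c(20, 30), noiseSd = 0)
#' dim(sim$movie)
#' @export
simulateCalciumMovie <- function(schedule, sources, dim, rateHz = 1,
                                 noiseSd = 0.1, baseline = 1, seed = 1L) {
    stopifnot(is(schedule, "StimulusSchedule"), length(sources) >= 1L)
    .assertScalarNumber(rateHz, "rateHz", positive = TRUE)
    dim <- as.integer(dim)
    for (s in sources) {
        if (!is(s, "PlantedSource")) stop("sources must be PlantedSource")
        if (!identical(dim(s@footprint), dim))
            stop("source footprint shape does not match 'dim'")
    }
    ## identical duplicated (footprint, class) pairs are allowed but suspect
    keys <- vapply(sources, function(s)
        paste(s@responseClass, digestFootprint(s@footprint)), character(1L))
    if (anyDuplicated(keys))
        warning("overlapping identical footprints with identical classes")

    nT <- as.integer(round(totalDuration(schedule) * rateHz))
    times <- (seq_len(nT) - 1L) / rateHz
    P <- prod(dim)
    k <- length(sources)
    resp <- matrix(0, k, nT)
    F <- matrix(0, k, P)
    for (i in seq_len(k)) {
        s <- sources[[i]]
        resp[i, ] <- s@amplitude *
            .classResponse(s@responseClass, schedule, times,
                           s@tauRise, s@tauDecay)
        F[i, ] <- as.vector(s@footprint)
    }
    M <- baseline + t(resp) %*% F         # T x P
    if (noiseSd > 0)
        M <- M + .withSeed(seed,
                           matrix(stats::rnorm(nT * P, 0, noiseSd), nT, P))
    movie <- array(M, c(nT, dim))
    masks <- matrix(0L, dim[1L], dim[2L])
    for (i in seq_len(k)) masks[sources[[i]]@footprint > 0] <- i
    list(movie = movie, rateHz = rateHz, masks = masks,
         classes = vapply(sources, function(s) s@responseClass,
                          character(1L)),
         responses = resp,
         footprints = lapply(sources, function(s) s@footprint),
         schedule = schedule)
}

## Cheap footprint fingerprint for duplicate detection.
digestFootprint <- function(fp) {
    idx <- which(fp > 0)
    paste(length(idx), sum(idx), signif(sum(fp), 10), collapse = "-")
}
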