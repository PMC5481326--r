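#' Build a stimulus schedule
#'
#' Generates the two schedule layouts used throughout the package. In
#' \code{behavior_cycles} mode each cycle is 60 s light OFF (dark) followed by
#' 60 s light ON of a single channel, mirroring the climbing assay's 10
#' alternating light/dark cycles. In \code{imaging_random} mode \code{nCycles}
#' one-minute colored pulses (half blue, half red, in seeded random order)
#' alternate with one-minute dark epochs, mirroring the randomized imaging
#' stimulus.
#'
#' @param mode \code{"behavior_cycles"} or \code{"imaging_random"}.
#' @param nCycles number of cycles (behavior) or colored pulses (imaging;
#'   must be even so blue and red counts are equal).
#' @param seed integer seed; the same seed reproduces the same pulse order.
#' @param channel light channel for behavior cycles (see
#'   \code{\link{lightChannels}}).
#' @param epochDuration epoch duration in seconds (default 60).
#' @param irradiance irradiance of lit epochs, uW/cm^2 (default 600, the
#'   mid-level blue condition).
#' @param pulseChannels the two channels randomized in imaging mode.
#' @return A \linkS4class{StimulusSchedule}.
#' @examples
#' makeSchedule("behavior_cycles", nCycles = 10, seed = 1)
#' makeSchedule("imaging_random", nCycles = 6, seed = 7)
#' @export
makeSchedule <- function(mode = c("behavior_cycles", "imaging_random"),
                         nCycles, seed = 1L, channel = "blue470",
                         epochDuration = 60, irradiance = 600,
                         pulseChannels = c("blue470", "red660")) {
    mode <- match.arg(mode)
    if (!is.numeric(nCycles) || length(nCycles) != 1L || nCycles < 1 ||
        nCycles != round(nCycles))
        stop("'nCycles' must be a positive integer")
    nCycles <- as.integer(nCycles)
    .assertScalarNumber(epochDuration, "epochDuration", positive = TRUE)
    if (mode == "behavior_cycles") {
        if (!channel %in% names(.CHANNEL_WAVELENGTHS) || channel == "dark")
            stop("'channel' must be a lit channel")
        chans <- rep(c("dark", channel), nCycles)
    } else {
        if (nCycles %% 2L != 0L)
            stop("imaging_random needs an even 'nCycles' so the two colors",
                 " have equal counts")
        stopifnot(length(pulseChannels) == 2L,
                  all(pulseChannels %in% names(.CHANNEL_WAVELENGTHS)),
                  !"dark" %in% pulseChannels)
        pulses <- .withSeed(seed, sample(rep(pulseChannels, nCycles / 2L)))
        chans <- as.vector(rbind("dark", pulses))
    }
    n <- length(chans)
    e <- data.frame(
        start_s = (seq_len(n) - 1L) * epochDuration,
        duration_s = rep(epochDuration, n),
        channel = chans,
        irradiance = ifelse(chans == "dark", 0, irradiance),
        stringsAsFactors = FALSE)
    new("StimulusSchedule", epochs = e,
        totalDuration = n * epochDuration, seed = as.integer(seed))
}

#' Write / read a stimulus schedule as JSON
#'
#' The on-disk form is a JSON object with an \code{epochs} array
#' (\code{start_s}, \code{duration_s}, \code{channel}, \code{irradiance}),
#' plus \code{total_duration_s} and \code{seed}.
#'
#' @param schedule a \linkS4class{StimulusSchedule}.
#' @param path file path.
#' @return \code{readScheduleJSON} returns a \linkS4class{StimulusSchedule};
#'   \code{writeScheduleJSON} returns \code{path} invisibly.
#' @examples
#' sch <- makeSchedule("behavior_cycles", nCycles = 2)
#' f <- tempfile(fileext = ".json")
#' writeScheduleJSON(sch, f)
#' epochs(readScheduleJSON(f))
#' @export
writeScheduleJSON <- function(schedule, path) {
    stopifnot(is(schedule, "StimulusSchedule"))
    obj <- list(epochs = schedule@epochs,
                total_duration_s = schedule@totalDuration,
                seed = schedule@seed)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' @rdname writeScheduleJSON
#' @export
readScheduleJSON <- function(path) {
    if (!file.exists(path)) stop("schedule file not found: ", path)
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    e <- as.data.frame(obj$epochs, stringsAsFactors = FALSE)
    new("StimulusSchedule", epochs = e,
        totalDuration = as.numeric(obj$total_duration_s),
        seed = if (is.null(obj$seed)) NA_integer_ else as.integer(obj$seed))
}
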