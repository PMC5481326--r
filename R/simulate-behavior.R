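#' Behavior-model parameters for the trajectory simulator
#'
#' Parameters of the first-order drift-diffusion model used to emulate
#' light-masked vertical migration: larvae climb during light ON and dive
#' during the adjacent darkness with per-channel probability
#' (\code{responsiveness}), and otherwise perform an unbiased random walk.
#' Defaults emulate the assay's wavelength dependence: strong climbing under
#' blue and green light, weak responses to red and UV, none in sustained
#' darkness.
#'
#' @param responsiveness named numeric in [0, 1], one entry per channel;
#'   probability that a fish responds (climbs/dives) in a given epoch. The
#'   entry for \code{dark} must be 0: diving during a dark epoch is governed
#'   by the adjacent lit channel, not by darkness itself.
#' @param climbSpeed,diveSpeed mean drift speeds, cm/s.
#' @param speedSd between-epoch SD of the drift speed, cm/s.
#' @param positionNoiseSd diffusion scale, cm per sqrt(s): each step adds
#'   Gaussian noise with SD \code{positionNoiseSd * sqrt(dt)}.
#' @param startDepthRange depth range (cm) fish start from, uniform draw;
#'   dark-adapted fish sit low in the column.
#' @return A named list of validated parameters.
#' @examples
#' behaviorParams(responsiveness = c(blue470 = 1))
#' @export
behaviorParams <- function(responsiveness = c(dark = 0, blue470 = 0.85,
                                              green525 = 0.85, red660 = 0.30,
                                              uv375 = 0.25),
                           climbSpeed = 0.12, diveSpeed = 0.12,
                           speedSd = 0.03, positionNoiseSd = 0.15,
                           startDepthRange = c(3.5, 5.0)) {
    full <- c(dark = 0, blue470 = 0, green525 = 0, red660 = 0, uv375 = 0)
    if (is.null(names(responsiveness)) ||
        !all(names(responsiveness) %in% names(full)))
        stop("'responsiveness' must be named by channel")
    full[names(responsiveness)] <- responsiveness
    if (any(full < 0 | full > 1)) stop("responsiveness must lie in [0, 1]")
    if (full["dark"] != 0) stop("responsiveness for dark must be 0")
    .assertScalarNumber(climbSpeed, "climbSpeed")
    .assertScalarNumber(diveSpeed, "diveSpeed")
    if (climbSpeed < 0 || diveSpeed < 0) stop("speeds must be >= 0")
    .assertScalarNumber(speedSd, "speedSd")
    .assertScalarNumber(positionNoiseSd, "positionNoiseSd")
    if (speedSd < 0 || positionNoiseSd < 0) stop("noise SDs must be >= 0")
    stopifnot(length(startDepthRange) == 2L,
              all(startDepthRange >= 0),
              all(startDepthRange <= .CHAMBER_HEIGHT_CM))
    list(responsiveness = full, climbSpeed = climbSpeed,
         diveSpeed = diveSpeed, speedSd = speedSd,
         positionNoiseSd = positionNoiseSd,
         startDepthRange = sort(startDepthRange))
}

#' Simulate vertical-migration trajectories
#'
#' Drift-diffusion simulation of single-larva depth over a stimulus schedule.
#' At the start of each epoch, each fish independently decides (Bernoulli with
#' the epoch channel's responsiveness) whether to respond; responders drift
#' upward (depth decreasing) during lit epochs at a speed drawn around
#' \code{climbSpeed}, and downward during dark epochs at a speed drawn around
#' \code{diveSpeed} (dark epochs inherit the responsiveness of the adjacent
#' lit epoch). Every step adds diffusion noise, and positions are clipped to
#' the chamber, \code{[0, chamberHeight()]} cm.
#'
#' @param params list from \code{\link{behaviorParams}}.
#' @param schedule a \linkS4class{StimulusSchedule}.
#' @param nFish number of fish (>= 1).
#' @param rateHz sampling rate, frames per second (default 5, the assay's
#'   video rate).
#' @param seed integer seed; identical seeds give bit-identical trajectories.
#' @param startDepth optional fixed start depth (cm) overriding the random
#'   draw from \code{params$startDepthRange}.
#' @return A \linkS4class{TrajectorySet}, fish x time, depths in cm
#'   (0 = surface).
#' @examples
#' sch <- makeSchedule("behavior_cycles", nCycles = 2)
#' tr <- simulateTrajectories(behaviorParams(), sch, nFish = 3, seed = 1)
#' dim(depths(tr))
#' @export
simulateTrajectories <- function(params, schedule, nFish, rateHz = 5,
                                 seed = 1L, startDepth = NULL) {
    stopifnot(is(schedule, "StimulusSchedule"))
    .assertScalarNumber(rateHz, "rateHz", positive = TRUE)
    if (!is.numeric(nFish) || nFish < 1 || nFish != round(nFish))
        stop("'nFish' must be a positive integer")
    nFish <- as.integer(nFish)
    e <- epochs(schedule)
    if (nrow(e) == 0L) stop("empty schedule")
    dt <- 1 / rateHz
    nT <- as.integer(round(totalDuration(schedule) * rateHz))
    times <- (seq_len(nT) - 1L) * dt
    epIdx <- .epochIndexAt(schedule, times)
    gov <- .governingChannel(schedule)
    ## drift direction per epoch: lit -> climb (-1), dark -> dive (+1)
    dirs <- ifelse(e$channel == "dark", 1, -1)

    depth <- .withSeed(seed, {
        start <- if (is.null(startDepth))
            stats::runif(nFish, params$startDepthRange[1L],
                         params$startDepthRange[2L])
        else rep(startDepth, nFish)
        ## per (fish, epoch) response decision and drift speed
        nE <- nrow(e)
        resp <- matrix(stats::rbinom(nFish * nE, 1L,
                                     rep(params$responsiveness[gov],
                                         each = nFish)),
                       nFish, nE)
        spMean <- ifelse(dirs > 0, params$diveSpeed, params$climbSpeed)
        speed <- matrix(pmax(0, stats::rnorm(nFish * nE,
                                             rep(spMean, each = nFish),
                                             params$speedSd)),
                        nFish, nE)
        drift <- resp * speed * matrix(rep(dirs, each = nFish), nFish, nE)
        noise <- if (params$positionNoiseSd > 0)
            matrix(stats::rnorm(nFish * (nT - 1L), 0,
                                params$positionNoiseSd * sqrt(dt)),
                   nFish, nT - 1L)
        else matrix(0, nFish, nT - 1L)
        d <- matrix(0, nFish, nT)
        d[, 1L] <- pmin(pmax(start, 0), .CHAMBER_HEIGHT_CM)
        for (k in seq_len(nT - 1L)) {
            step <- drift[, epIdx[k]] * dt + noise[, k]
            d[, k + 1L] <- pmin(pmax(d[, k] + step, 0), .CHAMBER_HEIGHT_CM)
        }
        d
    })
    new("TrajectorySet", depth = depth, rateHz = rateHz,
        calibration = list(),
        sourceIds = sprintf("fish%02d", seq_len(nFish)),
        flags = matrix(FALSE, nFish, nT))
}

#' Render a single-fish behavior video
#'
#' Renders a trajectory as the assay camera would see it: one bright Gaussian
#' blob per frame on a dark background, at the image row corresponding to the
#' fish's depth. The linear depth-to-row calibration is returned so the
#' tracker can convert back to cm. One chamber holds one fish, so the
#' trajectory set must contain exactly one fish.
#'
#' @param traj a single-fish \linkS4class{TrajectorySet}.
#' @param imageSize integer c(height, width) in pixels; the height must
#'   accommodate the blob with a margin.
#' @param blobSigma Gaussian blob SD in pixels.
#' @param blobPeak peak blob intensity (image units, background 0).
#' @param noiseSd per-pixel Gaussian noise SD (0 for a clean video).
#' @param seed seed for the pixel noise.
#' @return List with \code{frames} (list of height x width matrices) and
#'   \code{calibration} (\code{cm_per_px}, \code{row_offset}: depth d maps to
#'   row \code{row_offset + d / cm_per_px}).
#' @examples
#' sch <- makeSchedule("behavior_cycles", nCycles = 1)
#' tr <- simulateTrajectories(behaviorParams(), sch, nFish = 1, rateHz = 1)
#' vid <- renderBehaviorVideo(tr, imageSize = c(60, 20))
#' length(vid$frames)
#' @export
renderBehaviorVideo <- function(traj, imageSize = c(120L, 40L),
                                blobSigma = 2, blobPeak = 1,
                                noiseSd = 0, seed = 1L) {
    stopifnot(is(traj, "TrajectorySet"))
    if (nFish(traj) != 1L)
        stop("one chamber holds one fish: render one trajectory per video")
    h <- as.integer(imageSize[1L]); w <- as.integer(imageSize[2L])
    margin <- ceiling(3 * blobSigma) + 1L
    if (2 * margin >= h)
        stop("blob radius too large for the image height")
    cmPerPx <- .CHAMBER_HEIGHT_CM / (h - 1L - 2L * margin)
    rowOffset <- margin + 1L   # row of depth 0
    d <- depths(traj)[1L, ]
    col0 <- (w + 1) / 2
    rows <- seq_len(h); cols <- seq_len(w)
    colG <- exp(-(cols - col0)^2 / (2 * blobSigma^2))
    frames <- .withSeed(seed, lapply(seq_along(d), function(k) {
        r0 <- rowOffset + d[k] / cmPerPx
        fr <- blobPeak * outer(exp(-(rows - r0)^2 / (2 * blobSigma^2)), colG)
        if (noiseSd > 0)
            fr <- fr + matrix(stats::rnorm(h * w, 0, noiseSd), h, w)
        fr
    }))
    list(frames = frames,
         calibration = list(cm_per_px = cmPerPx, row_offset = rowOffset))
}
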