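#' Track a single larva by intensity thresholding
#'
#' Recovers per-frame vertical position from a bright-fish-on-dark video.
#' Each frame is thresholded; the largest above-threshold connected component
#' is taken as the fish and its intensity-weighted centroid row converted to
#' depth (cm) via the linear calibration. Frames with no component are filled
#' by linear interpolation from neighbours (up to \code{maxGap} consecutive
#' frames) and flagged; unusable videos raise an error.
#'
#' @param frames list of equal-sized numeric matrices (one per frame), or a
#'   T x Y x X array.
#' @param threshold intensity threshold; must lie within the video's intensity
#'   range.
#' @param calibration list with \code{cm_per_px} and \code{row_offset} (as
#'   emitted by \code{\link{renderBehaviorVideo}}).
#' @param rateHz frame rate (default 5 fps).
#' @param invert set TRUE for dark-fish-on-bright videos.
#' @param maxGap longest run of undetected frames filled by interpolation
#'   (default 5 frames = 1 s at 5 fps); a longer gap is an error.
#' @param maxMissingFrac hard-error ceiling on the overall fraction of frames
#'   without a detectable component (default 0.2).
#' @return A single-fish \linkS4class{TrajectorySet}; interpolated samples are
#'   flagged in \code{interpFlags()}.
#' @examples
#' sch <- makeSchedule("behavior_cycles", nCycles = 1)
#' tr <- simulateTrajectories(behaviorParams(), sch, nFish = 1, rateHz = 1)
#' vid <- renderBehaviorVideo(tr, imageSize = c(60, 20))
#' out <- trackPositions(vid$frames, 0.5, vid$calibration, rateHz = 1)
#' max(abs(depths(out) - depths(tr)))
#' @export
trackPositions <- function(frames, threshold = 0.5, calibration,
                           rateHz = 5, invert = FALSE,
                           maxGap = 5L, maxMissingFrac = 0.2) {
    if (is.array(frames) && length(dim(frames)) == 3L) {
        nT <- dim(frames)[1L]
        frames <- lapply(seq_len(nT), function(k) frames[k, , ])
    }
    stopifnot(is.list(frames), length(frames) >= 1L)
    dims <- vapply(frames, dim, integer(2L))
    if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
        stop("frames must all have the same size")
    stopifnot(is.list(calibration),
              !is.null(calibration$cm_per_px),
              !is.null(calibration$row_offset))
    rng <- range(vapply(frames, range, numeric(2L)))
    if (threshold <= rng[1L] || threshold >= rng[2L])
        stop(sprintf("threshold %.3g outside the video intensity range [%.3g, %.3g]",
                     threshold, rng[1L], rng[2L]))
    nT <- length(frames)
    rowPos <- rep(NA_real_, nT)
    for (k in seq_len(nT)) {
        fr <- frames[[k]]
        if (invert) fr <- rng[2L] - fr + rng[1L]
        bw <- fr > threshold
        if (!any(bw)) next
        lab <- EBImage::bwlabel(bw)
        sizes <- tabulate(lab[lab > 0L])
        big <- which.max(sizes)
        sel <- lab == big
        w <- fr[sel]
        rowsel <- row(fr)[sel]
        rowPos[k] <- sum(rowsel * w) / sum(w)   # sub-pixel centroid
    }
    missing <- is.na(rowPos)
    if (mean(missing) > maxMissingFrac)
        stop(sprintf("unusable video: %.0f%% of frames have no component above threshold",
                     100 * mean(missing)))
    if (any(missing)) {
        runs <- rle(missing)
        if (any(runs$lengths[runs$values] > maxGap))
            stop(sprintf("gap of more than %d consecutive undetected frames",
                         maxGap))
        ok <- which(!missing)
        rowPos <- stats::approx(ok, rowPos[ok], xout = seq_len(nT),
                                rule = 2)$y
    }
    depth <- (rowPos - calibration$row_offset) * calibration$cm_per_px
    depth <- pmin(pmax(depth, 0), .CHAMBER_HEIGHT_CM)
    new("TrajectorySet",
        depth = matrix(depth, 1L, nT),
        rateHz = rateHz,
        calibration = calibration,
        sourceIds = "tracked01",
        flags = matrix(missing, 1L, nT))
}
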