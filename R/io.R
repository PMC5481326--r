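#' Trajectory CSV I/O
#'
#' Trajectories are stored as a CSV with a \code{time_s} column plus one
#' \code{depth_cm_<id>} column per fish, and a JSON sidecar holding the
#' sampling rate, calibration and interpolation flags.
#'
#' @param traj a \linkS4class{TrajectorySet}.
#' @param path CSV path; the sidecar goes to \code{<path>.meta.json} unless
#'   \code{metaPath} is given.
#' @param metaPath optional sidecar path.
#' @return \code{readTrajectoriesCSV} returns a \linkS4class{TrajectorySet};
#'   the writer returns \code{path} invisibly.
#' @examples
#' sch <- makeSchedule("behavior_cycles", nCycles = 1)
#' tr <- simulateTrajectories(behaviorParams(), sch, nFish = 2, rateHz = 1)
#' f <- tempfile(fileext = ".csv")
#' writeTrajectoriesCSV(tr, f)
#' nFish(readTrajectoriesCSV(f))
#' @export
writeTrajectoriesCSV <- function(traj, path, metaPath = NULL) {
    stopifnot(is(traj, "TrajectorySet"))
    if (is.null(metaPath)) metaPath <- paste0(path, ".meta.json")
    d <- depths(traj)
    df <- data.frame(time_s = (seq_len(ncol(d)) - 1L) / rateHz(traj))
    for (i in seq_len(nrow(d)))
        df[[paste0("depth_cm_", sourceIds(traj)[i])]] <- d[i, ]
    utils::write.csv(df, path, row.names = FALSE)
    jsonlite::write_json(
        list(rate_hz = rateHz(traj),
             calibration = calibration(traj),
             source_ids = sourceIds(traj),
             interpolated = lapply(seq_len(nrow(d)), function(i)
                 which(interpFlags(traj)[i, ])),
             n_samples = ncol(d)),
        metaPath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
}

#' @rdname writeTrajectoriesCSV
#' @export
readTrajectoriesCSV <- function(path, metaPath = NULL) {
    if (!file.exists(path)) stop("trajectory file not found: ", path)
    if (is.null(metaPath)) metaPath <- paste0(path, ".meta.json")
    df <- utils::read.csv(path, check.names = FALSE)
    depthCols <- grep("^depth_cm_", names(df), value = TRUE)
    if (!length(depthCols)) stop("no depth_cm_* columns in ", path)
    d <- t(as.matrix(df[depthCols]))
    ids <- sub("^depth_cm_", "", depthCols)
    meta <- if (file.exists(metaPath))
        jsonlite::read_json(metaPath, simplifyVector = TRUE) else NULL
    rate <- if (!is.null(meta$rate_hz)) meta$rate_hz
            else 1 / diff(df$time_s[1:2])
    flags <- matrix(FALSE, nrow(d), ncol(d))
    if (!is.null(meta$interpolated))
        for (i in seq_along(meta$interpolated))
            flags[i, unlist(meta$interpolated[[i]])] <- TRUE
    calib <- if (!is.null(meta$calibration) && length(meta$calibration))
        as.list(meta$calibration) else list()
    dimnames(d) <- NULL
    new("TrajectorySet", depth = d, rateHz = rate, calibration = calib,
        sourceIds = ids, flags = flags)
}

#' Movie / image-stack TIFF I/O
#'
#' Writes a T x Y x X array (or a list of Y x X matrices) as a multi-page
#' 32-bit TIFF. TIFF samples are stored in [0, 1], so the data are affinely
#' rescaled and the (offset, scale) recorded in a JSON sidecar
#' (\code{<path>.scale.json}); the reader undoes the scaling.
#'
#' @param movie T x Y x X array, or list of matrices (pages).
#' @param path TIFF path.
#' @return \code{readMovieTIFF} returns a T x Y x X array; the writer returns
#'   \code{path} invisibly.
#' @examples
#' arr <- array(rnorm(4 * 5 * 6), c(4, 5, 6))
#' f <- tempfile(fileext = ".tif")
#' writeMovieTIFF(arr, f)
#' max(abs(readMovieTIFF(f) - arr)) < 1e-6
#' @export
writeMovieTIFF <- function(movie, path) {
    pages <- if (is.array(movie) && length(dim(movie)) == 3L)
        lapply(seq_len(dim(movie)[1L]), function(k) movie[k, , ])
    else movie
    stopifnot(is.list(pages), length(pages) >= 1L)
    rng <- range(vapply(pages, range, numeric(2L)))
    offset <- rng[1L]
    scale <- if (diff(rng) > 0) diff(rng) else 1
    scaled <- lapply(pages, function(m) (m - offset) / scale)
    tiff::writeTIFF(scaled, path, bits.per.sample = 32L)
    jsonlite::write_json(list(offset = offset, scale = scale),
                         paste0(path, ".scale.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeMovieTIFF
#' @export
readMovieTIFF <- function(path) {
    if (!file.exists(path)) stop("TIFF not found: ", path)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    sc <- paste0(path, ".scale.json")
    offset <- 0; scale <- 1
    if (file.exists(sc)) {
        meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
        offset <- meta$offset; scale <- meta$scale
    }
    arr <- array(0, c(length(pages), dim(pages[[1L]])))
    for (k in seq_along(pages)) arr[k, , ] <- pages[[k]] * scale + offset
    arr
}
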