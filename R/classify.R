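#' Build the five stimulus-locked response templates
#'
#' Template timing is derived solely from the fish's own stimulus schedule.
#' The sustained categories are square waves: \code{blue_onset} is 1 during
#' blue epochs, \code{red_onset} during red epochs. The transient categories
#' are sawtooth waves that jump to 1 at a light edge and decay exponentially
#' with constant \code{tau}: \code{mixed_onset} at every light onset (both
#' colors), \code{mixed_offset} at every light offset, \code{blue_offset} at
#' blue offsets only. If the schedule lacks a color, the affected templates
#' are emitted empty and excluded from matching, with a warning.
#'
#' @param schedule a \linkS4class{StimulusSchedule}.
#' @param rateHz sampling rate matching the ICA temporal signals.
#' @param tau sawtooth decay constant in seconds (default 2, a few times the
#'   indicator decay, so transient templates resemble transient calcium
#'   responses).
#' @return A \linkS4class{ResponseTemplateBank}.
#' @examples
#' sch <- makeSchedule("imaging_random", nCycles = 4, seed = 2)
#' buildTemplates(sch, rateHz = 1)
#' @export
buildTemplates <- function(schedule, rateHz = 1, tau = 2) {
    stopifnot(is(schedule, "StimulusSchedule"))
    .assertScalarNumber(rateHz, "rateHz", positive = TRUE)
    .assertScalarNumber(tau, "tau", positive = TRUE)
    e <- epochs(schedule)
    nT <- as.integer(round(totalDuration(schedule) * rateHz))
    times <- (seq_len(nT) - 1L) / rateHz
    idx <- .epochIndexAt(schedule, times)
    haveBlue <- any(e$channel == "blue470")
    haveRed <- any(e$channel == "red660")
    if (!haveBlue || !haveRed)
        warning("schedule lacks ",
                paste(c("blue", "red")[!c(haveBlue, haveRed)],
                      collapse = " and "),
                " epochs; the affected templates are empty and excluded")
    square <- function(chan) as.numeric(e$channel[idx] == chan)
    ## sawtooth: 1 at the most recent event, exponential decay afterwards
    sawtooth <- function(eventTimes) {
        if (!length(eventTimes)) return(numeric(nT))
        out <- numeric(nT)
        last <- findInterval(times, eventTimes)
        on <- last >= 1L
        out[on] <- exp(-(times[on] - eventTimes[last[on]]) / tau)
        out
    }
    lit <- e$channel != "dark"
    blue <- e$channel == "blue470"
    tmpl <- list(
        blue_onset = if (haveBlue) square("blue470") else numeric(0L),
        red_onset = if (haveRed) square("red660") else numeric(0L),
        mixed_onset = if (haveBlue && haveRed)
            sawtooth(e$start_s[lit]) else numeric(0L),
        mixed_offset = if (haveBlue && haveRed)
            sawtooth(e$start_s[lit] + e$duration_s[lit]) else numeric(0L),
        blue_offset = if (haveBlue)
            sawtooth(e$start_s[blue] + e$duration_s[blue]) else numeric(0L))
    kinds <- c(blue_onset = "square", red_onset = "square",
               mixed_onset = "sawtooth", mixed_offset = "sawtooth",
               blue_offset = "sawtooth")
    new("ResponseTemplateBank", templates = tmpl, kinds = kinds,
        rateHz = rateHz, tau = tau)
}

#' Classify ICA temporal signals against the template bank
#'
#' For each temporal signal, Pearson correlations against all available
#' templates are computed and the maximum is taken; the signal (and its
#' spatial map) is assigned to the winning category iff the maximum exceeds
#' \code{threshold} (default 0.5), otherwise it stays unclassified. Ties are
#' broken by the fixed key order blue_onset, red_onset, mixed_onset,
#' mixed_offset, blue_offset. Classification is invariant to affine rescaling
#' of a signal (a Pearson correlation property). All-constant signals are
#' unclassified with a warning.
#'
#' @param decomp an \linkS4class{ICADecomposition}, or a k x T numeric matrix
#'   of temporal signals.
#' @param bank a \linkS4class{ResponseTemplateBank} at the same rate/length.
#' @param threshold minimum winning correlation (default 0.5).
#' @return data.frame with one row per component: \code{component},
#'   \code{category} (\code{"unclassified"} when below threshold),
#'   \code{max_corr}.
#' @examples
#' sch <- makeSchedule("imaging_random", nCycles = 4, seed = 2)
#' bank <- buildTemplates(sch, rateHz = 1)
#' sig <- matrix(templates(bank)$blue_onset, nrow = 1)
#' classifyComponents(sig, bank)
#' @export
classifyComponents <- function(decomp, bank, threshold = 0.5) {
    stopifnot(is(bank, "ResponseTemplateBank"))
    sigs <- if (is(decomp, "ICADecomposition")) temporalSignals(decomp)
            else as.matrix(decomp)
    avail <- names(bank@templates)[
        vapply(bank@templates, length, integer(1L)) > 0L]
    if (!length(avail)) stop("template bank has no available templates")
    nT <- length(bank@templates[[avail[1L]]])
    if (ncol(sigs) != nT)
        stop("signals and templates must have the same length")
    out <- data.frame(component = seq_len(nrow(sigs)),
                      category = "unclassified",
                      max_corr = NA_real_,
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(sigs))) {
        s <- sigs[i, ]
        if (stats::sd(s) == 0) {
            warning("component ", i, " has a constant signal; unclassified")
            next
        }
        rr <- vapply(avail, function(k) {
            tm <- bank@templates[[k]]
            if (stats::sd(tm) == 0) -Inf else stats::cor(s, tm)
        }, numeric(1L))
        best <- which.max(rr)        # first max wins: fixed key order
        out$max_corr[i] <- rr[best]
        if (rr[best] > threshold) out$category[i] <- avail[best]
    }
    out
}

## Integer-translation registration by maximising the 2-D cross-correlation
## (dot product on the overlap) over shifts up to maxShift. Returns c(dy, dx)
## such that moving `map` by (dy, dx) aligns it to `ref`.
.bestShift <- function(ref, map, maxShift) {
    best <- c(0L, 0L); bestVal <- -Inf
    nr <- nrow(ref); nc <- ncol(ref)
    for (dy in -maxShift:maxShift) {
        ry <- max(1L, 1L + dy):min(nr, nr + dy)
        my <- ry - dy
        for (dx in -maxShift:maxShift) {
            rx <- max(1L, 1L + dx):min(nc, nc + dx)
            mx <- rx - dx
            val <- sum(ref[ry, rx] * map[my, mx])
            if (val > bestVal) { bestVal <- val; best <- c(dy, dx) }
        }
    }
    best
}

.shiftMap <- function(map, dy, dx) {
    out <- matrix(NA_real_, nrow(map), ncol(map))
    ry <- max(1L, 1L + dy):min(nrow(map), nrow(map) + dy)
    rx <- max(1L, 1L + dx):min(ncol(map), ncol(map) + dx)
    out[ry, rx] <- map[ry - dy, rx - dx]
    out
}

#' Register categorized maps across fish and average per category
#'
#' Within each category, every fish's spatial map is shifted by the integer
#' translation maximising its 2-D cross-correlation with the reference fish's
#' map, then the shifted maps are averaged (mean over the fish contributing
#' to each pixel of the overlap). Empty categories are omitted.
#'
#' @param maps nested list: \code{maps[[category]][[fishId]]} is that fish's
#'   Y x X spatial map for the category (all maps the same shape). Entries
#'   may also carry an optional \code{maxCorr} attribute and a
#'   \code{component} attribute, which are propagated to the member table.
#' @param reference fish id (name) used as the registration reference; it
#'   must appear in every non-empty category it is needed for. Defaults to
#'   the first fish of each category.
#' @param maxShift largest absolute shift searched, pixels (default a quarter
#'   of the smaller image dimension).
#' @return A \linkS4class{ClassifiedMaps}: per-category averaged maps in
#'   reference coordinates plus a member table with per-fish offsets.
#' @examples
#' m <- matrix(0, 20, 20); m[8:12, 8:12] <- 1
#' cm <- registerAndAverage(list(blue_onset = list(f1 = m, f2 = m)))
#' names(categoryAverages(cm))
#' @export
registerAndAverage <- function(maps, reference = NULL, maxShift = NULL) {
    stopifnot(is.list(maps), length(maps) >= 1L)
    maps <- Filter(function(x) length(x) > 0L, maps)
    if (!length(maps)) stop("no non-empty category supplied")
    shape <- dim(maps[[1L]][[1L]])
    if (is.null(maxShift)) maxShift <- max(1L, floor(min(shape) / 4))
    members <- list()
    averages <- list()
    refId <- if (is.null(reference)) {
        nm <- names(maps[[1L]])
        if (is.null(nm)) "fish01" else nm[1L]
    } else as.character(reference)
    for (cat in names(maps)) {
        group <- maps[[cat]]
        if (is.null(names(group)))
            names(group) <- sprintf("fish%02d", seq_along(group))
        for (g in group)
            if (!identical(dim(g), shape)) stop("maps must share one shape")
        ref <- if (refId %in% names(group)) group[[refId]] else group[[1L]]
        shifted <- vector("list", length(group))
        for (j in seq_along(group)) {
            sh <- .bestShift(ref, group[[j]], maxShift)
            shifted[[j]] <- .shiftMap(group[[j]], sh[1L], sh[2L])
            members[[length(members) + 1L]] <- data.frame(
                category = cat,
                fish = names(group)[j],
                component = attr(group[[j]], "component") %||% NA_integer_,
                maxCorr = attr(group[[j]], "maxCorr") %||% NA_real_,
                offsetY = sh[1L], offsetX = sh[2L],
                stringsAsFactors = FALSE)
        }
        stack <- array(unlist(shifted), c(shape, length(group)))
        avg <- apply(stack, c(1L, 2L), mean, na.rm = TRUE)
        avg[is.nan(avg)] <- NA_real_
        averages[[cat]] <- avg
    }
    new("ClassifiedMaps",
        members = do.call(rbind, members),
        averages = averages,
        reference = refId)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
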