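## In-code fixtures shared across the suite.

## TrajectorySet straight from a depth matrix (fish x time).
makeTraj <- function(depth, rateHz = 1) {
    depth <- rbind(depth)
    new("TrajectorySet", depth = depth, rateHz = rateHz,
        calibration = list(),
        sourceIds = sprintf("fish%02d", seq_len(nrow(depth))),
        flags = matrix(FALSE, nrow(depth), ncol(depth)))
}

## Hand-built schedule from a channel sequence of 60 s epochs.
manualSchedule <- function(channels, dur = 60, irradiance = 600) {
    n <- length(channels)
    new("StimulusSchedule",
        epochs = data.frame(
            start_s = (seq_len(n) - 1L) * dur,
            duration_s = rep(dur, n),
            channel = channels,
            irradiance = ifelse(channels == "dark", 0, irradiance),
            stringsAsFactors = FALSE),
        totalDuration = n * dur, seed = NA_integer_)
}

## Gaussian blob image.
blobMap <- function(dim, center, sigma = 2, peak = 1) {
    peak * outer(exp(-(seq_len(dim[1]) - center[1])^2 / (2 * sigma^2)),
                 exp(-(seq_len(dim[2]) - center[2])^2 / (2 * sigma^2)))
}

## Deterministic noiseless behavior parameters.
noiselessParams <- function(responsiveness = c(blue470 = 1),
                            speed = 0.1)
    behaviorParams(responsiveness = responsiveness, climbSpeed = speed,
                   diveSpeed = speed, speedSd = 0, positionNoiseSd = 0)

## Brute-force Mann-Whitney p over all C(n1+n2, n1) labelings (tie-free).
bruteMannWhitneyP <- function(x, y, tail) {
    n1 <- length(x); n2 <- length(y)
    pooled <- c(x, y)
    r <- rank(pooled)
    UxObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    Uobs <- min(UxObs, n1 * n2 - UxObs)
    labelings <- utils::combn(n1 + n2, n1)
    Uperm <- apply(labelings, 2L, function(idx)
        sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2)
    if (tail == "one") mean(Uperm <= Uobs)
    else mean(pmin(Uperm, n1 * n2 - Uperm) <= Uobs)
}

## One simulated imaging fish run through the decomposition+classification
## chain; returns the classification table and per-source map correlations.
runImagingFish <- function(seed, dim = c(28L, 40L), nPulses = 10L,
                           noiseSd = 0.1, k = 10L, tau = 2, jitterPx = 2L) {
    sch <- makeSchedule("imaging_random", nCycles = nPulses, seed = seed)
    srcs <- defaultSources(dim = dim, jitterPx = jitterPx, seed = seed)
    sim <- simulateCalciumMovie(sch, srcs, dim = dim, rateHz = 1,
                                noiseSd = noiseSd, seed = seed)
    ica <- spatialICA(pcaReduce(sim$movie, k))
    bank <- buildTemplates(sch, rateHz = 1, tau = tau)
    cls <- classifyComponents(ica, bank)
    list(sim = sim, ica = ica, cls = cls,
         centers = attr(srcs, "centers"))
}
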