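#' Epoch-aligned climbing and diving metrics
#'
#' For every fish and every epoch, computes the statistics the behavioral
#' figures are built from. Initial speed is the net displacement over the
#' first 20 s of the epoch divided by 20 s, signed so that movement in the
#' epoch-congruent direction is positive (up during light ON, down during
#' dark). Final position is the mean depth over the epoch's last 20 s.
#' \code{reached_half} records whether the fish crossed the half-column depth
#' (2.5 cm) in the epoch-congruent direction within the epoch, and
#' \code{time_to_half} the first crossing time (s from epoch start, censored
#' at the epoch duration; NA when no crossing).
#'
#' @param traj a \linkS4class{TrajectorySet}.
#' @param schedule the \linkS4class{StimulusSchedule} the trajectories were
#'   recorded under; must match the trajectory duration.
#' @param window analysis window in seconds (default 20).
#' @return data.frame with one row per fish x epoch: \code{fish},
#'   \code{cycle}, \code{direction} ("climb" for lit epochs, "dive" for
#'   dark), \code{epoch_start_s}, \code{initial_speed_cm_s},
#'   \code{final_position_cm}, \code{reached_half}, \code{time_to_half_s}.
#' @examples
#' sch <- makeSchedule("behavior_cycles", nCycles = 2)
#' tr <- simulateTrajectories(behaviorParams(), sch, nFish = 2, seed = 1)
#' head(epochMetrics(tr, sch))
#' @export
epochMetrics <- function(traj, schedule, window = 20) {
    stopifnot(is(traj, "TrajectorySet"), is(schedule, "StimulusSchedule"))
    e <- epochs(schedule)
    if (any(e$duration_s < window))
        stop(sprintf("every epoch must be at least %g s long", window))
    rate <- rateHz(traj)
    d <- depths(traj)
    nT <- ncol(d)
    if (abs(nT / rate - totalDuration(schedule)) > 1 / rate + 1e-9)
        stop("trajectory and schedule durations do not match")
    rows <- vector("list", nrow(e) * nFish(traj))
    ri <- 0L
    dirCount <- c(climb = 0L, dive = 0L)
    for (ei in seq_len(nrow(e))) {
        dirn <- if (e$channel[ei] == "dark") "dive" else "climb"
        dirCount[dirn] <- dirCount[dirn] + 1L
        s0 <- as.integer(round(e$start_s[ei] * rate)) + 1L
        sW <- min(s0 + as.integer(round(window * rate)), nT)
        send <- min(as.integer(round((e$start_s[ei] + e$duration_s[ei]) *
                                     rate)), nT)
        sF <- send - as.integer(round(window * rate)) + 1L
        for (f in seq_len(nFish(traj))) {
            tr <- d[f, s0:send]
            disp <- d[f, s0] - d[f, sW]          # positive = moved up
            speed <- if (dirn == "climb") disp / window else -disp / window
            crossings <- if (dirn == "climb")
                which(tr[-1L] <= .HALF_DEPTH_CM &
                      tr[-length(tr)] > .HALF_DEPTH_CM)
            else
                which(tr[-1L] >= .HALF_DEPTH_CM &
                      tr[-length(tr)] < .HALF_DEPTH_CM)
            reached <- length(crossings) > 0L
            ri <- ri + 1L
            rows[[ri]] <- data.frame(
                fish = sourceIds(traj)[f],
                cycle = dirCount[[dirn]],
                direction = dirn,
                epoch_start_s = e$start_s[ei],
                initial_speed_cm_s = speed,
                final_position_cm = mean(d[f, sF:send]),
                reached_half = reached,
                time_to_half_s = if (reached) crossings[1L] / rate
                                 else NA_real_,
                stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, rows)
}

#' Occurrence rate of half-column crossings
#'
#' Counts, per direction, the fish x cycle events in which the animal reached
#' the halfway point of the water column during a climb or dive.
#'
#' @param metrics data.frame from \code{\link{epochMetrics}}.
#' @return data.frame with columns \code{direction}, \code{occurrences},
#'   \code{total} (fish x cycles for that direction).
#' @examples
#' sch <- makeSchedule("behavior_cycles", nCycles = 2)
#' tr <- simulateTrajectories(behaviorParams(), sch, nFish = 2, seed = 1)
#' occurrenceRate(epochMetrics(tr, sch))
#' @export
occurrenceRate <- function(metrics) {
    if (!is.data.frame(metrics) || nrow(metrics) == 0L)
        stop("'metrics' must be a non-empty epochMetrics data.frame")
    dirs <- unique(metrics$direction)
    data.frame(
        direction = dirs,
        occurrences = vapply(dirs, function(dd)
            sum(metrics$reached_half[metrics$direction == dd]), integer(1L)),
        total = vapply(dirs, function(dd)
            sum(metrics$direction == dd), integer(1L)),
        row.names = NULL, stringsAsFactors = FALSE)
}

#' Pairwise Pearson correlation of depth traces
#'
#' Correlates every pair of fish over the full recording (no detrending).
#' Zero-variance traces cannot be correlated: their rows/columns are NA,
#' excluded from \code{\link{upperTriValues}}, with a warning.
#'
#' @param traj a \linkS4class{TrajectorySet} with at least two fish.
#' @param group optional group label carried into the result.
#' @return A \linkS4class{CorrelationMatrix}.
#' @examples
#' sch <- makeSchedule("behavior_cycles", nCycles = 2)
#' tr <- simulateTrajectories(behaviorParams(), sch, nFish = 4, seed = 1)
#' corMatrix(pairwiseCorrelation(tr))[1:2, 1:2]
#' @export
pairwiseCorrelation <- function(traj, group = "") {
    stopifnot(is(traj, "TrajectorySet"))
    d <- depths(traj)
    if (nrow(d) < 2L) stop("need at least two fish")
    sds <- apply(d, 1L, stats::sd)
    R <- matrix(NA_real_, nrow(d), nrow(d))
    ok <- sds > 0
    if (any(!ok))
        warning(sum(!ok), " zero-variance trace(s) excluded from correlations")
    R[ok, ok] <- stats::cor(t(d[ok, , drop = FALSE]))
    diag(R)[ok] <- 1
    dimnames(R) <- list(sourceIds(traj), sourceIds(traj))
    new("CorrelationMatrix", R = R, nSamples = ncol(d), group = group)
}

#' Upper-triangle correlation sample
#'
#' The off-diagonal upper-triangle values of a correlation matrix, the sample
#' used when groups are compared on their "correlation coefficients"
#' (66 values for 12 fish, 276 for 24).
#'
#' @param cm a \linkS4class{CorrelationMatrix}.
#' @return Numeric vector (NA pairs from excluded traces dropped).
#' @export
upperTriValues <- function(cm) {
    stopifnot(is(cm, "CorrelationMatrix"))
    v <- cm@R[upper.tri(cm@R)]
    v[!is.na(v)]
}

#' Jennrich's chi-square test for equality of two correlation matrices
#'
#' Implements the Jennrich (1970) asymptotic test. With sample sizes n1, n2
#' and correlation matrices R1, R2 of dimension p, let
#' c = n1 n2 / (n1 + n2), Rbar = (n1 R1 + n2 R2) / (n1 + n2),
#' Z = sqrt(c) Rbar^-1 (R1 - R2), and S with entries
#' S_ij = delta_ij + rbar_ij * rbar^ij (rbar^ij the entries of Rbar^-1).
#' Then chi2 = tr(Z^2)/2 - dg(Z)' S^-1 dg(Z) with p(p-1)/2 degrees of
#' freedom.
#'
#' When applied to time-sampled trajectories, n1 and n2 are the number of
#' time samples; temporal autocorrelation violates the test's independence
#' assumption, so \code{decimate} optionally thins the effective sample count
#' (n / decimate) without changing the matrices.
#'
#' @param R1,R2 \linkS4class{CorrelationMatrix} objects or plain correlation
#'   matrices of equal dimension p.
#' @param n1,n2 sample counts (> p). Taken from \code{nSamples()} when
#'   \code{R1}/\code{R2} are \linkS4class{CorrelationMatrix} and not given.
#' @param decimate divide both sample counts by this factor (default 1).
#' @return List with \code{chi2}, \code{df} = p(p-1)/2 and \code{p} (upper
#'   chi-square tail).
#' @references Jennrich, R. I. (1970). An asymptotic chi-square test for the
#'   equality of two correlation matrices. JASA 65, 904-912.
#' @examples
#' R <- diag(3); R[1, 2] <- R[2, 1] <- 0.5
#' jennrichTest(R, diag(3), n1 = 100, n2 = 100)
#' @export
jennrichTest <- function(R1, R2, n1 = NULL, n2 = NULL, decimate = 1) {
    if (is(R1, "CorrelationMatrix")) {
        if (is.null(n1)) n1 <- nSamples(R1)
        R1 <- corMatrix(R1)
    }
    if (is(R2, "CorrelationMatrix")) {
        if (is.null(n2)) n2 <- nSamples(R2)
        R2 <- corMatrix(R2)
    }
    stopifnot(is.matrix(R1), is.matrix(R2))
    if (!identical(dim(R1), dim(R2))) stop("dimension mismatch")
    if (anyNA(R1) || anyNA(R2))
        stop("correlation matrices contain NA (zero-variance traces?)")
    p <- nrow(R1)
    n1 <- n1 / decimate; n2 <- n2 / decimate
    if (n1 <= p || n2 <= p)
        stop("sample counts must exceed the matrix dimension")
    cc <- n1 * n2 / (n1 + n2)
    Rbar <- (n1 * R1 + n2 * R2) / (n1 + n2)
    Ri <- tryCatch(solve(Rbar), error = function(e)
        stop("pooled correlation matrix is singular"))
    Z <- sqrt(cc) * Ri %*% (R1 - R2)
    S <- diag(p) + Rbar * Ri
    dg <- diag(Z)
    chi2 <- max(0, 0.5 * sum(Z * t(Z)) -
                   drop(t(dg) %*% solve(S, dg)))
    df <- p * (p - 1) / 2
    list(chi2 = chi2, df = df,
         p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Mann-Whitney U test with rank-biserial effect size
#'
#' Computes U with midrank tie handling and reports the smaller of the two
#' U statistics. The p-value is exact (from the null U distribution) for
#' tie-free samples with n1 + n2 <= \code{exactMax}, otherwise a normal
#' approximation with tie and continuity corrections is used. One-tailed
#' p-values are for the observed direction. The rank-biserial correlation is
#' reported as a magnitude, |1 - 2U/(n1 n2)|.
#'
#' @param x,y numeric samples (non-empty).
#' @param tail \code{"two"} (default) or \code{"one"}.
#' @param exactMax largest n1 + n2 for which the exact null distribution is
#'   used (default 20).
#' @return List with \code{U} (= min(Ux, Uy)), \code{Ux}, \code{Uy},
#'   \code{n1}, \code{n2}, \code{tail}, \code{p}, \code{rank_biserial} and
#'   \code{method} ("exact" or "normal").
#' @examples
#' mannWhitneyU(c(1, 2), c(3, 4))
#' @export
mannWhitneyU <- function(x, y, tail = c("two", "one"), exactMax = 20L) {
    tail <- match.arg(tail)
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (!length(x) || !length(y)) stop("both samples must be non-empty")
    n1 <- length(x); n2 <- length(y)
    r <- rank(c(x, y))
    Ux <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    Uy <- n1 * n2 - Ux
    U <- min(Ux, Uy)
    ties <- anyDuplicated(c(x, y)) > 0L
    if (!ties && n1 + n2 <= exactMax) {
        method <- "exact"
        pLow <- stats::pwilcox(U, n1, n2)
        p <- if (tail == "one") pLow
             else min(1, pLow + stats::pwilcox(n1 * n2 - U - 1, n1, n2,
                                               lower.tail = FALSE))
    } else {
        method <- "normal"
        N <- n1 + n2
        tj <- table(c(x, y))
        sigma2 <- n1 * n2 / 12 *
            ((N + 1) - sum(tj^3 - tj) / (N * (N - 1)))
        z <- (U - n1 * n2 / 2 + 0.5) / sqrt(sigma2)
        pOne <- stats::pnorm(z)
        p <- if (tail == "one") pOne else min(1, 2 * pOne)
    }
    list(U = U, Ux = Ux, Uy = Uy, n1 = n1, n2 = n2, tail = tail, p = p,
         rank_biserial = rankBiserial(U, n1, n2), method = method)
}

#' Rank-biserial correlation from a U statistic
#'
#' The nonparametric effect size reported alongside Mann-Whitney tests,
#' |1 - 2U/(n1 n2)|, as a magnitude in [0, 1].
#'
#' @param U a Mann-Whitney U statistic.
#' @param n1,n2 group sizes.
#' @return Numeric effect-size magnitude.
#' @examples
#' rankBiserial(28, 12, 12)   # 0.61
#' @export
rankBiserial <- function(U, n1, n2) {
    stopifnot(U >= 0, U <= n1 * n2)
    abs(1 - 2 * U / (n1 * n2))
}

#' Kruskal-Wallis test across groups
#'
#' Tie-corrected Kruskal-Wallis H with k - 1 degrees of freedom and an upper
#' chi-square tail p-value (delegates to \code{stats::kruskal.test}).
#'
#' @param groups list of two or more non-empty numeric samples.
#' @return List with \code{H}, \code{df}, \code{p}.
#' @examples
#' kruskalWallisTest(list(c(1, 2), c(3, 4), c(5, 6)))
#' @export
kruskalWallisTest <- function(groups) {
    if (!is.list(groups) || length(groups) < 2L)
        stop("need at least two groups")
    if (any(vapply(groups, length, integer(1L)) == 0L))
        stop("groups must be non-empty")
    kt <- stats::kruskal.test(groups)
    list(H = unname(kt$statistic), df = unname(kt$parameter),
         p = kt$p.value)
}

#' Bonferroni-corrected significance level
#'
#' alpha / n, reported at 4 decimals (e.g. 0.05 over three hypotheses gives
#' 0.0167).
#'
#' @param alpha family-wise level in (0, 1).
#' @param n number of hypotheses (>= 1).
#' @return Corrected per-hypothesis level, rounded to 4 decimals.
#' @examples
#' bonferroniAlpha(0.05, 3)
#' @export
bonferroniAlpha <- function(alpha, n) {
    if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
        stop("'n' must be a positive integer")
    if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
        stop("'alpha' must lie in (0, 1)")
    round(alpha / n, 4)
}

#' Photon intensity from power density and wavelength
#'
#' Converts an irradiance P/A (uW/cm^2) at wavelength lambda (nm) into a
#' photon flux density I = (P/A) / E with E = h c / lambda the single-photon
#' energy (CODATA h and c). This is the quantity matched across wavelengths
#' in the assay.
#'
#' @param powerDensity irradiance in uW/cm^2 (> 0).
#' @param wavelength wavelength in nm (> 0).
#' @return Photon intensity in photons cm^-2 s^-1.
#' @examples
#' photonIntensity(650, 470)   # ~1.54e15
#' @export
photonIntensity <- function(powerDensity, wavelength) {
    if (any(powerDensity <= 0) || any(wavelength <= 0))
        stop("inputs must be positive")
    h <- 6.62607015e-34   # J s
    cl <- 2.99792458e8    # m/s
    E <- h * cl / (wavelength * 1e-9)
    (powerDensity * 1e-6) / E
}

#' Per-timepoint mean and confidence band across fish
#'
#' The t-based interval mean +/- t_{1-(1-c)/2, n-1} * sd / sqrt(n) at every
#' time point, the band drawn as a shadow around group-average traces.
#'
#' @param traj a \linkS4class{TrajectorySet} with at least two fish.
#' @param confidence confidence level in [0, 1) (default 0.95; 0 gives a
#'   degenerate band equal to the mean).
#' @return data.frame with \code{time_s}, \code{mean_cm}, \code{halfwidth_cm}.
#' @examples
#' sch <- makeSchedule("behavior_cycles", nCycles = 1)
#' tr <- simulateTrajectories(behaviorParams(), sch, nFish = 4, rateHz = 1)
#' head(meanCIBand(tr))
#' @export
meanCIBand <- function(traj, confidence = 0.95) {
    stopifnot(is(traj, "TrajectorySet"))
    d <- depths(traj)
    n <- nrow(d)
    if (n < 2L) stop("need at least two fish for a confidence band")
    if (confidence < 0 || confidence >= 1)
        stop("'confidence' must lie in [0, 1)")
    tcrit <- stats::qt(1 - (1 - confidence) / 2, df = n - 1L)
    data.frame(time_s = (seq_len(ncol(d)) - 1L) / rateHz(traj),
               mean_cm = colMeans(d),
               halfwidth_cm = tcrit * apply(d, 2L, stats::sd) / sqrt(n))
}

#' Shapiro-Wilk normality check
#'
#' Used to justify nonparametric tests in the reports; requires
#' 3 <= n <= 5000 and a non-constant sample.
#'
#' @param x numeric sample.
#' @return List with \code{W} and \code{p}.
#' @examples
#' normalityCheck(rnorm(30))
#' @export
normalityCheck <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 3L || length(x) > 5000L)
        stop("sample size must lie in [3, 5000]")
    if (stats::sd(x) == 0) stop("sample has zero variance")
    st <- stats::shapiro.test(x)
    list(W = unname(st$statistic), p = st$p.value)
}
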