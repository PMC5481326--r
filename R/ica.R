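#' PCA reduction of a calcium movie
#'
#' Factors the mean-subtracted pixel-time matrix of a T x Y x X movie into
#' its top-k principal components. The eigen-decomposition runs on the
#' smaller Gram matrix, so movies with many pixels and few frames (or vice
#' versa) stay cheap. Component signs are fixed deterministically by the
#' positive-skew rule on the spatial loadings (falling back to the largest
#' loading element when skewness vanishes).
#'
#' @param movie T x Y x X numeric array (finite values).
#' @param k number of components to retain; must not exceed the matrix rank.
#' @return A \linkS4class{PCAReduction}: temporal \code{scores} (T x k),
#'   orthonormal spatial \code{loadings} (P x k), per-component
#'   \code{varianceExplained}, the removed per-pixel \code{center} and
#'   \code{movieDim}.
#' @examples
#' sch <- makeSchedule("imaging_random", nCycles = 2, seed = 3)
#' sim <- simulateCalciumMovie(sch, defaultSources(dim = c(20, 30))[1:2],
#'                             dim = c(20, 30), noiseSd = 0.05)
#' varianceExplained(pcaReduce(sim$movie, 2))
#' @export
pcaReduce <- function(movie, k) {
    stopifnot(is.array(movie), length(dim(movie)) == 3L)
    if (any(!is.finite(movie))) stop("movie must be finite-valued")
    dm <- dim(movie)
    nT <- dm[1L]; P <- dm[2L] * dm[3L]
    if (k < 1L || k > min(nT, P))
        stop("'k' must lie in [1, min(T, Y*X)]")
    X <- matrix(movie, nT, P)
    ctr <- colMeans(X)
    X <- sweep(X, 2L, ctr)
    totVar <- sum(X^2)
    if (totVar <= 0) stop("movie has zero variance")
    if (nT <= P) {
        G <- tcrossprod(X)                   # T x T
        eg <- eigen(G, symmetric = TRUE)
        d2 <- pmax(eg$values, 0)
        rank <- sum(d2 > max(d2) * 1e-10)
        if (k > rank) stop(sprintf("'k' exceeds the movie rank (%d)", rank))
        d <- sqrt(d2[seq_len(k)])
        U <- eg$vectors[, seq_len(k), drop = FALSE]
        V <- crossprod(X, U) %*% diag(1 / d, k)
    } else {
        G <- crossprod(X)                    # P x P
        eg <- eigen(G, symmetric = TRUE)
        d2 <- pmax(eg$values, 0)
        rank <- sum(d2 > max(d2) * 1e-10)
        if (k > rank) stop(sprintf("'k' exceeds the movie rank (%d)", rank))
        d <- sqrt(d2[seq_len(k)])
        V <- eg$vectors[, seq_len(k), drop = FALSE]
        U <- X %*% V %*% diag(1 / d, k)
    }
    ## deterministic sign: positive skew of the spatial loading
    for (j in seq_len(k)) {
        sk <- .skewness(V[, j])
        s <- if (abs(sk) > 1e-12) sign(sk)
             else sign(V[which.max(abs(V[, j])), j])
        if (s < 0) { V[, j] <- -V[, j]; U[, j] <- -U[, j] }
    }
    new("PCAReduction",
        scores = U %*% diag(d, k),
        loadings = V,
        varianceExplained = d^2 / totVar,
        center = ctr,
        movieDim = as.integer(dm[2:3]))
}

.skewness <- function(x) {
    x <- x - mean(x)
    s2 <- mean(x^2)
    if (s2 <= 0) return(0)
    mean(x^3) / s2^1.5
}

#' Fixed-point skewness-contrast ICA on a PCA-reduced movie
#'
#' Rotates the whitened principal components to maximise the skewness
#' (third-moment non-Gaussianity, appropriate for positively skewed calcium
#' signals) of a mu-weighted concatenation of the spatial and temporal views:
#' mu = 0 is purely spatial ICA, mu = 1 purely temporal. The fixed-point
#' iteration with symmetric decorrelation starts from the identity rotation,
#' so results are deterministic; an optional seed switches to a random
#' orthogonal start. Components are ordered by decreasing temporal-signal
#' skewness and sign-oriented so each temporal signal has positive skewness.
#'
#' @param pca a \linkS4class{PCAReduction}.
#' @param nComponents number of independent components (defaults to the
#'   number of retained PCs).
#' @param mu spatiotemporal weight in [0, 1] (default 0, purely spatial).
#' @param maxIter,tol fixed-point iteration controls.
#' @param seed optional seed for a random orthogonal initialisation; NULL
#'   (default) uses the deterministic identity start.
#' @return An \linkS4class{ICADecomposition}. Non-convergence is reported
#'   with a warning and flagged in the object; the best iterate is returned.
#' @examples
#' sch <- makeSchedule("imaging_random", nCycles = 2, seed = 3)
#' sim <- simulateCalciumMovie(sch, defaultSources(dim = c(20, 30))[1:2],
#'                             dim = c(20, 30), noiseSd = 0)
#' ica <- spatialICA(pcaReduce(sim$movie, 2))
#' ica
#' @export
spatialICA <- function(pca, nComponents = NULL, mu = 0,
                       maxIter = 500L, tol = 1e-8, seed = NULL) {
    stopifnot(is(pca, "PCAReduction"))
    k <- ncol(pca@loadings)
    if (is.null(nComponents)) nComponents <- k
    if (nComponents > k) stop("'nComponents' exceeds the retained PCs")
    if (mu < 0 || mu > 1) stop("'mu' must lie in [0, 1]")
    n <- as.integer(nComponents)
    V <- pca@loadings[, seq_len(n), drop = FALSE]          # P x n, orthonormal
    d <- sqrt(colSums(pca@scores[, seq_len(n), drop = FALSE]^2))
    Uw <- sweep(pca@scores[, seq_len(n), drop = FALSE], 2L, d, "/")  # T x n
    ## whitened mu-weighted concatenation; columns orthonormal
    Z <- rbind(sqrt(1 - mu) * V, sqrt(mu) * Uw)            # (P+T) x n
    m <- nrow(Z)
    W <- if (is.null(seed)) diag(n)
         else .withSeed(seed, {
             A <- matrix(stats::rnorm(n * n), n, n)
             qr.Q(qr(A))
         })
    symOrth <- function(M) {
        e <- eigen(tcrossprod(M), symmetric = TRUE)
        vals <- pmax(e$values, .Machine$double.eps)
        e$vectors %*% diag(1 / sqrt(vals), n) %*% t(e$vectors) %*% M
    }
    converged <- FALSE
    it <- 0L
    while (it < maxIter) {
        it <- it + 1L
        Y <- Z %*% t(W)                                    # m x n sources
        Wnew <- t(crossprod(Y^2, Z)) / m                   # n x n: E[z (w'z)^2]
        Wnew <- symOrth(t(Wnew))
        delta <- max(abs(1 - abs(rowSums(Wnew * W))))
        W <- Wnew
        if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged)
        warning("ICA did not converge within ", maxIter,
                " iterations; returning the best iterate")
    ## back-project the unmixing onto pixels and frames
    maps <- W %*% t(V)                                     # n x P
    sigs <- W %*% t(pca@scores[, seq_len(n), drop = FALSE])  # n x T
    ## orient by temporal skewness, order by decreasing skewness
    sk <- apply(sigs, 1L, .skewness)
    flip <- ifelse(sk < 0, -1, 1)
    maps <- maps * flip
    sigs <- sigs * flip
    sk <- abs(sk)
    ord <- order(sk, decreasing = TRUE)
    new("ICADecomposition",
        spatialMaps = maps[ord, , drop = FALSE],
        temporalSignals = sigs[ord, , drop = FALSE],
        retainedPCs = as.integer(k),
        varianceExplained = pca@varianceExplained,
        mu = mu,
        converged = converged,
        iterations = it,
        movieDim = pca@movieDim)
}

#' Segment ROIs from ICA spatial maps
#'
#' Thresholds each sign-oriented spatial map at mean + \code{zThreshold} x SD
#' of that map; connected components of at least \code{minPixels} pixels
#' become ROIs labelled with the component they came from. Pixels already
#' claimed by an earlier (higher-skewness) component are not relabelled, so
#' ROI pixel sets are disjoint.
#'
#' @param decomp an \linkS4class{ICADecomposition}.
#' @param zThreshold threshold in map-SD units (default 2).
#' @param minPixels minimum ROI area in pixels (default 10).
#' @return An \linkS4class{ROISet}; empty (with a warning) when no pixel
#'   passes threshold in any map.
#' @examples
#' sch <- makeSchedule("imaging_random", nCycles = 2, seed = 3)
#' sim <- simulateCalciumMovie(sch, defaultSources(dim = c(20, 30))[1:2],
#'                             dim = c(20, 30), noiseSd = 0)
#' rois <- segmentROIs(spatialICA(pcaReduce(sim$movie, 2)))
#' length(rois)
#' @export
segmentROIs <- function(decomp, zThreshold = 2, minPixels = 10L) {
    stopifnot(is(decomp, "ICADecomposition"))
    dm <- decomp@movieDim
    lab <- matrix(0L, dm[1L], dm[2L])
    pix <- list()
    prov <- integer(0L)
    nextLab <- 0L
    for (i in seq_len(nrow(decomp@spatialMaps))) {
        mp <- matrix(decomp@spatialMaps[i, ], dm[1L], dm[2L])
        thr <- mean(mp) + zThreshold * stats::sd(mp)
        bw <- mp > thr
        if (!any(bw)) next
        cc <- EBImage::bwlabel(bw)
        for (l in seq_len(max(cc))) {
            idx <- which(cc == l & lab == 0L)
            if (length(idx) >= minPixels) {
                nextLab <- nextLab + 1L
                lab[idx] <- nextLab
                pix[[nextLab]] <- idx
                prov <- c(prov, i)
            }
        }
    }
    if (nextLab == 0L)
        warning("no ROI passed the threshold; returning an empty ROISet")
    new("ROISet", labelImage = lab, pixels = pix, provenance = prov)
}

#' Z-scored ROI traces
#'
#' Averages the movie over each ROI's pixels per frame, then z-scores each
#' trace over the full recording. Zero-variance traces are returned all-zero
#' with a warning.
#'
#' @param movie T x Y x X array (same field as the ROISet).
#' @param rois an \linkS4class{ROISet}.
#' @return k x T numeric matrix of z-scored traces (k = number of ROIs).
#' @examples
#' sch <- makeSchedule("imaging_random", nCycles = 2, seed = 3)
#' sim <- simulateCalciumMovie(sch, defaultSources(dim = c(20, 30))[1:2],
#'                             dim = c(20, 30), noiseSd = 0)
#' rois <- segmentROIs(spatialICA(pcaReduce(sim$movie, 2)))
#' dim(roiTraces(sim$movie, rois))
#' @export
roiTraces <- function(movie, rois) {
    stopifnot(is.array(movie), length(dim(movie)) == 3L, is(rois, "ROISet"))
    dm <- dim(movie)
    P <- dm[2L] * dm[3L]
    if (length(rois@pixels) &&
        max(unlist(rois@pixels)) > P)
        stop("ROI pixels fall outside the movie frame")
    X <- matrix(movie, dm[1L], P)
    out <- matrix(0, length(rois@pixels), dm[1L])
    for (i in seq_along(rois@pixels)) {
        tr <- rowMeans(X[, rois@pixels[[i]], drop = FALSE])
        s <- stats::sd(tr)
        if (s == 0) {
            warning("ROI ", i, " has a zero-variance trace; returning zeros")
            out[i, ] <- 0
        } else out[i, ] <- (tr - mean(tr)) / s
    }
    out
}
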