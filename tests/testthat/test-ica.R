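test_that("PCA variance fractions reflect constructed source power", {
    ## rank-1 movie: a single source explains everything
    resp <- c(rep(0, 20), rep(1, 20), rep(0, 20))
    fp <- blobMap(c(12, 12), c(6, 6), 1.5)
    m1 <- array(outer(resp, fp), c(60, 12, 12)) + 1
    p1 <- pcaReduce(m1, 1)
    expect_equal(varianceExplained(p1)[1], 1, tolerance = 1e-10)
    expect_error(pcaReduce(m1, 2), "rank")

    ## two orthogonal equal-power sources split variance evenly
    t1 <- sin(2 * pi * (1:200) / 20); t2 <- cos(2 * pi * (1:200) / 20)
    f1 <- matrix(0, 10, 20); f1[3:5, 3:5] <- 1
    f2 <- matrix(0, 10, 20); f2[7:9, 14:16] <- 1
    m2 <- array(outer(t1, f1) + outer(t2, f2), c(200, 10, 20))
    ve <- varianceExplained(pcaReduce(m2, 2))
    expect_equal(ve, c(0.5, 0.5), tolerance = 0.02)

    expect_error(pcaReduce(array(3, c(10, 5, 5)), 1), "zero variance")
})

test_that("retained PCs reconstruct the movie to within numerical tolerance", {
    set.seed(5)
    m <- array(rnorm(40 * 6 * 8), c(40, 6, 8))
    pr <- pcaReduce(m, 39)     # centering costs one rank: T - 1 components
    X <- matrix(m, 40, 48)
    Xc <- sweep(X, 2, colMeans(X))
    recon <- pr@scores %*% t(pr@loadings)
    expect_lt(max(abs(recon - Xc)), 1e-8)
    expect_equal(sum(varianceExplained(pr)), 1, tolerance = 1e-10)
    ## truncation leaves exactly the unexplained variance behind
    pr5 <- pcaReduce(m, 5)
    resid <- Xc - pr5@scores %*% t(pr5@loadings)
    expect_equal(sum(resid^2) / sum(Xc^2),
                 1 - sum(varianceExplained(pr5)), tolerance = 1e-10)
})

test_that("spatial ICA separates planted sources and is deterministic", {
    sch <- makeSchedule("imaging_random", nCycles = 4, seed = 2)
    srcs <- defaultSources(dim = c(20, 30), sigma = 1.8)[c(1, 2)]
    sim <- simulateCalciumMovie(sch, srcs, dim = c(20, 30), rateHz = 1,
                                noiseSd = 0)
    ica <- spatialICA(pcaReduce(sim$movie, 2))
    expect_true(ica@converged)
    fp <- vapply(sim$footprints, as.vector, numeric(600))
    cors <- abs(stats::cor(t(spatialMaps(ica)), fp))
    ## each footprint matched by some component, up to permutation/sign
    expect_true(all(apply(cors, 2, max) > 0.99))
    ## temporal signals are zero-mean
    expect_lt(max(abs(rowMeans(temporalSignals(ica)))), 1e-8)
    ## bit-identical rerun
    ica2 <- spatialICA(pcaReduce(sim$movie, 2))
    expect_identical(spatialMaps(ica), spatialMaps(ica2))
})

test_that("a single source dominates its decomposition", {
    sch <- makeSchedule("imaging_random", nCycles = 4, seed = 3)
    srcs <- defaultSources(dim = c(20, 30), sigma = 1.8)[1]
    sim <- simulateCalciumMovie(sch, srcs, dim = c(20, 30), rateHz = 1,
                                noiseSd = 0.05, seed = 8)
    ica <- spatialICA(pcaReduce(sim$movie, 4))
    ## the leading (most skewed) component carries the planted source; the
    ## rest are noise
    expect_gt(abs(stats::cor(temporalSignals(ica)[1, ],
                             sim$responses[1, ])), 0.95)
    expect_gt(abs(stats::cor(spatialMaps(ica)[1, ],
                             as.vector(sim$footprints[[1]]))), 0.95)
})

test_that("the decomposition is invariant to whole-movie translation", {
    sch <- makeSchedule("imaging_random", nCycles = 4, seed = 4)
    srcs <- defaultSources(dim = c(24, 30), sigma = 1.8)[c(1, 3)]
    sim <- simulateCalciumMovie(sch, srcs, dim = c(24, 30), rateHz = 1,
                                noiseSd = 0)
    shifted <- array(0, dim(sim$movie))
    shifted[, 3:24, 4:30] <- sim$movie[, 1:22, 1:27]
    icaA <- spatialICA(pcaReduce(sim$movie, 2))
    icaB <- spatialICA(pcaReduce(shifted, 2))
    for (i in 1:2) {
        mA <- matrix(spatialMaps(icaA)[i, ], 24, 30)
        mAs <- matrix(0, 24, 30); mAs[3:24, 4:30] <- mA[1:22, 1:27]
        best <- max(abs(stats::cor(as.vector(mAs),
                                   t(spatialMaps(icaB)))))
        expect_gt(best, 0.99)
    }
})

test_that("ROI segmentation thresholds maps into labelled components", {
    dm <- c(30L, 30L)
    blob <- blobMap(dm, c(10, 10), 2)
    dec <- function(maps) new("ICADecomposition",
        spatialMaps = maps, temporalSignals = matrix(0, nrow(maps), 5),
        retainedPCs = nrow(maps), varianceExplained = numeric(0),
        mu = 0, converged = TRUE, iterations = 1L, movieDim = dm)
    one <- segmentROIs(dec(rbind(as.vector(blob))), zThreshold = 2,
                       minPixels = 4)
    expect_equal(length(one), 1L)
    expect_true(all(roiPixels(one)[[1]] %in% which(blob > 0.2)))
    ## two disjoint blobs in one map: two ROIs, same provenance
    two <- segmentROIs(dec(rbind(as.vector(
        blobMap(dm, c(8, 8), 2) + blobMap(dm, c(22, 22), 2)))),
        zThreshold = 2, minPixels = 4)
    expect_equal(length(two), 2L)
    expect_equal(provenance(two), c(1L, 1L))
    ## pure-noise maps yield no ROI at the default threshold
    empties <- vapply(1:20, function(s) {
        set.seed(s)
        d <- dec(rbind(rnorm(prod(dm))))
        length(suppressWarnings(segmentROIs(d)))
    }, integer(1))
    expect_gte(mean(empties == 0L), 0.95)
})

test_that("ROI traces are spatially averaged and z-scored", {
    sch <- makeSchedule("imaging_random", nCycles = 4, seed = 6)
    srcs <- defaultSources(dim = c(20, 30), sigma = 1.8)[1]
    sim <- simulateCalciumMovie(sch, srcs, dim = c(20, 30), rateHz = 1,
                                noiseSd = 0.05, seed = 2)
    ica <- spatialICA(pcaReduce(sim$movie, 3))
    rois <- segmentROIs(ica, minPixels = 4)
    tra <- roiTraces(sim$movie, rois)
    expect_equal(dim(tra)[2], dim(sim$movie)[1])
    expect_equal(rowMeans(tra), rep(0, nrow(tra)), tolerance = 1e-10)
    ## the planted-source ROI trace matches its ICA temporal signal
    i <- provenance(rois)[1]
    expect_gt(abs(stats::cor(tra[1, ], temporalSignals(ica)[i, ])), 0.9)

    ## single-pixel ROI equals that pixel's z-scored series
    rs <- new("ROISet", labelImage = matrix(0L, 20, 30),
              pixels = list(7L), provenance = 1L)
    px <- sim$movie[, 7, 1]
    expect_equal(roiTraces(sim$movie, rs)[1, ],
                 (px - mean(px)) / stats::sd(px))
    ## constant movies warn and return zeros
    flat <- array(1, c(10, 20, 30))
    expect_warning(z <- roiTraces(flat, rs), "zero-variance")
    expect_equal(z[1, ], rep(0, 10))
})
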