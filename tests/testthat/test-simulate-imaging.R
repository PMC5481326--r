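test_that("a sustained blue source is elevated exactly during blue epochs", {
    sch <- manualSchedule(c("dark", "blue470", "dark", "red660"))
    src <- plantedSource(responseClass = "blue_onset_sustained",
                         amplitude = 2, center = c(10, 12), sigma = 2,
                         dim = c(20, 24))
    sim <- simulateCalciumMovie(sch, list(src), dim = c(20, 24), rateHz = 1,
                                noiseSd = 0, baseline = 1)
    px <- sim$movie[, 10, 12]        # footprint center
    fp <- src@footprint[10, 12]
    ## plateau after the kernel rise, baseline in dark (allowing decay tail)
    expect_equal(px[65:120], rep(1 + 2 * fp, 56), tolerance = 0.02)
    expect_equal(px[1:60], rep(1, 60), tolerance = 1e-8)
    expect_equal(px[130:180], rep(1, 51), tolerance = 0.02)
    expect_equal(px[190:240], rep(1, 51), tolerance = 0.02)  # red epoch
})

test_that("mixed-onset sources spike at every ON edge of both colors", {
    sch <- manualSchedule(c("dark", "blue470", "dark", "red660"))
    src <- plantedSource(responseClass = "mixed_onset_transient",
                         amplitude = 1, center = c(8, 8), sigma = 2,
                         dim = c(16, 16))
    sim <- simulateCalciumMovie(sch, list(src), dim = c(16, 16), rateHz = 1,
                                noiseSd = 0)
    px <- sim$movie[, 8, 8] - 1
    fp <- src@footprint[8, 8]
    onsets <- c(61, 181)             # frames of the blue and red onsets
    expect_equal(px[onsets], rep(fp, 2), tolerance = 1e-6)
    ## decays away within a few frames; silent in the sustained phase
    expect_lt(max(px[onsets + 5]), 0.02 * fp)
    expect_lt(max(abs(px[100:160])), 0.02 * fp)
    ## no response at offsets
    expect_lt(max(abs(px[c(125, 130)])), 0.02 * fp)
})

test_that("noiseless movies equal the analytic superposition of sources", {
    sch <- makeSchedule("imaging_random", nCycles = 2, seed = 9)
    srcs <- defaultSources(dim = c(20, 30), sigma = 1.5)[c(1, 3, 5)]
    sim <- simulateCalciumMovie(sch, srcs, dim = c(20, 30), rateHz = 1,
                                noiseSd = 0, baseline = 0.5)
    expected <- array(0.5, dim(sim$movie))
    for (i in seq_along(srcs))
        expected <- expected + outer(sim$responses[i, ],
                                     srcs[[i]]@footprint)
    expect_equal(max(abs(sim$movie - expected)), 0)
})

test_that("movie generation is seed-deterministic and validates inputs", {
    sch <- makeSchedule("imaging_random", nCycles = 2, seed = 1)
    srcs <- defaultSources(dim = c(16, 20), sigma = 1.5)[1:2]
    a <- simulateCalciumMovie(sch, srcs, dim = c(16, 20), seed = 5)
    b <- simulateCalciumMovie(sch, srcs, dim = c(16, 20), seed = 5)
    expect_identical(a$movie, b$movie)
    expect_false(identical(
        a$movie, simulateCalciumMovie(sch, srcs, dim = c(16, 20),
                                      seed = 6)$movie))
    ## ground truth masks label every source's support
    expect_setequal(unique(as.vector(a$masks)), c(0L, 1L, 2L))
    expect_error(simulateCalciumMovie(sch, srcs, dim = c(8, 8)), "shape")
    expect_warning(
        simulateCalciumMovie(sch, c(srcs[1], srcs[1]), dim = c(16, 20)),
        "identical")
    expect_error(plantedSource(responseClass = "nope", center = c(3, 3),
                               dim = c(8, 8)), "responseClass")
    expect_error(plantedSource(responseClass = "red_onset", amplitude = -1,
                               center = c(3, 3), dim = c(8, 8)), "positive")
})
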