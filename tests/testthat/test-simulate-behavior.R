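test_that("noiseless responders follow exact drift kinematics with clipping", {
    sch <- makeSchedule("behavior_cycles", nCycles = 1)
    tr <- simulateTrajectories(noiselessParams(), sch, nFish = 1, rateHz = 5,
                               seed = 1, startDepth = 4.5)
    d <- depths(tr)[1, ]
    ## dark epoch: dives 0.1 cm/s from 4.5, clipped at the bottom (5.0)
    expect_equal(d[1], 4.5)
    expect_equal(d[26], 4.5 + 0.1 * 5)      # t = 5 s
    expect_equal(d[301], 5.0)               # t = 60 s, clipped
    ## ON epoch: climbs 0.1 cm/s; would fall 6.0 cm but clips at 0
    expect_equal(d[401], 5.0 - 0.1 * 20)    # t = 80 s
    expect_equal(d[600], 0)                 # near the end of the ON epoch
    expect_true(all(d >= 0 & d <= chamberHeight()))
})

test_that("trajectory matrices have the assay's shape and are reproducible", {
    sch <- makeSchedule("behavior_cycles", nCycles = 10)
    tr1 <- simulateTrajectories(behaviorParams(), sch, nFish = 12,
                                rateHz = 5, seed = 11)
    expect_equal(dim(depths(tr1)), c(12L, 6000L))
    tr2 <- simulateTrajectories(behaviorParams(), sch, nFish = 12,
                                rateHz = 5, seed = 11)
    expect_identical(depths(tr1), depths(tr2))
    tr3 <- simulateTrajectories(behaviorParams(), sch, nFish = 12,
                                rateHz = 5, seed = 12)
    expect_false(identical(depths(tr1), depths(tr3)))
    ## depths always inside the chamber
    for (s in 1:5) {
        d <- depths(simulateTrajectories(behaviorParams(), sch, 3, 5, s))
        expect_true(all(d >= 0 & d <= chamberHeight()))
    }
})

test_that("non-responders are independent of the light channel", {
    schRed <- makeSchedule("behavior_cycles", nCycles = 2, channel = "red660")
    schBlue <- makeSchedule("behavior_cycles", nCycles = 2)
    p0 <- behaviorParams(responsiveness = c(red660 = 0, blue470 = 0),
                         positionNoiseSd = 0.1)
    tA <- simulateTrajectories(p0, schRed, nFish = 4, rateHz = 5, seed = 5)
    tB <- simulateTrajectories(p0, schBlue, nFish = 4, rateHz = 5, seed = 5)
    expect_identical(depths(tA), depths(tB))
})

test_that("non-responder per-epoch displacement matches the random-walk law", {
    ## E|X| for X ~ N(0, sigma^2 * T) is sigma * sqrt(T) * sqrt(2/pi);
    ## small sigma keeps the walk far from the boundaries
    sigma <- 0.05
    sch <- makeSchedule("behavior_cycles", nCycles = 1)
    p <- behaviorParams(responsiveness = c(blue470 = 0),
                        positionNoiseSd = sigma)
    tr <- simulateTrajectories(p, sch, nFish = 400, rateHz = 5, seed = 7,
                               startDepth = 2.5)
    d <- depths(tr)
    disp <- abs(cbind(d[, 300] - d[, 1], d[, 600] - d[, 300]))
    expected <- sigma * sqrt(60) * sqrt(2 / pi)
    expect_lt(abs(mean(disp) - expected) / expected, 0.1)
})

test_that("simulator rejects invalid inputs", {
    sch <- makeSchedule("behavior_cycles", nCycles = 1)
    expect_error(simulateTrajectories(behaviorParams(), sch, 0, 5), "positive")
    expect_error(simulateTrajectories(behaviorParams(), sch, 2, -1),
                 "positive")
    expect_error(behaviorParams(responsiveness = c(dark = 0.3)), "dark")
    expect_error(behaviorParams(responsiveness = c(blue470 = 1.4)), "0, 1")
})
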