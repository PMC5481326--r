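test_that("epoch metrics recover linear kinematics and crossings exactly", {
    sch <- manualSchedule(c("dark", "blue470"))
    ## dive epoch: 2.4 -> 4.4 cm over 20 s (0.1 cm/s), then hold; the climb
    ## epoch is flat
    d <- c(2.4 + 0.1 * 0:20, rep(4.4, 39), rep(4.4, 60))
    m <- epochMetrics(makeTraj(d, rateHz = 1), sch)
    dive <- m[m$direction == "dive", ]
    climb <- m[m$direction == "climb", ]
    expect_equal(dive$initial_speed_cm_s, 0.1)
    expect_equal(dive$final_position_cm, 4.4)
    expect_true(dive$reached_half)
    expect_equal(dive$time_to_half_s, 1)     # crosses 2.5 cm at t = 1 s
    expect_equal(climb$initial_speed_cm_s, 0)
    expect_false(climb$reached_half)
    expect_true(is.na(climb$time_to_half_s))

    ## constant depth: all zeros, nothing reached
    mc <- epochMetrics(makeTraj(rep(3, 120), rateHz = 1), sch)
    expect_true(all(mc$initial_speed_cm_s == 0))
    expect_true(all(!mc$reached_half))

    expect_error(epochMetrics(makeTraj(rep(3, 120), rateHz = 1),
                              manualSchedule("blue470", dur = 10)),
                 "20")
    expect_error(epochMetrics(makeTraj(rep(3, 50), rateHz = 1), sch),
                 "duration")
})

test_that("occurrence rates count fish-by-cycle events per direction", {
    sch <- makeSchedule("behavior_cycles", nCycles = 10)
    tr <- simulateTrajectories(noiselessParams(speed = 0.2), sch, nFish = 12,
                               rateHz = 5, seed = 1, startDepth = 4.8)
    occ <- occurrenceRate(epochMetrics(tr, sch))
    expect_equal(occ$total, c(120L, 120L))   # 12 fish x 10 cycles, both dirs
    ## every responder crosses on every climb; dives cross from cycle 2 on
    expect_equal(occ$occurrences[occ$direction == "climb"], 120L)
    expect_equal(occ$occurrences[occ$direction == "dive"], 108L)

    ## a toy metrics table with exactly 72 crossings out of 120
    toy <- data.frame(direction = "climb",
                      reached_half = rep(c(TRUE, FALSE), c(72, 48)))
    occ72 <- occurrenceRate(toy)
    expect_equal(occ72$occurrences, 72L)
    expect_equal(occ72$total, 120L)
    expect_error(occurrenceRate(toy[0, ]), "non-empty")
})

test_that("pairwise correlations behave at the exact limits", {
    base <- 2.5 + 1.5 * sin(seq(0, 6 * pi, length.out = 200))
    same <- makeTraj(rbind(base, base))
    expect_equal(corMatrix(pairwiseCorrelation(same))[1, 2], 1)
    ## mirror about mid-depth
    anti <- makeTraj(rbind(base, 5 - base))
    expect_equal(corMatrix(pairwiseCorrelation(anti))[1, 2], -1)
    ## zero-variance trace excluded with warning
    flat <- makeTraj(rbind(base, rep(2.5, 200)))
    expect_warning(cm <- pairwiseCorrelation(flat), "zero-variance")
    expect_true(is.na(corMatrix(cm)[1, 2]))
    expect_length(upperTriValues(cm), 0L)
})

test_that("shared-drive responders show the closed-form synchrony", {
    ## depth_i = mid + a*(s_t + n_it) with shared s and private n of equal
    ## variance: expected pairwise r = 1/2
    set.seed(42)
    Tn <- 3000; nF <- 12
    s <- rnorm(Tn)
    d <- t(replicate(nF, 2.5 + 0.4 * (s + rnorm(Tn)) / 3))
    d <- pmin(pmax(d, 0), 5)
    cm <- pairwiseCorrelation(makeTraj(d))
    expect_equal(median(upperTriValues(cm)), 0.5, tolerance = 0.05)
})

test_that("confidence bands match the closed-form t interval", {
    ## 12 fish at equispaced constant depths: halfwidth = t * sd / sqrt(n);
    ## for depths k/2.4 (k = 1..12) this is 2.290858 / 2.4 (closed form)
    d <- matrix(rep(1:12 / 2.4, 10), nrow = 12)
    band <- meanCIBand(makeTraj(d), 0.95)
    expect_equal(band$mean_cm, rep(6.5 / 2.4, 10))
    expect_equal(band$halfwidth_cm, rep(2.290858 / 2.4, 10),
                 tolerance = 1e-6)
    ## identical traces: zero width; confidence 0: degenerate band
    same <- makeTraj(matrix(2, 3, 10))
    expect_equal(meanCIBand(same, 0.95)$halfwidth_cm, rep(0, 10))
    expect_equal(meanCIBand(makeTraj(d), 0)$halfwidth_cm, rep(0, 10))
    expect_error(meanCIBand(makeTraj(rep(1, 10))), "two fish")
})

test_that("Bonferroni correction reproduces the printed levels", {
    expect_equal(bonferroniAlpha(0.05, 3), 0.0167)
    expect_equal(bonferroniAlpha(0.05, 1), 0.05)
    expect_equal(bonferroniAlpha(0.01, 4), 0.0025)
    expect_error(bonferroniAlpha(0.05, 0), "positive")
})

test_that("photon intensity follows I = (P/A)/(hc/lambda)", {
    ## frozen values from direct evaluation with CODATA constants
    expect_equal(photonIntensity(650, 470), 1.5379e15, tolerance = 1e-4)
    expect_equal(photonIntensity(580, 525), 1.5329e15, tolerance = 1e-4)
    expect_equal(photonIntensity(465, 660), 1.5450e15, tolerance = 1e-4)
    ## exact linearity and the inverse identity I * E = P/A
    expect_equal(photonIntensity(1300, 470), 2 * photonIntensity(650, 470))
    h <- 6.62607015e-34; cl <- 2.99792458e8
    E <- h * cl / 470e-9
    expect_equal(photonIntensity(650, 470) * E / 650e-6, 1)
    ## monotone increasing in wavelength at fixed power
    lam <- seq(380, 700, by = 20)
    expect_true(all(diff(photonIntensity(500, lam)) > 0))
    expect_error(photonIntensity(-5, 470), "positive")
})

test_that("Shapiro-Wilk wrapper is calibrated and guards its domain", {
    expect_error(normalityCheck(rep(1, 20)), "zero variance")
    expect_error(normalityCheck(1:2), "3")
    ## p-values uniform under normality
    set.seed(1)
    ps <- replicate(300, normalityCheck(rnorm(50))$p)
    expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
    ## strongly bimodal samples are rejected essentially always
    set.seed(2)
    rej <- replicate(200, {
        x <- c(rnorm(25, -3, 0.5), rnorm(25, 3, 0.5))
        normalityCheck(x)$p < 0.05
    })
    expect_gte(mean(rej), 0.95)
})
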