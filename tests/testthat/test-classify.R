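test_that("square templates follow their color's epochs exactly", {
    sch <- manualSchedule(c("dark", "blue470", "dark", "red660"))
    bank <- buildTemplates(sch, rateHz = 1, tau = 10)
    tm <- templates(bank)
    expect_equal(tm$blue_onset,
                 rep(c(0, 1, 0, 0), each = 60))
    expect_equal(tm$red_onset, rep(c(0, 0, 0, 1), each = 60))
    ## sawtooth: 1 at the event, 1/e one tau later, ~0 after 6 tau
    expect_equal(tm$blue_offset[121], 1)               # t = 120 s
    expect_equal(tm$blue_offset[131], exp(-1), tolerance = 1e-9)
    expect_lt(tm$blue_offset[181], 0.01)
    expect_true(all(diff(tm$blue_offset[121:180]) < 0))  # monotone decay
    ## mixed templates fire at both colors' edges
    expect_equal(tm$mixed_onset[c(61, 181)], c(1, 1))
    expect_equal(tm$mixed_offset[121], 1)
})

test_that("one-color schedules emit empty excluded templates with warning", {
    sch <- manualSchedule(c("dark", "blue470"))
    expect_warning(bank <- buildTemplates(sch, rateHz = 1), "red")
    expect_length(templates(bank)$red_onset, 0L)
    expect_length(templates(bank)$mixed_onset, 0L)
    expect_gt(length(templates(bank)$blue_onset), 0L)
    ## classification then only considers the available templates
    sig <- rbind(templates(bank)$blue_onset)
    cls <- classifyComponents(sig, bank)
    expect_equal(cls$category, "blue_onset")
})

test_that("template banks share structure but not timing across fish", {
    b1 <- buildTemplates(makeSchedule("imaging_random", 6, seed = 1),
                         rateHz = 1)
    b2 <- buildTemplates(makeSchedule("imaging_random", 6, seed = 2),
                         rateHz = 1)
    expect_identical(names(templates(b1)), names(templates(b2)))
    expect_identical(lengths(templates(b1)), lengths(templates(b2)))
    expect_false(identical(templates(b1)$blue_onset,
                           templates(b2)$blue_onset))
})

test_that("classification picks the best template above threshold", {
    sch <- makeSchedule("imaging_random", nCycles = 6, seed = 5)
    bank <- buildTemplates(sch, rateHz = 1)
    tm <- templates(bank)
    sigs <- rbind(tm$blue_onset, tm$mixed_offset)
    cls <- classifyComponents(sigs, bank)
    expect_equal(cls$category, c("blue_onset", "mixed_offset"))
    expect_equal(cls$max_corr, c(1, 1), tolerance = 1e-9)
    ## invariant to affine rescaling of the signal
    cls2 <- classifyComponents(rbind(5 * tm$blue_onset + 3), bank)
    expect_equal(cls2$category, "blue_onset")
    expect_equal(cls2$max_corr, 1, tolerance = 1e-9)
    ## constant signals are unclassified with a warning
    expect_warning(
        cls3 <- classifyComponents(rbind(rep(1, length(tm$blue_onset))),
                                   bank),
        "constant")
    expect_equal(cls3$category, "unclassified")
})

test_that("white-noise signals stay unclassified at the 0.5 threshold", {
    sch <- makeSchedule("imaging_random", nCycles = 6, seed = 5)
    bank <- buildTemplates(sch, rateHz = 1)
    nT <- length(templates(bank)$blue_onset)
    un <- vapply(1:20, function(s) {
        set.seed(s)
        classifyComponents(rbind(rnorm(nT)), bank)$category
    }, character(1))
    expect_gte(mean(un == "unclassified"), 0.95)
})

test_that("registration recovers planted translations and averages on overlap", {
    ref <- blobMap(c(30, 40), c(15, 20), 2.5)
    ## the same blob shifted by (dy, dx) = (3, -2): it sits at (18, 18)
    moved <- blobMap(c(30, 40), c(18, 18), 2.5)
    cm <- registerAndAverage(list(blue_onset = list(f1 = ref, f2 = moved)),
                             reference = "f1")
    off <- memberMaps(cm)
    expect_equal(off$offsetY[off$fish == "f2"], -3)
    expect_equal(off$offsetX[off$fish == "f2"], 2)
    avg <- categoryAverages(cm)$blue_onset
    keep <- !is.na(avg)
    expect_equal(avg[keep],
                 ref[keep], tolerance = 1e-9)
    ## single fish: identity registration
    one <- registerAndAverage(list(red_onset = list(f1 = ref)))
    expect_equal(memberMaps(one)$offsetY, 0)
    expect_equal(memberMaps(one)$offsetX, 0)
    expect_equal(categoryAverages(one)$red_onset, ref)
})

test_that("jittered fish maps average to the consensus location", {
    set.seed(7)
    maps <- lapply(1:7, function(f) {
        jit <- sample(-3:3, 2, replace = TRUE)
        blobMap(c(30, 40), c(15 + jit[1], 20 + jit[2]), 2.5)
    })
    names(maps) <- sprintf("f%d", 1:7)
    ref <- blobMap(c(30, 40), c(15, 20), 2.5)
    maps$f1 <- ref
    cm <- registerAndAverage(list(mixed_onset = maps), reference = "f1")
    avg <- categoryAverages(cm)$mixed_onset
    avg[is.na(avg)] <- 0
    peak <- which(avg == max(avg), arr.ind = TRUE)[1, ]
    expect_lte(abs(peak["row"] - 15), 1)
    expect_lte(abs(peak["col"] - 20), 1)
})
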