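test_that("R-R intervals derive from peak gaps in milliseconds", {
    expect_equal(intervals(rriFromPeaks(PeakTrain(c(0, 1, 2)))),
                 c(1000, 1000))
    expect_equal(intervals(rriFromPeaks(PeakTrain(c(0, 0.8, 1.7)))),
                 c(800, 900))
    expect_error(rriFromPeaks(PeakTrain(1.5)), "2 peaks")
    expect_equal(sourceTag(rriFromPeaks(PeakTrain(c(0, 1, 2), "ECG"))), "ECG")
})

test_that("heart rate is beats per elapsed time", {
    expect_equal(heartRate(rep(1000, 10)), 60)
    expect_equal(heartRate(rep(833.333, 5)), 72, tolerance = 1e-5)
    expect_equal(heartRate(c(800, 900)), 60000 / 850)
    expect_error(heartRate(numeric()), "empty")
})

test_that("Poincare formulas reproduce hand-computed values and edge cases", {
    p0 <- poincare(rep(1000, 10))
    expect_equal(sd1(p0), 0)
    expect_equal(sd2(p0), 0)
    expect_true(is.na(sdRatio(p0)))
    expect_true("sd_ratio_undefined" %in% summaryFlags(p0))

    p1 <- poincare(c(1000, 900, 1000, 900))
    expect_equal(sd1(p1), 81.65, tolerance = 5e-4)
    expect_equal(sd2(p1), 0, tolerance = 1e-9)
    expect_true(is.na(sdRatio(p1)))

    p2 <- poincare(c(1000, 950, 1000, 1050, 1000))
    expect_equal(sd1(p2), 40.82, tolerance = 5e-4)
    expect_equal(sd2(p2), 28.87, tolerance = 5e-4)
    expect_equal(sdRatio(p2), 1.414, tolerance = 5e-4)

    expect_error(poincare(c(1000, 900)), "3 intervals")
})

test_that("SD1 equals the perpendicular projection SD exactly", {
    set.seed(8)
    for (i in 1:100) {
        rri <- 900 + rnorm(sample(10:200, 1), 0, 50)
        p <- poincare(rri)
        orc <- poincareProjectionOracle(rri)
        expect_lt(relErr(sd1(p), orc["sd1"]), 1e-9)
    }
})

test_that("Poincare statistics obey scale and translation symmetries", {
    set.seed(9)
    for (i in 1:20) {
        rri <- 800 + rnorm(50, 0, 40)
        p <- poincare(rri)
        expect_gte(sd1(p), 0); expect_gte(sd2(p), 0)

        c0 <- runif(1, 0.5, 3)
        ps <- poincare(c0 * rri)
        expect_equal(sd1(ps), c0 * sd1(p), tolerance = 1e-10)
        expect_equal(sd2(ps), c0 * sd2(p), tolerance = 1e-10)
        expect_equal(sdRatio(ps), sdRatio(p), tolerance = 1e-10)

        pt <- poincare(rri + 200)
        expect_equal(sd1(pt), sd1(p), tolerance = 1e-9)
        expect_equal(sd2(pt), sd2(p), tolerance = 1e-9)
        expect_equal(sdRatio(pt), sdRatio(p), tolerance = 1e-9)
    }
})

test_that("implausible intervals are flagged, not rejected", {
    r <- RRISeries(c(1000, 100, 1000, 3000))
    expect_equal(implausibleIntervals(r), c(FALSE, TRUE, FALSE, TRUE))
    p <- poincare(r)
    expect_true("implausible_intervals" %in% summaryFlags(p))
})

test_that("peak matching scores sensitivity and aligns interval series", {
    truth <- PeakTrain(seq(0, 10, by = 1), "truth")
    det <- PeakTrain(c(seq(0, 6, by = 1) + 0.002, 7.5, seq(8, 10, by = 1)))
    m <- matchPeaks(det, truth, toleranceS = 0.1)
    expect_equal(m$sensitivity, 10 / 11)
    expect_equal(m$falsePositives, 1)

    a <- alignedRRI(det, truth, toleranceS = 0.1)
    expect_equal(length(a$detected), length(a$reference))
    expect_true(all(abs(a$reference - 1000) < 1e-9))
})
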