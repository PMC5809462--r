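test_that("signal composition is the weighted bitplane sum and is linear", {
    ## all-zero weights give a flagged zero series
    B <- matrix(runif(50 * 24), 50, 24, dimnames = list(NULL, bitplaneLabels()))
    hc0 <- composeSignal(B, BitplaneWeights(), fps = 60)
    expect_true(hc0@degenerate)
    expect_true(all(signalValues(hc0) == 0))

    ## single +1 on G7 equals the ROI mean of the green MSB plane
    set.seed(4)
    fr <- array(sample(0:255, 8 * 4 * 4 * 3, TRUE), c(8, 4, 4, 3))
    fs <- FrameStack(fr, fps = 60)
    mask <- matrix(TRUE, 4, 4)
    hc <- composeSignal(fs, BitplaneWeights(c(G7 = 1)), roi = mask)
    manual <- vapply(1:8, function(t)
        mean(fr[t, , , 2] >= 128), numeric(1))
    expect_equal(signalValues(hc), manual)

    ## +1 on all green bits over a uniform frame counts the set bits of v
    for (v in c(0L, 5L, 37L, 128L, 200L, 255L)) {
        fr <- array(0L, c(2, 3, 3, 3)); fr[, , , 2] <- v
        hc <- composeSignal(FrameStack(fr, fps = 60),
                            BitplaneWeights(setNames(rep(1, 8),
                                                     paste0("G", 0:7))),
                            roi = matrix(TRUE, 3, 3))
        expect_equal(signalValues(hc), rep(popcount(v), 2))
    }

    ## linearity in the weights
    wA <- BitplaneWeights(c(G7 = 1, R0 = -1))
    wB <- BitplaneWeights(c(G7 = 1, B3 = 1))
    sAB <- signalValues(composeSignal(B, BitplaneWeights(c(R0 = -1, B3 = 1)),
                                      fps = 60))
    sA <- signalValues(composeSignal(B, wA, fps = 60))
    sB <- signalValues(composeSignal(B, wB, fps = 60))
    ## wA + wB - 2*G7 = (R0=-1, B3=1)
    s2 <- sA + sB - 2 * signalValues(composeSignal(
        B, BitplaneWeights(c(G7 = 1)), fps = 60))
    expect_equal(s2, sAB)
})

test_that("weights validate and roundtrip through the JSON file format", {
    expect_error(BitplaneWeights(c(G9 = 1)), "label")
    expect_error(BitplaneWeights(c(G7 = 2)), "-1, 0, 1")
    w <- BitplaneWeights(c(G7 = 1, G6 = 1, R0 = -1))
    path <- tempfile(fileext = ".json")
    writeBitplaneWeights(w, path, band = c(0.7, 4))
    w2 <- readBitplaneWeights(path)
    expect_equal(weightVector(w2), weightVector(w))
    expect_equal(attr(w2, "band"), c(0.7, 4))
})

test_that("cardiac-band SNR behaves like a band power ratio", {
    fs <- 60; t <- seq(0, 120 - 1 / fs, by = 1 / fs)
    expect_gt(snrObjective(sin(2 * pi * 1.2 * t), fs), 30)
    expect_lt(snrObjective(sin(2 * pi * 0.2 * t), fs), -10)

    ## white noise: flat-spectrum expectation 10 log10(3.3 / 26.65) dB
    expected <- 10 * log10((4 - 0.7) / ((30 - 0.05) - (4 - 0.7)))
    set.seed(5)
    snrs <- vapply(1:50, function(i)
        snrObjective(rnorm(length(t)), fs), numeric(1))
    expect_lt(abs(mean(snrs) - expected), 1.5)

    expect_error(snrObjective(rep(1, 7200), fs), "constant")
    expect_error(snrObjective(rnorm(100), fs), "short")
})

test_that("greedy selection is deterministic, monotone, and rejects noise", {
    sub <- memo("sel24", smallSubject(seed = 21, durationS = 60))
    B <- bitplaneROIMeans(sub$video, sub$truth$roiMap)
    s1 <- selectBitplaneWeights(B, fs = 60)
    s2 <- selectBitplaneWeights(B, fs = 60)
    expect_identical(weightVector(s1@weights), weightVector(s2@weights))
    expect_identical(s1@trace, s2@trace)
    expect_identical(s1@snrTrain, s2@snrTrain)
    expect_true(s1@converged)
    ## monotone ascent of the accepted objective
    expect_true(all(diff(s1@trace$objective) > 0))

    ## noise-only video (null embedding): no cardiac component
    g <- genRRI(hrBpm = 72, durationS = 60, seed = 22)
    fv0 <- genFaceVideo(g$peaks, durationS = 60, frameShape = c(24, 24),
                        embed = list(channel = "G", bits = c(5, 6, 7),
                                     rois = "Forehead Small", amplitude = 0),
                        seed = 23)
    s0 <- selectBitplaneWeights(bitplaneROIMeans(fv0$video, fv0$truth$roiMap),
                                fs = 60)
    expect_false(s0@converged)
    expect_true(all(weightVector(s0@weights) == 0))
})
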