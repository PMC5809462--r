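test_that("RRI generation honours the iterative construction and its limits", {
    g <- genRRI(hrBpm = 60, rsaAmpMs = 0, rriNoiseMs = 0, durationS = 30,
                seed = 1)
    expect_true(all(intervals(g$rri) == 1000))
    expect_equal(peakTimes(g$peaks)[1], 0)
    ## cumulative intervals reproduce the peak times
    expect_equal(peakTimes(g$peaks),
                 c(0, cumsum(intervals(g$rri)) / 1000), tolerance = 1e-12)

    g1 <- genRRI(hrBpm = 72, durationS = 60, seed = 5)
    g2 <- genRRI(hrBpm = 72, durationS = 60, seed = 5)
    expect_identical(intervals(g1$rri), intervals(g2$rri))

    ## RSA-only variability approaches the sinusoid RMS amp/sqrt(2)
    g3 <- genRRI(hrBpm = 60, rsaAmpMs = 50, rriNoiseMs = 0, durationS = 600,
                 seed = 6)
    expect_lt(relErr(stats::sd(intervals(g3$rri)), 50 / sqrt(2)), 0.05)

    expect_error(genRRI(hrBpm = 30, seed = 1), "40, 180")
    expect_error(genRRI(hrBpm = 72, respFreqHz = 0.7, seed = 1),
                 "half the beat")
    expect_error(genRRI(hrBpm = 180, rsaAmpMs = 300, rriNoiseMs = 20,
                        seed = 1), "non-positive")
    expect_error(genRRI(hrBpm = 72), "seed")
})

test_that("synthetic ECG places template maxima on the true beats", {
    g <- genRRI(hrBpm = 72, durationS = 30, seed = 7)
    clean <- genECG(g$peaks, noiseSd = 0, durationS = 30, seed = 8)
    v <- ecgVoltage(clean)
    for (p in peakTimes(g$peaks)[2:10]) {
        i <- round(p * 1000) + 1
        win <- v[(i - 100):(i + 100)]
        expect_lt(abs(which.max(win) - 101) / 1000, 0.0006)
    }
    e1 <- genECG(g$peaks, snrDb = 20, durationS = 30, seed = 9)
    e2 <- genECG(g$peaks, snrDb = 20, durationS = 30, seed = 9)
    expect_identical(ecgVoltage(e1), ecgVoltage(e2))
})

test_that("the pulse waveform peaks at beats and stays in [0, 1]", {
    pk <- PeakTrain(c(0, 1, 2.1, 3), "truth")
    t <- seq(0, 3, by = 0.01)
    p <- pulseWaveform(t, pk)
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(p[t %in% c(0, 1, 3)], rep(1, 3))
    expect_lt(p[t == 0.5], 0.01)
})

test_that("face-video generation is reproducible and validated", {
    g <- genRRI(hrBpm = 72, durationS = 20, seed = 13)
    fv1 <- genFaceVideo(g$peaks, durationS = 20, frameShape = c(24, 24),
                        seed = 14)
    fv2 <- genFaceVideo(g$peaks, durationS = 20, frameShape = c(24, 24),
                        seed = 14)
    expect_identical(frameData(fv1$video), frameData(fv2$video))
    expect_equal(nFrames(fv1$video), 1200L)
    expect_error(genFaceVideo(g$peaks, durationS = 20,
                              embed = list(channel = "G", bits = 5,
                                           rois = "Forehead Small",
                                           amplitude = 1.4), seed = 1),
                 "amplitude")

    path <- tempfile(fileext = ".json")
    writeTruthBundle(fv1$truth, path)
    tb <- jsonlite::read_json(path, simplifyVector = TRUE)
    expect_equal(tb$true_rri_ms, intervals(fv1$truth$rri), tolerance = 1e-9)
    expect_equal(tb$true_peaks_s, peakTimes(fv1$truth$peaks),
                 tolerance = 1e-9)
})

test_that("the embedding places cardiac power in the chosen planes only", {
    sub <- memo("sel24", smallSubject(seed = 21, durationS = 60))
    B <- bitplaneROIMeans(sub$video, sub$truth$roiMap)
    bf <- B[["Forehead Small"]]
    inband <- function(s) {
        sp <- welchPSD(s, 60)
        pw <- sum(sp$psd[sp$freq >= 0.7 & sp$freq <= 4])
        pw / sum(sp$psd[sp$freq >= 0.05])
    }
    varying <- colnames(bf)[apply(bf, 2, stats::sd) > 0]
    embedded <- intersect(paste0("G", 5:7), varying)
    others <- intersect(c("R5", "R6", "R7", "B5", "B6", "B7"), varying)
    expect_gt(length(embedded), 0)
    expect_gt(length(others), 0)
    fEmb <- vapply(embedded, function(cn) inband(bf[, cn]), numeric(1))
    fOther <- vapply(others, function(cn) inband(bf[, cn]), numeric(1))
    expect_gt(min(fEmb), 2 * max(fOther))
})
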