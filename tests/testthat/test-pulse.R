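test_that("cardiac bandpass rejects DC, keeps the band, attenuates below it", {
    fs <- 60; t <- seq(0, 60 - 1 / fs, by = 1 / fs)
    const <- bandpassFilter(rep(3.7, length(t)), fs = fs)
    expect_lt(max(abs(const)), 1e-6 * 3.7)

    core <- seq(10 * fs, 50 * fs)   # away from the edges
    y <- bandpassFilter(sin(2 * pi * 1.2 * t), fs = fs)
    expect_lt(abs(max(y[core]) - 1), 0.01)

    slow <- bandpassFilter(sin(2 * pi * 0.1 * t), fs = fs)
    expect_lt(20 * log10(max(abs(slow[core]))), -20)

    expect_error(bandpassFilter(sin(t), fs = 7), "Nyquist")
})

test_that("empirical mode decomposition is complete and separates tones", {
    fs <- 60; t <- seq(0, 60 - 1 / fs, by = 1 / fs)

    tone <- sin(2 * pi * 1.2 * t)
    e <- emd(tone, fs = fs)
    rec <- rowSums(imfMatrix(e)) + imfResidue(e)
    expect_lt(max(abs(rec - tone)) / stats::sd(tone), 1e-8)
    expect_gt(cor(imfMatrix(e)[, 1], tone), 0.99)

    set.seed(6)
    noisy <- rnorm(1024)
    e2 <- emd(noisy, fs = fs)
    rec2 <- rowSums(imfMatrix(e2)) + imfResidue(e2)
    expect_lt(max(abs(rec2 - noisy)) / stats::sd(noisy), 1e-8)

    two <- sin(2 * pi * 1.5 * t) + sin(2 * pi * 0.25 * t)
    e3 <- emd(two, fs = fs)
    M <- imfMatrix(e3)
    corFast <- apply(M, 2, cor, y = sin(2 * pi * 1.5 * t))
    corSlow <- apply(M, 2, cor, y = sin(2 * pi * 0.25 * t))
    expect_gt(max(corFast), 0.95)
    expect_gt(max(corSlow), 0.95)

    expect_error(emd(rep(1, 100)), "constant")
    expect_error(emd(rnorm(8)), "16 samples")
})

test_that("the Hilbert stage finds the principal cardiac frequency", {
    fs <- 60; t <- seq(0, 60 - 1 / fs, by = 1 / fs)
    pr <- principalFrequency(emd(sin(2 * pi * 1.2 * t), fs = fs))
    expect_lt(abs(pr$frequency - 1.2), 0.02)

    pr2 <- principalFrequency(emd(sin(2 * pi * 1.0 * t), fs = fs))
    expect_lt(abs(pr2$frequency - 1.0), 0.02)
    expect_lt(abs(60 * pr2$frequency - 60), 1.2)   # 60 BPM

    ## respiratory tone rejected as out of band
    mix <- sin(2 * pi * 1.2 * t) + 1.5 * sin(2 * pi * 0.25 * t)
    pr3 <- principalFrequency(emd(mix, fs = fs))
    expect_lt(abs(pr3$frequency - 1.2), 0.05)

    expect_error(principalFrequency(emd(sin(2 * pi * 0.2 * t), fs = fs)),
                 "no cardiac component")
})

test_that("peak reconstruction recovers maxima, merges, and errors sensibly", {
    fs <- 60; t <- seq(0, 10 - 1 / fs, by = 1 / fs)
    pk <- reconstructPeaks(sin(2 * pi * 1.0 * (t - 0.25)), fs, edgeTrim = 0)
    expect_length(peakTimes(pk), 10L)
    expect_lt(max(abs(diff(peakTimes(pk)) - 1.0)), 0.001)

    expect_error(reconstructPeaks(rep(0, 600), fs), "insufficient beats")

    ## alternating 900/1000 ms intervals survive the full pulse chain
    times <- cumsum(c(0, rep(c(0.9, 1.0), 60)))
    times <- times[times <= 110]
    tr <- PeakTrain(times, "truth")
    tt <- seq(0, max(times), by = 1 / fs)
    y <- bandpassFilter(pulseWaveform(tt, tr), fs = fs)
    pr <- principalFrequency(emd(y, fs = fs))
    rec <- reconstructPeaks(pr$imf, fs, principalHz = pr$frequency)
    gaps <- 1000 * diff(peakTimes(rec))
    short <- gaps[gaps < 950]; long <- gaps[gaps >= 950]
    expect_gt(length(short), 20); expect_gt(length(long), 20)
    expect_true(all(abs(short - 900) < 20))
    expect_true(all(abs(long - 1000) < 20))
})

test_that("peak timing is invariant to signal amplitude", {
    fs <- 60
    g <- genRRI(hrBpm = 72, durationS = 60, seed = 31)
    t <- seq(0, 60, by = 1 / fs)
    set.seed(32)
    p <- pulseWaveform(t, g$peaks) + rnorm(length(t), 0, 0.05)
    for (c in c(0.01, 5.3, 1000)) {
        p1 <- reconstructPeaks(principalFrequency(
            emd(bandpassFilter(p, fs = fs), fs = fs))$imf, fs)
        p2 <- reconstructPeaks(principalFrequency(
            emd(bandpassFilter(c * p, fs = fs), fs = fs))$imf, fs)
        expect_equal(peakTimes(p1), peakTimes(p2), tolerance = 1e-9)
    }
})

test_that("heart rate is recovered within 1 BPM from noisy harmonic signals", {
    ## synthetic HC signal: cardiac tone + white noise at 10 dB broadband SNR
    fs <- 60; t <- seq(0, 120 - 1 / fs, by = 1 / fs)
    set.seed(7)
    for (hr in c(48, 60, 72, 90, 120)) {
        sig <- cos(2 * pi * hr / 60 * t)
        y <- sig + rnorm(length(t), 0, sqrt(mean(sig^2)) / 10^(10 / 20))
        pr <- principalFrequency(emd(bandpassFilter(y, fs = fs), fs = fs))
        pk <- reconstructPeaks(pr$imf, fs, principalHz = pr$frequency)
        hrRec <- heartRate(rriFromPeaks(pk))
        expect_lt(abs(hrRec - hr), 1)
        ## peak count tracks duration x principal frequency
        expect_lt(abs(length(peakTimes(pk)) - 118 * pr$frequency), 2.5)
    }
})
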