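test_that("bitplane decomposition matches bit arithmetic on known frames", {
    z <- array(0L, c(3, 4, 3))
    pl <- decomposeBitplanes(z)
    expect_length(pl, 24L)
    expect_true(all(vapply(pl, function(p) all(p == 0L), logical(1))))

    f255 <- array(255L, c(3, 4, 3))
    expect_true(all(vapply(decomposeBitplanes(f255),
                           function(p) all(p == 1L), logical(1))))

    f5 <- array(0L, c(2, 2, 3))
    f5[1, 2, 2] <- 5L                       # 5 = 00000101 in green
    pl <- decomposeBitplanes(f5)
    expect_equal(pl$G0[1, 2], 1L)
    expect_equal(pl$G2[1, 2], 1L)
    for (lab in setdiff(bitplaneLabels(), c("G0", "G2")))
        expect_true(all(pl[[lab]][1, 2] == 0L) || lab %in% c("G0", "G2"))
    expect_equal(pl$G1[1, 2], 0L)
    expect_equal(pl$R0[1, 2], 0L)

    expect_error(decomposeBitplanes(array(0L, c(2, 2))), "RGB")
    expect_error(decomposeBitplanes(array(300L, c(2, 2, 3))), "8-bit")
})

test_that("bitplane roundtrip is exact for all 256 channel values", {
    frame <- array(rep(0:255, length.out = 16 * 16 * 3), c(16, 16, 3))
    storage.mode(frame) <- "integer"
    expect_setequal(unique(as.vector(frame)), 0:255)
    pl <- decomposeBitplanes(frame)
    for (ci in seq_along(c("R", "G", "B"))) {
        ch <- c("R", "G", "B")[ci]
        rec <- reconstructChannel(pl[paste0(ch, 0:7)])
        expect_identical(rec, frame[, , ci])
    }
})

test_that("bitplane roundtrip is exact on random frames and planes are binary", {
    set.seed(1)
    for (i in 1:25) {
        frame <- array(sample(0:255, 6 * 5 * 3, replace = TRUE), c(6, 5, 3))
        storage.mode(frame) <- "integer"
        pl <- decomposeBitplanes(frame)
        expect_true(all(unlist(pl) %in% c(0L, 1L)))
        for (ci in 1:3) {
            rec <- reconstructChannel(pl[paste0(c("R", "G", "B")[ci], 0:7)])
            expect_identical(rec, frame[, , ci])
        }
    }
    expect_error(reconstructChannel(list(matrix(0L, 2, 2))), "8 bitplanes")
    b7 <- c(rep(list(matrix(0L, 2, 2)), 7), list(matrix(1L, 2, 2)))
    expect_true(all(reconstructChannel(b7) == 128L))
})

test_that("ROI averaging is the arithmetic pixel mean and is linear", {
    v <- array(7, c(3, 2, 2))
    full <- matrix(TRUE, 2, 2)
    expect_equal(averageROI(v, full), rep(7, 3))

    two <- array(0, c(1, 2, 2))
    two[1, 1, 1] <- 4; two[1, 2, 1] <- 10
    mask <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
    expect_equal(averageROI(two, mask), 7)

    ## checkerboard, brute-force pixel-loop oracle
    H <- 6; W <- 6
    cb <- outer(1:H, 1:W, function(i, j) (i + j) %% 2)
    vid <- array(0, c(2, H, W)); vid[1, , ] <- cb; vid[2, , ] <- cb
    oracle <- mean(vapply(1:H, function(i) sum(cb[i, ]), numeric(1))) / W
    expect_equal(averageROI(vid, matrix(TRUE, H, W)), rep(0.5, 2))
    expect_equal(oracle, 0.5)

    set.seed(2)
    X <- array(rnorm(4 * 3 * 3), c(4, 3, 3))
    Y <- array(rnorm(4 * 3 * 3), c(4, 3, 3))
    m <- matrix(sample(c(TRUE, FALSE), 9, TRUE, prob = c(.7, .3)), 3, 3)
    if (!any(m)) m[1, 1] <- TRUE
    expect_equal(averageROI(2.5 * X - 1.2 * Y, m),
                 2.5 * averageROI(X, m) - 1.2 * averageROI(Y, m))

    expect_error(averageROI(X, matrix(FALSE, 3, 3)), "empty")
})

test_that("FrameStack archives roundtrip and accessors agree", {
    set.seed(3)
    fr <- array(sample(0:255, 10 * 4 * 4 * 3, TRUE), c(10, 4, 4, 3))
    fs <- FrameStack(fr, fps = 60)
    expect_equal(nFrames(fs), 10L)
    expect_equal(frameDim(fs), c(4L, 4L))
    expect_equal(duration(fs), 10 / 60)
    path <- tempfile(fileext = ".rds")
    writeFrameStack(fs, path)
    fs2 <- readFrameStack(path)
    expect_identical(frameData(fs2), frameData(fs))
    expect_equal(fps(fs2), 60)
    expect_error(FrameStack(array(-1L, c(2, 2, 2, 3))), "0, 255")
})

test_that("ROI maps validate masks and roundtrip through JSON config", {
    expect_error(ROIMap(list(a = matrix(FALSE, 2, 2))), "empty")
    expect_error(validObject(new("ROIMap",
        masks = list(matrix(TRUE, 2, 2)))), "unique")

    rm <- defaultFaceROIs(c(48, 48))
    expect_setequal(roiNames(rm), faceROINames())
    expect_true(all(vapply(rm@masks, sum, numeric(1)) > 0))
    ## regions must not collide pairwise more than trivially
    expect_true(all(dim(roiMask(rm, "Upper Lip")) == c(48, 48)))

    path <- tempfile(fileext = ".json")
    writeROIConfig(rm, path)
    rm2 <- readROIConfig(path)
    expect_identical(lapply(rm2@masks, unname), lapply(rm@masks, unname))

    ## half-open rectangle convention, 0-based x (columns) / y (rows)
    one <- roiMapFromRects(list(r = list(x0 = 1, y0 = 0, x1 = 3, y1 = 2)),
                           c(4, 4))
    m <- roiMask(one, "r")
    expect_equal(sum(m), 4)
    expect_true(all(m[1:2, 2:3]))
    expect_error(roiMapFromRects(list(r = list(x0 = 0, y0 = 0, x1 = 9,
                                               y1 = 1)), c(4, 4)), "bounds")
})
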