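#' Generate an RSA-modulated R-R interval series
#'
#' Beat times are built iteratively: `t_0 = 0`,
#' `RRI_n = base + rsaAmp * sin(2 pi respFreq t_n) + N(0, rriNoise^2)`,
#' `t_{n+1} = t_n + RRI_n / 1000`, truncated to the recording duration,
#' with `base = 60000 / hrBpm`. The sinusoidal term emulates respiratory
#' sinus arrhythmia: heart rate rises on inhalation and falls on
#' exhalation, locked to the breathing frequency.
#'
#' @param hrBpm mean heart rate, 40-180 beats/min (default 72).
#' @param rsaAmpMs RSA modulation depth in ms (default 40).
#' @param respFreqHz breathing frequency in Hz (default 0.25); must be below
#'   half the beat frequency.
#' @param rriNoiseMs white interval jitter SD in ms (default 10).
#' @param durationS recording length in seconds (default 120).
#' @param seed RNG seed (mandatory: every generator is bit-reproducible).
#' @return List with `peaks` (truth [PeakTrain-class]) and `rri`
#'   (truth [RRISeries-class]).
#' @examples
#' g <- genRRI(hrBpm = 60, rsaAmpMs = 0, rriNoiseMs = 0, seed = 1)
#' head(intervals(g$rri))   # all exactly 1000 ms
#' @export
genRRI <- function(hrBpm = 72, rsaAmpMs = 40, respFreqHz = 0.25,
                   rriNoiseMs = 10, durationS = 120, seed) {
    if (missing(seed)) stop("a seed is mandatory")
    if (hrBpm < 40 || hrBpm > 180) stop("hrBpm must lie in [40, 180]")
    if (respFreqHz >= hrBpm / 60 / 2)
        stop("respFreqHz must be below half the beat frequency")
    base <- 60000 / hrBpm
    if (base - rsaAmpMs - 6 * rriNoiseMs <= 0)
        stop("parameters imply non-positive intervals")
    set.seed(seed)
    t <- 0
    times <- numeric(0)
    while (t <= durationS) {
        times <- c(times, t)
        rri <- base + rsaAmpMs * sin(2 * pi * respFreqHz * t) +
            stats::rnorm(1, 0, rriNoiseMs)
        if (rri <= 0) stop("parameters imply non-positive intervals")
        t <- t + rri / 1000
    }
    peaks <- new("PeakTrain", times = times, source = "truth")
    list(peaks = peaks,
         rri = RRISeries(1000 * diff(times), source = "truth"))
}

#' Generate a synthetic ECG waveform from beat times
#'
#' Each beat contributes a unit-amplitude Gaussian R wave (SD 10 ms) at the
#' true peak time, a P bump (amplitude 0.15, 180 ms before, SD 25 ms) and a
#' T bump (amplitude 0.3, 250 ms after, SD 50 ms); white noise is added on
#' top. Setting `snrDb` instead of `noiseSd` chooses the noise SD so the
#' clean-waveform RMS is that many dB above it.
#'
#' @param peaks a [PeakTrain-class] of true beat times (>= 2 peaks).
#' @param ecgFs sampling rate in Hz (default 1000).
#' @param noiseSd additive white noise SD (waveform units).
#' @param snrDb alternative noise specification in dB.
#' @param durationS record length (default: covers the last beat + 0.5 s).
#' @param seed RNG seed (mandatory).
#' @return An [ECGRecord-class].
#' @export
genECG <- function(peaks, ecgFs = 1000, noiseSd = NULL, snrDb = NULL,
                   durationS = NULL, seed) {
    if (missing(seed)) stop("a seed is mandatory")
    pt <- peakTimes(peaks)
    if (length(pt) < 2L) stop("at least 2 peaks are required")
    if (is.null(durationS)) durationS <- max(pt) + 0.5
    n <- round(durationS * ecgFs)
    t <- (seq_len(n) - 1) / ecgFs
    clean <- numeric(n)
    bump <- function(center, amp, sdS) {
        lo <- max(1L, floor((center - 5 * sdS) * ecgFs) + 1L)
        hi <- min(n, ceiling((center + 5 * sdS) * ecgFs) + 1L)
        if (lo > hi) return(invisible())
        i <- lo:hi
        clean[i] <<- clean[i] + amp * exp(-((t[i] - center)^2) / (2 * sdS^2))
    }
    for (p in pt) {
        bump(p, 1, 0.010)
        bump(p - 0.180, 0.15, 0.025)
        bump(p + 0.250, 0.30, 0.050)
    }
    if (is.null(noiseSd)) {
        noiseSd <- if (is.null(snrDb)) 0 else
            sqrt(mean(clean^2)) / 10^(snrDb / 20)
    }
    set.seed(seed)
    ECGRecord(clean + stats::rnorm(n, 0, noiseSd), fs = ecgFs)
}

#' Pulse waveform locked to beat times
#'
#' Raised cosine per beat: within `[t_n, t_{n+1})` the waveform is
#' `0.5 * (1 + cos(2 pi (t - t_n) / RRI_n))`, so it peaks at every beat and
#' dips to zero mid-interval. A waveform carrying only timing information is
#' all downstream analysis uses; no physiological pulse template is needed.
#'
#' @param t numeric evaluation times in seconds.
#' @param peaks a [PeakTrain-class] of beat times.
#' @return Numeric values in `[0, 1]`.
#' @export
pulseWaveform <- function(t, peaks) {
    pt <- peakTimes(peaks)
    if (length(pt) < 2L) stop("at least 2 peaks are required")
    rri <- diff(pt)
    ## index of the beat interval each t falls in (clamped to the ends)
    k <- findInterval(t, pt)
    k[k < 1L] <- 1L
    k[k > length(rri)] <- length(rri)
    phase <- (t - pt[k]) / rri[k]
    0.5 * (1 + cos(2 * pi * phase))
}

#' Default synthetic face base image
#'
#' A static skin-toned shading gradient (R brightest, then G, then B) plus a
#' deterministic quasi-periodic texture. The texture matters: real skin
#' imagery varies at the pixel scale, so every bitplane holds a mixed
#' population of set and unset bits; on a texture-free gradient whole
#' regions would saturate a bit at 0 or 1 and leave the embedding nothing
#' to modulate.
#'
#' @param frameShape integer `c(H, W)`.
#' @return Integer `H x W x 3` array.
#' @export
defaultBaseImage <- function(frameShape) {
    H <- frameShape[1]; W <- frameShape[2]
    gy <- matrix(seq(0, 1, length.out = H), H, W)
    gx <- matrix(seq(0, 1, length.out = W), H, W, byrow = TRUE)
    row <- matrix(seq_len(H), H, W)
    col <- matrix(seq_len(W), H, W, byrow = TRUE)
    tex <- 14 * sin(2.1 * row) * cos(1.7 * col) + 9 * sin(0.9 * row + 1.3 * col)
    base <- array(0L, c(H, W, 3))
    base[, , 1] <- round(140 + 50 * gx + 20 * gy + tex)
    base[, , 2] <- round(100 + 45 * gy + 25 * gx + tex)
    base[, , 3] <- round(80 + 40 * gx * gy + 20 * (1 - gy) + tex)
    base[base < 0] <- 0L
    base[base > 255] <- 255L
    storage.mode(base) <- "integer"
    base
}

#' Pixel noise SD realising a target cardiac-band intensity SNR
#'
#' The expected per-pixel cardiac intensity modulation of the embedding is
#' `amplitude * rms(p - mean(p)) * sum_b 2^b (1 - bit_b(base))` over the
#' embedded pixels (`rms` of the raised-cosine deviation is `1/(2 sqrt 2)`).
#' The returned SD places that modulation RMS `snrDb` decibels above the
#' white pixel noise.
#'
#' @param base integer `H x W x 3` base image.
#' @param roiMap an [ROIMap-class].
#' @param embed embedding spec (see [genFaceVideo()]).
#' @param snrDb target per-pixel SNR in dB.
#' @return Noise SD in intensity units.
#' @export
noiseSdForSNR <- function(base, roiMap, embed, snrDb) {
    ci <- match(embed$channel, CHANNELS)
    lift <- 0
    npx <- 0
    for (r in embed$rois) {
        idx <- which(roiMask(roiMap, r))
        ch <- base[, , ci]
        for (b in embed$bits)
            lift <- lift + sum(2^b * (bitwAnd(ch[idx], bitwShiftL(1L, b)) == 0))
        npx <- npx + length(idx)
    }
    sPix <- embed$amplitude * (1 / (2 * sqrt(2))) * lift / npx
    sPix / 10^(snrDb / 20)
}

#' Generate a synthetic facial video with a bitplane-embedded pulse
#'
#' A static face-like base image is repeated for every frame; inside the
#' embedded ROIs each target bit of the target channel is set with
#' probability `p(t) * amplitude` (`p` the raised-cosine pulse waveform of
#' [pulseWaveform()]), otherwise the base bit is kept, so the cardiac signal
#' genuinely lives in specific bitplanes of specific regions. White sensor
#' noise and a slow illumination drift are then added in intensity space and
#' the frames are re-quantised to 8 bits. All other ROIs receive noise only,
#' which is what exercises ROI and bitplane selection downstream.
#'
#' @param peaks a [PeakTrain-class] of true beat times.
#' @param fps frame rate (default 60).
#' @param durationS recording length in seconds (default: span of `peaks`).
#' @param frameShape integer `c(H, W)` (default 48 x 48).
#' @param roiMap an [ROIMap-class]; default [defaultFaceROIs()].
#' @param embed list: `channel` ("R"/"G"/"B"), `bits` (0..7), `rois`
#'   (names), `amplitude` (bit-set probability scale in [0, 1]). Default:
#'   green bits 5-7 in Forehead Small and both cheeks, amplitude 0.6.
#' @param videoNoiseSd white pixel noise SD, intensity units (default 2).
#' @param drift slow illumination trend: `list(amplitude, freqHz, slope)`
#'   in intensity units (default 2-unit sinusoid at 0.05 Hz).
#' @param baseImage optional `H x W x 3` integer base image.
#' @param seed RNG seed (mandatory).
#' @return List with `video` (a [FrameStack-class]) and `truth` (list:
#'   `peaks`, `rri`, `roiMap`, `embed`, `config`).
#' @export
genFaceVideo <- function(peaks, fps = 60, durationS = NULL,
                         frameShape = c(48, 48), roiMap = NULL,
                         embed = list(channel = "G", bits = c(5, 6, 7),
                                      rois = c("Forehead Small",
                                               "Right Cheek Narrow",
                                               "Left Cheek Narrow"),
                                      amplitude = 0.6),
                         videoNoiseSd = 2,
                         drift = list(amplitude = 2, freqHz = 0.05,
                                      slope = 0),
                         baseImage = NULL, seed) {
    if (missing(seed)) stop("a seed is mandatory")
    if (embed$amplitude < 0 || embed$amplitude > 1)
        stop("embedding amplitude must lie in [0, 1]")
    if (any(!embed$bits %in% 0:7)) stop("embedded bits must lie in 0..7")
    if (is.null(durationS)) durationS <- max(peakTimes(peaks))
    if (is.null(roiMap)) roiMap <- defaultFaceROIs(frameShape)
    if (is.null(baseImage)) baseImage <- defaultBaseImage(frameShape)
    H <- frameShape[1]; W <- frameShape[2]
    T <- round(fps * durationS)
    tGrid <- (seq_len(T) - 1) / fps
    p <- pulseWaveform(tGrid, peaks)
    ci <- match(embed$channel, CHANNELS)
    if (is.na(ci)) stop("embed$channel must be 'R', 'G' or 'B'")

    set.seed(seed)
    frames <- array(0L, c(T, H, W, 3))
    driftV <- drift$amplitude * sin(2 * pi * drift$freqHz * tGrid) +
        drift$slope * tGrid
    for (cc in 1:3) {
        ch <- matrix(rep(as.integer(baseImage[, , cc]), each = T), nrow = T)
        if (cc == ci && embed$amplitude > 0) {
            q <- p * embed$amplitude
            for (r in embed$rois) {
                idx <- which(roiMask(roiMap, r))
                sub <- ch[, idx, drop = FALSE]
                for (b in embed$bits) {
                    bit <- bitwShiftL(1L, b)
                    hit <- matrix(stats::runif(T * length(idx)), T) < q
                    sub[hit] <- bitwOr(sub[hit], bit)
                }
                ch[, idx] <- sub
            }
        }
        x <- ch + driftV + stats::rnorm(length(ch), 0, videoNoiseSd)
        x <- round(x)
        x[x < 0] <- 0; x[x > 255] <- 255
        storage.mode(x) <- "integer"
        dim(x) <- c(T, H, W)
        frames[, , , cc] <- x
    }
    video <- FrameStack(frames, fps = fps)
    truth <- list(peaks = peaks, rri = rriFromPeaks(peaks),
                  roiMap = roiMap, embed = embed,
                  config = list(fps = fps, durationS = durationS,
                                frameShape = frameShape,
                                videoNoiseSd = videoNoiseSd, drift = drift,
                                seed = seed))
    list(video = video, truth = truth)
}

#' Write a synthetic truth bundle to JSON
#'
#' Records the ground-truth R-R intervals and beat times together with a
#' configuration echo, so any downstream result can be scored against truth.
#'
#' @param truth the `truth` element returned by [genFaceVideo()] (or a list
#'   with `peaks`, `rri` and optionally `config`).
#' @param path output JSON path.
#' @export
writeTruthBundle <- function(truth, path) {
    jsonlite::write_json(list(
        true_rri_ms = intervals(truth$rri),
        true_peaks_s = peakTimes(truth$peaks),
        embed = truth$embed,
        config = truth$config), path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Generate one complete synthetic subject
#'
#' Draws an RSA-modulated truth RRI series, renders the facial video with
#' the pulse embedded in the configured bitplanes, and synthesises the
#' matched ECG from the same truth beats: the paired recording a validation
#' study would collect for one participant.
#'
#' @param seed RNG seed; sub-seeds for video and ECG are derived from it.
#' @param hrBpm,rsaAmpMs,respFreqHz,rriNoiseMs,durationS passed to
#'   [genRRI()].
#' @param ecgSnrDb ECG noise level in dB (default 20).
#' @param ... further arguments to [genFaceVideo()].
#' @return List with `truth`, `video`, `ecg`.
#' @export
synthSubject <- function(seed, hrBpm = 72, rsaAmpMs = 40, respFreqHz = 0.25,
                         rriNoiseMs = 10, durationS = 120, ecgSnrDb = 20,
                         ...) {
    g <- genRRI(hrBpm = hrBpm, rsaAmpMs = rsaAmpMs, respFreqHz = respFreqHz,
                rriNoiseMs = rriNoiseMs, durationS = durationS, seed = seed)
    fv <- genFaceVideo(g$peaks, durationS = durationS, seed = seed + 1L, ...)
    ecg <- genECG(g$peaks, snrDb = ecgSnrDb, durationS = durationS,
                  seed = seed + 2L)
    list(truth = fv$truth, video = fv$video, ecg = ecg)
}
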