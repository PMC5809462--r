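#' @import methods
NULL

CHANNELS <- c("R", "G", "B")

#' Canonical bitplane labels
#'
#' The 24 bitplanes of an 8-bit RGB frame are labelled by channel letter and
#' bit index, bit 0 being the least significant: `"R0"`..`"R7"`, `"G0"`..
#' `"G7"`, `"B0"`..`"B7"`.
#'
#' @return Character vector of the 24 labels in canonical order.
#' @export
bitplaneLabels <- function() {
    as.vector(t(outer(CHANNELS, 0:7, paste0)))
}

#' FrameStack: an ordered stack of RGB video frames
#'
#' Raw video is held as a `T x H x W x 3` integer array of 8-bit samples
#' (channels ordered R, G, B) together with the frame rate.
#'
#' @slot frames integer array, dimensions `T x H x W x 3`, values in 0..255.
#' @slot fps frames per second (positive scalar).
#' @export
setClass("FrameStack",
    representation(frames = "array", fps = "numeric"))

setValidity("FrameStack", function(object) {
    d <- dim(object@frames)
    if (length(d) != 4L)
        return("frames must be a T x H x W x 3 array")
    if (d[4] != 3L)
        return("frames must have 3 channels (R, G, B)")
    if (length(object@fps) != 1L || !is.finite(object@fps) || object@fps <= 0)
        return("fps must be a positive scalar")
    rng <- range(object@frames)
    if (rng[1] < 0 || rng[2] > 255)
        return("pixel values must lie in [0, 255]")
    if (any(object@frames != round(object@frames)))
        return("pixel values must be integers (8-bit samples)")
    TRUE
})

#' ROIMap: named pixel masks for facial regions of interest
#'
#' Each region is a logical `H x W` mask the same shape as the video frames.
#' The nine default facial regions follow the standard face layout: Forehead
#' Small, Nose Between Eyes, Nose Bridge Full, Nose Tip Small, Right Cheek
#' Narrow, Left Cheek Narrow, Upper Lip, Lower Lip, Chin Small.
#'
#' @slot masks named list of logical matrices, one per region.
#' @export
setClass("ROIMap", representation(masks = "list"))

setValidity("ROIMap", function(object) {
    m <- object@masks
    if (length(m) == 0L) return("at least one ROI is required")
    nm <- names(m)
    if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
        return("ROI names must be unique and non-empty")
    dims <- unique(lapply(m, dim))
    if (length(dims) != 1L)
        return("all masks must share the frame shape")
    for (i in seq_along(m)) {
        if (!is.logical(m[[i]]) || !is.matrix(m[[i]]))
            return("masks must be logical matrices")
        if (!any(m[[i]]))
            return(sprintf("ROI '%s' is empty", nm[i]))
    }
    TRUE
})

#' BitplaneWeights: signed bitplane combination coefficients
#'
#' One coefficient in {-1, 0, +1} per (channel, bit); the hemoglobin-
#' concentration image is the pixel-wise signed sum of the selected bitplanes.
#'
#' @slot w named numeric vector of length 24 (names [bitplaneLabels()]),
#'   values in {-1, 0, 1}.
#' @export
setClass("BitplaneWeights", representation(w = "numeric"))

setValidity("BitplaneWeights", function(object) {
    if (length(object@w) != 24L)
        return("exactly 24 coefficients are required")
    if (!identical(names(object@w), bitplaneLabels()))
        return("coefficients must be named R0..R7, G0..G7, B0..B7 in order")
    if (!all(object@w %in% c(-1, 0, 1)))
        return("coefficients must lie in {-1, 0, 1}")
    TRUE
})

#' HCSignal: a per-ROI hemoglobin-concentration time series
#'
#' @slot values numeric series sampled at the video frame rate.
#' @slot fps sampling rate in frames/second.
#' @slot roi name of the region the series was averaged over.
#' @slot degenerate flag set when the composing weights were all zero.
#' @export
setClass("HCSignal",
    representation(values = "numeric", fps = "numeric", roi = "character",
                   degenerate = "logical"),
    prototype(roi = NA_character_, degenerate = FALSE))

setValidity("HCSignal", function(object) {
    if (length(object@values) < 2L) return("at least 2 samples are required")
    if (any(!is.finite(object@values))) return("values must be finite")
    if (length(object@fps) != 1L || object@fps <= 0)
        return("fps must be a positive scalar")
    TRUE
})

#' IMFSet: intrinsic mode functions from empirical mode decomposition
#'
#' @slot imfs numeric matrix, one column per IMF (first column = fastest).
#' @slot residue numeric vector, the final monotone residue.
#' @slot fps sampling rate of the decomposed series.
#' @export
setClass("IMFSet",
    representation(imfs = "matrix", residue = "numeric", fps = "numeric"))

setValidity("IMFSet", function(object) {
    if (nrow(object@imfs) != length(object@residue))
        return("imfs and residue must have equal length")
    TRUE
})

#' PeakTrain: heartbeat (or R-wave) event times
#'
#' @slot times strictly increasing peak times in seconds.
#' @slot source one of "TOI", "ECG", "truth".
#' @export
setClass("PeakTrain",
    representation(times = "numeric", source = "character"),
    prototype(source = "TOI"))

setValidity("PeakTrain", function(object) {
    if (length(object@times) && any(diff(object@times) <= 0))
        return("peak times must be strictly increasing")
    if (length(object@source) != 1L ||
        !object@source %in% c("TOI", "ECG", "truth"))
        return("source must be one of 'TOI', 'ECG', 'truth'")
    TRUE
})

#' RRISeries: ordered R-R intervals in milliseconds
#'
#' Intervals outside the physiologically plausible range of 250-2500 ms are
#' flagged (see [implausibleIntervals()]) but not rejected.
#'
#' @slot rri numeric intervals in milliseconds, all positive.
#' @slot source one of "TOI", "ECG", "truth".
#' @export
setClass("RRISeries",
    representation(rri = "numeric", source = "character"),
    prototype(source = "TOI"))

setValidity("RRISeries", function(object) {
    if (any(object@rri <= 0)) return("intervals must be positive")
    if (length(object@source) != 1L ||
        !object@source %in% c("TOI", "ECG", "truth"))
        return("source must be one of 'TOI', 'ECG', 'truth'")
    TRUE
})

#' ECGRecord: a uniformly sampled ECG waveform
#'
#' @slot t time stamps in seconds.
#' @slot voltage sampled voltage, arbitrary units.
#' @slot fs sampling rate in Hz.
#' @export
setClass("ECGRecord",
    representation(t = "numeric", voltage = "numeric", fs = "numeric"))

setValidity("ECGRecord", function(object) {
    n <- length(object@t)
    if (n != length(object@voltage))
        return("t and voltage must have equal length")
    if (n < 2L || (object@t[n] - object@t[1]) < 2)
        return("at least 2 s of data are required")
    dt <- diff(object@t)
    if (max(abs(dt - 1 / object@fs)) > 1e-6 / object@fs)
        return("sampling must be uniform at fs (within 1 ppm)")
    TRUE
})

#' PoincareSummary: Poincare-plot HRV summary of an RRI series
#'
#' SD1 is the dispersion perpendicular to the identity line of the
#' RR(n) vs RR(n+1) scatter (short-term variability); SD2 the dispersion
#' along it (long-term variability). SD1/SD2 is the stress index: lower
#' ratios indicate higher basal stress.
#'
#' @slot sd1 SD1 in milliseconds.
#' @slot sd2 SD2 in milliseconds.
#' @slot sdRatio SD1/SD2 (NA when SD2 is zero).
#' @slot heartRate mean heart rate in beats/minute.
#' @slot n number of intervals summarised.
#' @slot flags character vector of quality flags.
#' @export
setClass("PoincareSummary",
    representation(sd1 = "numeric", sd2 = "numeric", sdRatio = "numeric",
                   heartRate = "numeric", n = "integer", flags = "character"),
    prototype(flags = character()))

setValidity("PoincareSummary", function(object) {
    if (object@sd1 < 0 || object@sd2 < 0)
        return("SD1 and SD2 must be non-negative")
    TRUE
})

#' SelectionReport: result of greedy bitplane-weight selection
#'
#' @slot weights the selected [BitplaneWeights-class].
#' @slot snrTrain mean cardiac-band SNR (dB) across ROIs on the training split.
#' @slot snrValidation the same on the held-out validation split.
#' @slot iterations number of accepted greedy steps.
#' @slot converged TRUE when a cardiac component was found (nonzero weights
#'   with positive training SNR).
#' @slot trace per-iteration data.frame (plane toggled, new value, mean-ROI objective in dB).
#' @export
setClass("SelectionReport",
    representation(weights = "BitplaneWeights", snrTrain = "numeric",
                   snrValidation = "numeric", iterations = "integer",
                   converged = "logical", trace = "data.frame"))

#' AgreementReport: Bland-Altman and correlation agreement statistics
#'
#' Differences are method A minus method B (TOI minus ECG).
#'
#' @slot bias mean difference.
#' @slot loaLower,loaUpper 95% limits of agreement (bias +/- 1.96 SD).
#' @slot pearsonR Pearson product-moment correlation of the paired values.
#' @slot n number of pairs.
#' @slot label which measure was compared (e.g. "heart_rate_bpm").
#' @export
setClass("AgreementReport",
    representation(bias = "numeric", loaLower = "numeric", loaUpper = "numeric",
                   pearsonR = "numeric", n = "integer", label = "character"),
    prototype(label = NA_character_))

setValidity("AgreementReport", function(object) {
    if (object@loaLower > object@bias || object@bias > object@loaUpper)
        return("limits of agreement must bracket the bias")
    if (is.finite(object@pearsonR) && abs(object@pearsonR) > 1 + 1e-12)
        return("pearsonR must lie in [-1, 1]")
    TRUE
})
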