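#' Construct an ECGRecord
#'
#' @param t time stamps in seconds (uniform) or NULL to derive from `fs`.
#' @param voltage sampled voltage, arbitrary units.
#' @param fs sampling rate in Hz (default 1000).
#' @return An [ECGRecord-class].
#' @export
ECGRecord <- function(voltage, fs = 1000, t = NULL) {
    if (is.null(t)) t <- (seq_along(voltage) - 1) / fs
    new("ECGRecord", t = as.numeric(t), voltage = as.numeric(voltage),
        fs = as.numeric(fs))
}

#' Voltage samples and time stamps of an ECGRecord
#' @param x an [ECGRecord-class].
#' @export
ecgVoltage <- function(x) { stopifnot(is(x, "ECGRecord")); x@voltage }

#' @rdname ecgVoltage
#' @export
ecgTime <- function(x) { stopifnot(is(x, "ECGRecord")); x@t }

setMethod("show", "ECGRecord", function(object) {
    cat(sprintf("ECGRecord: %.1f s @ %g Hz\n",
                object@t[length(object@t)] - object@t[1], object@fs))
})

#' Read / write an ECG waveform as a time/voltage table
#'
#' CSV with columns `t_s, voltage`; an optional JSON sidecar
#' (`<path>.json` with `{"fs": 1000}`) overrides the sampling rate inferred
#' from the time stamps.
#'
#' @param path CSV file path.
#' @return `readECGRecord` returns an [ECGRecord-class].
#' @export
readECGRecord <- function(path) {
    if (!file.exists(path)) stop("ECG file not found: ", path)
    d <- utils::read.csv(path)
    if (!all(c("t_s", "voltage") %in% names(d)))
        stop("ECG file must have columns 't_s' and 'voltage'")
    side <- paste0(path, ".json")
    fs <- if (file.exists(side))
        jsonlite::read_json(side)$fs else 1 / stats::median(diff(d$t_s))
    ECGRecord(d$voltage, fs = fs, t = d$t_s)
}

#' @rdname readECGRecord
#' @param x an [ECGRecord-class] to write.
#' @export
writeECGRecord <- function(x, path) {
    stopifnot(is(x, "ECGRecord"))
    utils::write.csv(data.frame(t_s = x@t, voltage = x@voltage), path,
                     row.names = FALSE)
    jsonlite::write_json(list(fs = x@fs), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Detect R-wave peaks in an ECG waveform
#'
#' Energy-based detector in the Pan-Tompkins tradition: band-pass 5-35 Hz,
#' squared derivative, 150 ms moving-window integration, adaptive threshold,
#' 250 ms refractory period; each detection is then refined to the local
#' maximum of the band-passed signal within +/- 50 ms. The record is
#' mirror-padded by one second before filtering so that beats at the very
#' start or end of the recording survive the filter and integration edges.
#'
#' The threshold sits a fixed fraction of the way from the noise floor
#' (25th percentile of the integrated energy) to the beat level (99.5th
#' percentile), in the spirit of Pan-Tompkins' signal/noise level tracking.
#' A pure location/scale statistic such as median + k * MAD fails at high
#' heart rates, where the integration window's duty cycle approaches one
#' half and the median no longer estimates the noise floor. Quantile-based
#' thresholding keeps detection invariant to the arbitrary voltage scale.
#'
#' @param record an [ECGRecord-class], non-constant.
#' @param band band-pass edges in Hz.
#' @param integrationMs integration window, ms.
#' @param thresholdFraction position of the threshold between the noise
#'   floor and the beat level (default 0.3).
#' @param refractoryMs minimum distance between beats, ms.
#' @param refineMs half-width of the refinement window, ms.
#' @return A [PeakTrain-class] with source `"ECG"`.
#' @export
detectRPeaks <- function(record, band = c(5, 35), integrationMs = 150,
                         thresholdFraction = 0.3, refractoryMs = 250,
                         refineMs = 50) {
    stopifnot(is(record, "ECGRecord"))
    v <- record@voltage
    fs <- record@fs
    n <- length(v)
    if (stats::sd(v) == 0) stop("no beats detected: constant signal")
    pad <- min(n - 1L, round(fs))
    vp <- c(rev(v[2:(pad + 1L)]), v, rev(v[(n - pad):(n - 1L)]))
    bf <- signal::butter(2, band / (fs / 2), type = "pass")
    filtp <- signal::filtfilt(bf, vp - mean(vp))
    energyp <- c(0, diff(filtp))^2
    win <- max(1L, round(integrationMs / 1000 * fs))
    integp <- as.numeric(stats::filter(energyp, rep(1 / win, win), sides = 2))
    integp[is.na(integp)] <- 0
    filt <- filtp[(pad + 1L):(pad + n)]
    integ <- integp[(pad + 1L):(pad + n)]

    qs <- stats::quantile(integ, c(0.25, 0.995), names = FALSE)
    thr <- qs[1] + thresholdFraction * (qs[2] - qs[1])
    above <- integ > thr
    if (!any(above)) stop("no beats detected: nothing above threshold")
    ## contiguous supra-threshold regions -> one detection each
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    det <- mapply(function(s, e) s - 1L + which.max(integ[s:e]),
                  starts[runs$values], ends[runs$values])

    ## refractory: keep the stronger of any two detections closer than 250 ms
    refr <- refractoryMs / 1000 * fs
    det <- sort(det)
    keep <- rep(TRUE, length(det))
    last <- 1L
    for (i in seq_along(det)[-1]) {
        if (det[i] - det[last] < refr) {
            if (integ[det[i]] > integ[det[last]]) {
                keep[last] <- FALSE; last <- i
            } else keep[i] <- FALSE
        } else last <- i
    }
    det <- det[keep]

    ## refine to the local maximum of the band-passed signal
    half <- round(refineMs / 1000 * fs)
    n <- length(filt)
    peakIdx <- vapply(det, function(i) {
        lo <- max(1L, i - half); hi <- min(n, i + half)
        lo - 1L + which.max(filt[lo:hi])
    }, numeric(1))
    peakIdx <- sort(unique(peakIdx))
    times <- record@t[1] + (peakIdx - 1) / fs
    new("PeakTrain", times = times, source = "ECG")
}
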