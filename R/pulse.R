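#' Construct an HCSignal
#'
#' @param values numeric series (finite, length >= 2).
#' @param fps sampling rate in frames/second.
#' @param roi optional region name.
#' @return An [HCSignal-class].
#' @export
HCSignal <- function(values, fps, roi = NA_character_) {
    new("HCSignal", values = as.numeric(values), fps = as.numeric(fps),
        roi = roi)
}

#' Series values of an HCSignal
#' @param x an [HCSignal-class].
#' @export
signalValues <- function(x) {
    stopifnot(is(x, "HCSignal"))
    x@values
}

setMethod("show", "HCSignal", function(object) {
    cat(sprintf("HCSignal: %d samples @ %g fps (ROI %s)%s\n",
                length(object@values), object@fps, object@roi,
                if (object@degenerate) " [degenerate]" else ""))
})

#' Zero-phase cardiac band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward-backward (zero phase),
#' default band 0.7-4.0 Hz (42-240 beats/min); the mean is removed with the
#' stop-band. The sampling rate must exceed twice the upper band edge.
#'
#' @param x an [HCSignal-class] or numeric vector.
#' @param band `c(f_lo, f_hi)` in Hz.
#' @param fs sampling rate (taken from `x` when it is an HCSignal).
#' @return Filtered object of the same type as `x`.
#' @export
bandpassFilter <- function(x, band = c(0.7, 4.0), fs = NULL) {
    v <- if (is(x, "HCSignal")) x@values else x
    if (is(x, "HCSignal")) fs <- x@fps
    if (is.null(fs)) stop("fs is required for a plain numeric series")
    if (fs <= 2 * band[2])
        stop("band extends above the Nyquist frequency")
    bf <- signal::butter(4, band / (fs / 2), type = "pass")
    y <- signal::filtfilt(bf, v - mean(v))
    if (is(x, "HCSignal")) {
        out <- x
        out@values <- as.numeric(y)
        out
    } else as.numeric(y)
}

## ---- empirical mode decomposition -------------------------------------------

## Strict local extrema (plateaus collapse to their midpoint).
localExtrema <- function(x) {
    n <- length(x)
    dx <- diff(x)
    s <- sign(dx)
    ## carry the sign through flat runs
    for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
    chg <- which(diff(s) != 0) + 1L
    list(max = chg[s[chg - 1L] > 0], min = chg[s[chg - 1L] < 0])
}

## Cubic-spline envelope through extrema, with the first/last two extrema
## mirrored about the series ends to tame boundary swings.
splineEnvelope <- function(idx, val, n) {
    if (length(idx) >= 2) {
        m <- length(idx)
        idx <- c(2 - idx[2], 2 - idx[1], idx,
                 2 * n - idx[m], 2 * n - idx[m - 1])
        val <- c(val[2], val[1], val, val[m], val[m - 1])
        o <- order(idx)
        idx <- idx[o]; val <- val[o]
        keep <- !duplicated(idx)
        idx <- idx[keep]; val <- val[keep]
    }
    stats::spline(idx, val, xout = seq_len(n), method = "fmm")$y
}

#' Empirical mode decomposition
#'
#' Standard sifting: intrinsic mode functions are extracted by repeated
#' subtraction of the mean of the cubic-spline envelopes of the maxima and
#' minima, using the two-threshold stopping criterion of Rilling
#' (theta1 = 0.05 on 95% of samples, theta2 = 0.5 everywhere), capped at 10
#' IMFs and 50 sifts per IMF. Decomposition stops when the residue has
#' fewer than three extrema. The decomposition is complete by construction:
#' the IMFs plus the residue sum back to the input.
#'
#' @param x an [HCSignal-class] or numeric vector (length >= 16,
#'   non-constant).
#' @param fs sampling rate (taken from `x` when it is an HCSignal).
#' @param maxIMF cap on the number of IMFs.
#' @param maxSift cap on sifting iterations per IMF.
#' @return An [IMFSet-class].
#' @export
emd <- function(x, fs = NULL, maxIMF = 10L, maxSift = 50L) {
    v <- if (is(x, "HCSignal")) x@values else as.numeric(x)
    if (is(x, "HCSignal")) fs <- x@fps
    if (is.null(fs)) fs <- 1
    n <- length(v)
    if (n < 16L) stop("at least 16 samples are required")
    if (stats::sd(v) == 0) stop("constant input has no oscillatory modes")

    imfs <- list()
    resid <- v
    for (k in seq_len(maxIMF)) {
        ex <- localExtrema(resid)
        if (length(ex$max) + length(ex$min) < 3L) break
        h <- resid
        for (s in seq_len(maxSift)) {
            ex <- localExtrema(h)
            if (length(ex$max) < 2L || length(ex$min) < 2L) break
            upper <- splineEnvelope(ex$max, h[ex$max], n)
            lower <- splineEnvelope(ex$min, h[ex$min], n)
            m <- (upper + lower) / 2
            a <- (upper - lower) / 2
            sigma <- abs(m) / pmax(abs(a), .Machine$double.eps)
            if (mean(sigma < 0.05) >= 0.95 && all(sigma < 0.5)) {
                h <- h - m
                break
            }
            h <- h - m
        }
        imfs[[k]] <- h
        resid <- resid - h
    }
    if (!length(imfs)) stop("no intrinsic mode could be extracted")
    new("IMFSet", imfs = do.call(cbind, imfs), residue = resid,
        fps = as.numeric(fs))
}

#' IMF matrix and residue of an IMFSet
#' @param x an [IMFSet-class].
#' @export
imfMatrix <- function(x) { stopifnot(is(x, "IMFSet")); x@imfs }

#' @rdname imfMatrix
#' @export
imfResidue <- function(x) { stopifnot(is(x, "IMFSet")); x@residue }

setMethod("show", "IMFSet", function(object) {
    cat(sprintf("IMFSet: %d IMFs of %d samples @ %g Hz\n",
                ncol(object@imfs), nrow(object@imfs), object@fps))
})

## ---- Hilbert spectral stage -------------------------------------------------

## Analytic signal via the frequency-domain Hilbert transform.
analyticSignal <- function(x) {
    n <- length(x)
    X <- stats::fft(x)
    h <- numeric(n)
    if (n %% 2 == 0) {
        h[c(1, n / 2 + 1)] <- 1
        h[2:(n / 2)] <- 2
    } else {
        h[1] <- 1
        h[2:((n + 1) / 2)] <- 2
    }
    stats::fft(X * h, inverse = TRUE) / n
}

## Instantaneous frequency (Hz) of an analytic signal.
instantaneousFrequency <- function(z, fs) {
    ph <- signal::unwrap(Arg(z))
    diff(ph) * fs / (2 * pi)
}

#' Principal cardiac frequency of an IMF set
#'
#' For each IMF the analytic signal gives the instantaneous phase, hence an
#' amplitude-weighted mean instantaneous frequency, and the averaged
#' periodogram gives the fraction of its power inside the cardiac band. The
#' cardiac component is the sum of all IMFs that hold the majority of their
#' power in band: sifting can split one physiological oscillation across
#' neighbouring IMFs (mode mixing), and summing the in-band modes restores
#' it. When no IMF passes the majority rule, the single in-band-mean-
#' frequency IMF with the greatest in-band power is used; when there is no
#' in-band IMF at all the decomposition holds no cardiac component and an
#' error is raised. The principal frequency is the amplitude-weighted mean
#' instantaneous frequency of the combined component (heart rate =
#' 60 x f_principal beats/min).
#'
#' @param x an [IMFSet-class].
#' @param band cardiac band in Hz.
#' @return List with `imf` (the cardiac component series), `index` (columns
#'   combined), and `frequency` (Hz).
#' @export
principalFrequency <- function(x, band = c(0.7, 4.0)) {
    stopifnot(is(x, "IMFSet"))
    fs <- x@fps
    k <- ncol(x@imfs)
    meanF <- rep(NA_real_, k)
    pin <- numeric(k)
    frac <- numeric(k)
    for (i in seq_len(k)) {
        v <- x@imfs[, i]
        if (stats::sd(v) == 0) next
        z <- analyticSignal(v)
        f <- instantaneousFrequency(z, fs)
        a <- (Mod(z)[-1] + Mod(z)[-length(z)]) / 2
        meanF[i] <- sum(f * a) / sum(a)
        sp <- welchPSD(v, fs)
        pw <- bandPowerSplit(sp$freq, sp$psd, band)
        pin[i] <- pw["pin"]
        frac[i] <- pw["pin"] / max(pw["pin"] + pw["pout"],
                                   .Machine$double.xmin)
    }
    sel <- which(frac > 0.5)
    if (!length(sel)) {
        ok <- which(is.finite(meanF) & meanF >= band[1] & meanF <= band[2])
        if (!length(ok)) stop("no cardiac component in the decomposition")
        sel <- ok[which.max(pin[ok])]
    }
    comp <- if (length(sel) == 1L) x@imfs[, sel] else
        rowSums(x@imfs[, sel, drop = FALSE])
    z <- analyticSignal(comp)
    f <- instantaneousFrequency(z, fs)
    a <- (Mod(z)[-1] + Mod(z)[-length(z)]) / 2
    list(imf = comp, index = sel, frequency = sum(f * a) / sum(a))
}

## ---- peak reconstruction ----------------------------------------------------

## Sub-sample refinement: vertex of the parabola through the three samples
## around a local maximum.
refineQuadratic <- function(v, i) {
    if (i <= 1L || i >= length(v)) return(i)
    den <- v[i - 1] - 2 * v[i] + v[i + 1]
    if (den >= 0) return(i)
    i + 0.5 * (v[i - 1] - v[i + 1]) / den
}

#' Reconstruct heartbeat peaks from the cardiac IMF
#'
#' Peak times are the local maxima of the cardiac intrinsic mode component,
#' refined by quadratic interpolation of the three samples around each
#' maximum. The first and last second are excluded (filter and
#' decomposition edge artifacts). The implied instantaneous rate is
#' confined using the synthesized frequency: peaks closer than
#' `mergeFraction` principal periods (or `1/band[2]` when no principal
#' frequency is supplied) are merged keeping the larger amplitude. A
#' beat-to-beat interval shortening below about half the principal period
#' is not physiological; without this guard, in-band noise riding the
#' cardiac oscillation inserts spurious beats at heart rates near the low
#' band edge.
#'
#' @param imf numeric vector, the cardiac component from
#'   [principalFrequency()].
#' @param fs sampling rate in Hz.
#' @param band cardiac band in Hz.
#' @param principalHz optional principal frequency from
#'   [principalFrequency()] used for the merge distance.
#' @param mergeFraction minimum peak spacing in principal periods.
#' @param edgeTrim seconds excluded at each end.
#' @return A [PeakTrain-class] with source `"TOI"`.
#' @export
reconstructPeaks <- function(imf, fs, band = c(0.7, 4.0), principalHz = NULL,
                             mergeFraction = 0.55, edgeTrim = 1) {
    n <- length(imf)
    ex <- localExtrema(imf)
    idx <- ex$max
    lo <- edgeTrim * fs
    hi <- n - edgeTrim * fs
    idx <- idx[idx > lo & idx < hi]
    if (length(idx) >= 2) {
        ## merge peaks violating the refractory distance, keep the larger
        minGap <- if (is.null(principalHz)) fs / band[2] else
            max(fs / band[2], mergeFraction * fs / principalHz)
        keep <- rep(TRUE, length(idx))
        last <- 1L
        for (i in seq_along(idx)[-1]) {
            if (idx[i] - idx[last] < minGap) {
                if (imf[idx[i]] > imf[idx[last]]) {
                    keep[last] <- FALSE; last <- i
                } else keep[i] <- FALSE
            } else last <- i
        }
        idx <- idx[keep]
    }
    if (length(idx) < 3L) stop("insufficient beats: fewer than 3 peaks")
    times <- vapply(idx, function(i) (refineQuadratic(imf, i) - 1) / fs,
                    numeric(1))
    new("PeakTrain", times = times, source = "TOI")
}

#' Construct a PeakTrain
#'
#' @param times strictly increasing peak times in seconds.
#' @param source `"TOI"`, `"ECG"` or `"truth"`.
#' @return A [PeakTrain-class].
#' @export
PeakTrain <- function(times, source = "TOI") {
    new("PeakTrain", times = as.numeric(times), source = source)
}

#' @rdname PeakTrain-accessors
#' @export
setMethod("peakTimes", "PeakTrain", function(x) x@times)

#' @rdname RRISeries-accessors
#' @export
setMethod("sourceTag", "PeakTrain", function(x) x@source)

setMethod("show", "PeakTrain", function(object) {
    cat(sprintf("PeakTrain (%s): %d peaks over %.1f s\n", object@source,
                length(object@times),
                if (length(object@times)) diff(range(object@times)) else 0))
})
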