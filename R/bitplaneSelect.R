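#' Construct BitplaneWeights
#'
#' Signed coefficients in {-1, 0, +1}, one per (channel, bit). The
#' hemoglobin-concentration image is composed by pixel-wise addition and
#' subtraction of the selected bitplanes; planes enter unscaled (no 2^bit
#' positional weight), the selector learns each plane's usefulness directly.
#'
#' @param w named numeric vector; names from [bitplaneLabels()] (e.g. "G7");
#'   omitted planes get coefficient 0.
#' @return A [BitplaneWeights-class].
#' @examples
#' BitplaneWeights(c(G7 = 1, G6 = 1, R0 = -1))
#' @export
BitplaneWeights <- function(w = numeric()) {
    full <- setNames(numeric(24), bitplaneLabels())
    if (length(w)) {
        if (is.null(names(w)) || !all(names(w) %in% bitplaneLabels()))
            stop("weights must be named with bitplane labels (e.g. 'G7')")
        full[names(w)] <- w
    }
    new("BitplaneWeights", w = full)
}

#' Coefficient vector of a BitplaneWeights object
#'
#' @param x a [BitplaneWeights-class].
#' @return Named numeric vector of length 24.
#' @export
weightVector <- function(x) {
    stopifnot(is(x, "BitplaneWeights"))
    x@w
}

setMethod("show", "BitplaneWeights", function(object) {
    nz <- object@w[object@w != 0]
    if (!length(nz)) {
        cat("BitplaneWeights: all zero\n")
    } else {
        cat("BitplaneWeights:",
            paste(sprintf("%s%s", ifelse(nz > 0, "+", "-"), names(nz)),
                  collapse = " "), "\n")
    }
})

#' Read / write a bitplane-weights file
#'
#' JSON layout: `{"weights": {"G7": 1, "R0": -1, ...}, "band": [0.7, 4.0]}`;
#' omitted planes are 0.
#'
#' @param path JSON file path.
#' @return `readBitplaneWeights` returns a [BitplaneWeights-class] with the
#'   cardiac band attached as attribute `"band"`.
#' @export
readBitplaneWeights <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    w <- BitplaneWeights(unlist(x$weights))
    attr(w, "band") <- as.numeric(x$band)
    w
}

#' @rdname readBitplaneWeights
#' @param weights a [BitplaneWeights-class].
#' @param band cardiac band in Hz recorded alongside the weights.
#' @export
writeBitplaneWeights <- function(weights, path, band = c(0.7, 4.0)) {
    v <- weightVector(weights)
    jsonlite::write_json(list(weights = as.list(v[v != 0]), band = band),
                         path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Compose a hemoglobin-concentration signal from weighted bitplanes
#'
#' Pixel-wise signed sum of the selected bitplanes, then averaged over the
#' region of interest. Because both steps are linear the composition is
#' evaluated on per-ROI bitplane means (see [bitplaneROIMeans()]).
#'
#' @param x a [FrameStack-class], or a `T x 24` bitplane-mean matrix from
#'   [bitplaneROIMeans()].
#' @param weights a [BitplaneWeights-class].
#' @param roi logical mask (required when `x` is a FrameStack).
#' @param fps frame rate (required when `x` is a matrix).
#' @param roiName label stored on the output.
#' @return An [HCSignal-class]; its `degenerate` flag is set when all
#'   weights are zero.
#' @export
composeSignal <- function(x, weights, roi = NULL, fps = NULL,
                          roiName = NA_character_) {
    w <- weightVector(weights)
    if (is(x, "FrameStack")) {
        if (is.null(roi)) stop("a ROI mask is required with a FrameStack")
        B <- bitplaneROIMeans(x, ROIMap(list(roi = roi)))[[1]]
        fps <- fps(x)
    } else if (is.matrix(x) && ncol(x) == 24L) {
        B <- x
        if (is.null(fps)) stop("fps is required with a bitplane-mean matrix")
    } else stop("x must be a FrameStack or a T x 24 bitplane-mean matrix")
    new("HCSignal", values = as.numeric(B %*% w), fps = fps,
        roi = roiName, degenerate = all(w == 0))
}

## ---- Welch spectral machinery ----------------------------------------------

hannWindow <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))

#' Averaged (Welch) periodogram
#'
#' Mean-removed, Hann-windowed, overlapping-segment averaged periodogram;
#' the spectral estimator behind the cardiac-band SNR objective.
#'
#' @param x numeric series.
#' @param fs sampling rate in Hz.
#' @param nseg number of segments (default 8).
#' @param overlap fractional overlap between segments (default 0.5).
#' @return List with `freq` (Hz, one-sided) and `psd`.
#' @export
welchPSD <- function(x, fs, nseg = 8, overlap = 0.5) {
    plan <- welchPlan(matrix(x, ncol = 1), fs, nseg, overlap)
    p <- welchPower(plan, 1)
    list(freq = plan$freq, psd = p)
}

## Precompute per-segment FFTs of every column of B so that the spectrum of
## any weighted combination B %*% w is the same combination of column
## spectra (demean, window and FFT are linear in the segment samples).
welchPlan <- function(B, fs, nseg = 8, overlap = 0.5) {
    n <- nrow(B)
    L <- floor(n / ((nseg - 1) * (1 - overlap) + 1))
    if (L < 8) stop("series too short for the requested segmentation")
    step <- max(1L, floor(L * (1 - overlap)))
    starts <- seq(1L, n - L + 1L, by = step)
    win <- hannWindow(L)
    scale <- 1 / (fs * sum(win^2) * length(starts))
    nh <- floor(L / 2) + 1L
    segs <- lapply(starts, function(s) {
        X <- B[s:(s + L - 1L), , drop = FALSE]
        X <- sweep(X, 2L, colMeans(X))
        stats::mvfft(X * win)[seq_len(nh), , drop = FALSE]
    })
    list(segs = segs, freq = (seq_len(nh) - 1) * fs / L, scale = scale,
         fs = fs, n = n)
}

## One-sided PSD of B %*% w given a plan (w may be a column index for speed).
welchPower <- function(plan, w) {
    acc <- 0
    for (Fm in plan$segs) {
        V <- if (length(w) == 1L) Fm[, w] else as.vector(Fm %*% w)
        acc <- acc + Re(V)^2 + Im(V)^2
    }
    p <- acc * plan$scale
    nh <- length(p)
    p[2:(nh - 1)] <- 2 * p[2:(nh - 1)]
    p
}

bandPowerSplit <- function(freq, psd, band, floorHz = 0.05) {
    inb <- freq >= band[1] & freq <= band[2]
    outb <- freq >= floorHz & !inb
    c(pin = sum(psd[inb]), pout = sum(psd[outb]))
}

#' Cardiac-band spectral signal-to-noise ratio
#'
#' `10 log10(P_in / P_out)` where `P_in` is averaged-periodogram power inside
#' the cardiac band and `P_out` the power in `[0.05 Hz, Nyquist]` outside it.
#' This is the objective the bitplane selector maximises: a stand-in for
#' "signal differentiation with regard to facial cardiovascular activity"
#' that is measurable without contact-instrument ground truth.
#'
#' @param series numeric time series (at least `10 * fs / band[1]` samples,
#'   i.e. ten slow cycles).
#' @param fs sampling rate in Hz.
#' @param band cardiac band `c(f_lo, f_hi)` in Hz; default 0.7-4.0
#'   (42-240 beats/min).
#' @return SNR in dB.
#' @export
snrObjective <- function(series, fs, band = c(0.7, 4.0)) {
    if (any(!is.finite(series))) stop("series must be finite")
    if (length(series) < 10 * fs / band[1])
        stop("series too short: need at least ten cycles of the slow band edge")
    if (stats::sd(series) == 0) stop("constant series has zero power")
    sp <- welchPSD(series, fs)
    pw <- bandPowerSplit(sp$freq, sp$psd, band)
    10 * log10(pw["pin"] / pw["pout"])
}

## ---- greedy selection -------------------------------------------------------

## Enumeration order for candidate moves: R before G before B, bit 7 down to
## bit 0, sign +1 before -1 (then removal). Fixed order makes ties, and hence
## the whole selection, deterministic.
candidateOrder <- function(planes = bitplaneLabels()) {
    ord <- as.vector(t(outer(CHANNELS, 7:0, paste0)))
    ord[ord %in% planes]
}

snrPerROI <- function(plans, Vcur, band) {
    vapply(seq_along(plans), function(r) {
        p <- 0
        for (s in seq_along(Vcur[[r]])) {
            V <- Vcur[[r]][[s]]
            p <- p + Re(V)^2 + Im(V)^2
        }
        p <- p * plans[[r]]$scale
        nh <- length(p)
        p[2:(nh - 1)] <- 2 * p[2:(nh - 1)]
        pw <- bandPowerSplit(plans[[r]]$freq, p, band)
        if (pw["pout"] <= 0 || pw["pin"] <= 0) return(-Inf)
        10 * log10(pw["pin"] / pw["pout"])
    }, numeric(1))
}

#' Select bitplane weights by greedy cardiac-band SNR ascent
#'
#' Starting from all-zero weights, repeatedly applies the single
#' (channel, bit, sign) change that most increases the mean training-split
#' SNR across ROIs, until the improvement falls below `snrTolerance` or
#' `maxIterations` accepted steps. The recording is split along the time
#' axis: the first `trainFraction` is the training split, the remainder the
#' validation split.
#'
#' The greedy objective is the mean SNR across all ROIs; the reported
#' `snrTrain`/`snrValidation` are the SNR of the best ROI under the final
#' weights, since that is the ROI the pulse stage consumes (the pulse need
#' not reach every facial region). `snrValidation` is `NA` when the
#' validation split is shorter than ten slow-band cycles. The `converged`
#' flag is `TRUE` when at least one plane was selected and the best-ROI
#' training SNR is positive (in-band power exceeds out-of-band power); on a
#' noise-only recording no composition reaches that, `converged` is `FALSE`
#' and all-zero weights are returned.
#'
#' @param x a [FrameStack-class], or a named list of `T x 24` bitplane-mean
#'   matrices (one per ROI) from [bitplaneROIMeans()].
#' @param roiMap an [ROIMap-class] (required when `x` is a FrameStack).
#' @param fs frame rate (required when `x` is a list of matrices).
#' @param band cardiac band in Hz.
#' @param trainFraction fraction of the time axis used for training
#'   (0.7, 0.8 or 0.9; default 0.8).
#' @param snrTolerance minimum accepted improvement per step, dB.
#' @param maxIterations cap on accepted greedy steps.
#' @param planes candidate plane labels (default: all 24); restricting the
#'   set supports small exhaustive cross-checks.
#' @param seed accepted for interface stability; the search is fully
#'   deterministic (ties are broken by the fixed enumeration order
#'   R-G-B, bit 7 down to 0, +1 before -1).
#' @return A [SelectionReport-class].
#' @export
selectBitplaneWeights <- function(x, roiMap = NULL, fs = NULL,
                                  band = c(0.7, 4.0), trainFraction = 0.8,
                                  snrTolerance = 0.5, maxIterations = 24L,
                                  planes = bitplaneLabels(), seed = NULL) {
    if (is(x, "FrameStack")) {
        if (is.null(roiMap)) stop("roiMap is required with a FrameStack")
        fs <- fps(x)
        B <- bitplaneROIMeans(x, roiMap)
    } else if (is.list(x) && all(vapply(x, is.matrix, logical(1)))) {
        if (is.null(fs)) stop("fs is required with bitplane-mean matrices")
        B <- x
    } else stop("x must be a FrameStack or a list of T x 24 matrices")
    if (!trainFraction %in% c(0.7, 0.8, 0.9))
        stop("trainFraction must be one of 0.7, 0.8, 0.9")

    n <- nrow(B[[1]])
    nTrain <- floor(trainFraction * n)
    if (nTrain < 10 * fs / band[1])
        stop("training split too short for the SNR objective")
    plans <- lapply(B, function(m)
        welchPlan(m[seq_len(nTrain), , drop = FALSE], fs))

    labs <- bitplaneLabels()
    w <- setNames(numeric(24), labs)
    ## running spectra of the composed signal per ROI per segment
    Vcur <- lapply(plans, function(pl)
        lapply(pl$segs, function(Fm) complex(real = numeric(nrow(Fm)))))
    score <- -Inf
    cand <- candidateOrder(planes)
    trace <- list()

    repeat {
        best <- list(score = -Inf)
        for (pl in cand) {
            j <- match(pl, labs)
            for (val in c(1, -1, 0)) {
                if (val == w[j]) next
                delta <- val - w[j]
                Vtry <- lapply(seq_along(plans), function(r)
                    lapply(seq_along(plans[[r]]$segs), function(s)
                        Vcur[[r]][[s]] + delta * plans[[r]]$segs[[s]][, j]))
                sc <- mean(snrPerROI(plans, Vtry, band))
                if (sc > best$score)
                    best <- list(score = sc, j = j, val = val, V = Vtry)
            }
        }
        improvement <- if (is.infinite(score)) Inf else best$score - score
        if (!is.finite(best$score) || improvement < snrTolerance)
            break
        w[best$j] <- best$val
        Vcur <- best$V
        score <- best$score
        trace[[length(trace) + 1L]] <- data.frame(
            plane = labs[best$j], value = best$val, objective = score)
        if (length(trace) >= maxIterations) break
        if (all(w == 0)) break   # removal emptied the weights
    }

    ## report the SNR of the best ROI under the final weights: that is the
    ## ROI the pulse stage consumes, and on a noise-only recording even the
    ## best ROI stays below 0 dB (in-band power below out-of-band power)
    perROI <- snrPerROI(plans, Vcur, band)
    bestROI <- which.max(perROI)
    snrTrain <- if (any(w != 0)) perROI[bestROI] else -Inf
    converged <- any(w != 0) && is.finite(snrTrain) && snrTrain > 0
    if (!converged) w[] <- 0
    weights <- BitplaneWeights(w[w != 0])

    snrVal <- NA_real_
    nVal <- n - nTrain
    if (converged && nVal >= 10 * fs / band[1]) {
        s <- as.numeric(B[[bestROI]][(nTrain + 1):n, , drop = FALSE] %*% w)
        snrVal <- if (stats::sd(s) == 0) -Inf else snrObjective(s, fs, band)
    }

    new("SelectionReport", weights = weights,
        snrTrain = if (converged) snrTrain else -Inf,
        snrValidation = snrVal, iterations = length(trace),
        converged = converged,
        trace = if (length(trace)) do.call(rbind, trace) else
            data.frame(plane = character(), value = numeric(),
                       objective = numeric()))
}

setMethod("show", "SelectionReport", function(object) {
    cat(sprintf("SelectionReport: %s after %d steps\n",
                if (object@converged) "converged" else "no cardiac component",
                object@iterations))
    show(object@weights)
    cat(sprintf("  SNR train %.2f dB, validation %.2f dB\n",
                object@snrTrain, object@snrValidation))
})
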