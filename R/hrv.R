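#' Construct an RRISeries
#'
#' @param rri positive intervals in milliseconds.
#' @param source `"TOI"`, `"ECG"` or `"truth"`.
#' @return An [RRISeries-class].
#' @export
RRISeries <- function(rri, source = "TOI") {
    new("RRISeries", rri = as.numeric(rri), source = source)
}

#' @rdname RRISeries-accessors
#' @export
setMethod("intervals", "RRISeries", function(x) x@rri)

#' @rdname RRISeries-accessors
#' @export
setMethod("sourceTag", "RRISeries", function(x) x@source)

setMethod("show", "RRISeries", function(object) {
    cat(sprintf("RRISeries (%s): %d intervals, mean %.1f ms\n",
                object@source, length(object@rri), mean(object@rri)))
})

#' Flag physiologically implausible intervals
#'
#' Intervals outside 250-2500 ms (240 down to 24 beats/min) are flagged
#' rather than rejected; real and synthetic artifacts both produce them.
#'
#' @param x an [RRISeries-class].
#' @param range plausible interval range in ms.
#' @return Logical vector, `TRUE` where implausible.
#' @export
implausibleIntervals <- function(x, range = c(250, 2500)) {
    r <- intervals(x)
    r < range[1] | r > range[2]
}

#' R-R intervals from a peak train
#'
#' @param peaks a [PeakTrain-class] with at least 2 peaks.
#' @return An [RRISeries-class] carrying the peak train's source tag
#'   (`"truth"` maps to the interval source `"truth"`).
#' @examples
#' rriFromPeaks(PeakTrain(c(0, 1, 2)))   # 1000, 1000 ms
#' @export
rriFromPeaks <- function(peaks) {
    stopifnot(is(peaks, "PeakTrain"))
    t <- peakTimes(peaks)
    if (length(t) < 2L) stop("at least 2 peaks are required")
    RRISeries(1000 * diff(t), source = sourceTag(peaks))
}

#' Mean heart rate of an RRI series
#'
#' `60000 / mean(rri_ms)`: beats per elapsed time, not the mean of per-beat
#' rates.
#'
#' @param rri an [RRISeries-class] or numeric vector of intervals in ms.
#' @return Heart rate in beats/minute.
#' @export
heartRate <- function(rri) {
    r <- if (is(rri, "RRISeries")) intervals(rri) else as.numeric(rri)
    if (!length(r)) stop("empty RRI series")
    60000 / mean(r)
}

#' Poincare-plot summary of an RRI series
#'
#' The Poincare plot scatters RR(n) against RR(n+1). SD1, the dispersion
#' perpendicular to the identity line, is `(sqrt(2)/2) * SD(RRn - RRn+1)`;
#' SD2, the dispersion along it, is
#' `sqrt(2 * SD(RRn)^2 - (1/2) * SD(RRn - RRn+1)^2)`. Sample (n-1) standard
#' deviations are used throughout. SD1/SD2 is the stress index; lower
#' ratios indicate higher basal stress. A numerically negative SD2 radicand
#' (possible for short anti-correlated series) is clamped to zero and
#' flagged; the ratio is `NA` whenever SD2 is zero.
#'
#' @param rri an [RRISeries-class] or numeric vector (at least 3 intervals).
#' @return A [PoincareSummary-class].
#' @examples
#' poincare(c(1000, 950, 1000, 1050, 1000))
#' @export
poincare <- function(rri) {
    src <- if (is(rri, "RRISeries")) sourceTag(rri) else "TOI"
    r <- if (is(rri, "RRISeries")) intervals(rri) else as.numeric(rri)
    n <- length(r)
    if (n < 3L) stop("at least 3 intervals are required")
    d <- r[-n] - r[-1]                       # RR(n) - RR(n+1)
    sdd <- stats::sd(d)
    sd1 <- sqrt(2) / 2 * sdd
    rad <- 2 * stats::sd(r)^2 - 0.5 * sdd^2
    flags <- character()
    if (rad < 0) {
        rad <- 0
        flags <- c(flags, "sd2_radicand_clamped")
    }
    sd2 <- sqrt(rad)
    ratio <- if (sd2 > 0) sd1 / sd2 else NA_real_
    if (sd2 == 0) flags <- c(flags, "sd_ratio_undefined")
    if (is(rri, "RRISeries") && any(implausibleIntervals(rri)))
        flags <- c(flags, "implausible_intervals")
    new("PoincareSummary", sd1 = sd1, sd2 = sd2, sdRatio = ratio,
        heartRate = heartRate(r), n = as.integer(n), flags = flags)
}

#' Accessors for PoincareSummary
#' @param x a [PoincareSummary-class].
#' @name PoincareSummary-accessors
#' @export
sd1 <- function(x) { stopifnot(is(x, "PoincareSummary")); x@sd1 }

#' @rdname PoincareSummary-accessors
#' @export
sd2 <- function(x) { stopifnot(is(x, "PoincareSummary")); x@sd2 }

#' @rdname PoincareSummary-accessors
#' @export
sdRatio <- function(x) { stopifnot(is(x, "PoincareSummary")); x@sdRatio }

#' @rdname PoincareSummary-accessors
#' @export
summaryHeartRate <- function(x) {
    stopifnot(is(x, "PoincareSummary")); x@heartRate
}

#' @rdname PoincareSummary-accessors
#' @export
summaryFlags <- function(x) { stopifnot(is(x, "PoincareSummary")); x@flags }

setMethod("show", "PoincareSummary", function(object) {
    cat(sprintf(
        "PoincareSummary: HR %.2f bpm, SD1 %.2f ms, SD2 %.2f ms, SD1/SD2 %s (n=%d)\n",
        object@heartRate, object@sd1, object@sd2,
        if (is.na(object@sdRatio)) "NA" else sprintf("%.3f", object@sdRatio),
        object@n))
    if (length(object@flags))
        cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

#' Serialise a PoincareSummary to JSON
#'
#' @param x a [PoincareSummary-class].
#' @param source originating branch recorded in the report.
#' @param path output path.
#' @export
writePoincareSummary <- function(x, path, source = "TOI") {
    stopifnot(is(x, "PoincareSummary"))
    jsonlite::write_json(list(
        source = source, heart_rate_bpm = x@heartRate, sd1_ms = x@sd1,
        sd2_ms = x@sd2, sd_ratio = x@sdRatio, n_intervals = x@n,
        flags = as.list(x@flags)), path, auto_unbox = TRUE, digits = NA,
        na = "null")
    invisible(path)
}

#' Match detected peaks to reference peaks
#'
#' Greedy nearest-neighbour matching within a tolerance; each reference peak
#' is matched to at most one detection and vice versa. Used to score
#' detector sensitivity and to align recovered and true R-R interval series
#' beat by beat.
#'
#' @param detected,reference [PeakTrain-class] objects or numeric times (s).
#' @param toleranceS maximum absolute time difference for a match.
#' @return List with `pairs` (two-column matrix of indices into reference
#'   and detected), `sensitivity`, and `falsePositives` (unmatched
#'   detections).
#' @export
matchPeaks <- function(detected, reference, toleranceS = 0.1) {
    dt <- if (is(detected, "PeakTrain")) peakTimes(detected) else detected
    rt <- if (is(reference, "PeakTrain")) peakTimes(reference) else reference
    usedD <- rep(FALSE, length(dt))
    pairs <- matrix(integer(), ncol = 2,
                    dimnames = list(NULL, c("reference", "detected")))
    for (i in seq_along(rt)) {
        j <- which(!usedD & abs(dt - rt[i]) <= toleranceS)
        if (length(j)) {
            j <- j[which.min(abs(dt[j] - rt[i]))]
            usedD[j] <- TRUE
            pairs <- rbind(pairs, c(i, j))
        }
    }
    list(pairs = pairs,
         sensitivity = nrow(pairs) / max(1L, length(rt)),
         falsePositives = sum(!usedD))
}

#' Beat-aligned RRI comparison of two peak trains
#'
#' Matches detected to reference peaks, then forms R-R intervals on
#' consecutive matched reference beats only, yielding two aligned interval
#' series suitable for correlation against ground truth.
#'
#' @inheritParams matchPeaks
#' @return List with numeric vectors `detected` and `reference` (ms).
#' @export
alignedRRI <- function(detected, reference, toleranceS = 0.4) {
    dt <- if (is(detected, "PeakTrain")) peakTimes(detected) else detected
    rt <- if (is(reference, "PeakTrain")) peakTimes(reference) else reference
    m <- matchPeaks(dt, rt, toleranceS)
    p <- m$pairs
    if (nrow(p) < 3L) stop("too few matched beats to form intervals")
    consec <- which(diff(p[, "reference"]) == 1L)
    list(detected = 1000 * (dt[p[consec + 1L, "detected"]] -
                            dt[p[consec, "detected"]]),
         reference = 1000 * (rt[p[consec + 1L, "reference"]] -
                             rt[p[consec, "reference"]]))
}
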