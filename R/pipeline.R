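#' Run the full transdermal pipeline on one recording
#'
#' Bitplane ROI means are computed once; weights are selected by greedy
#' cardiac-band SNR ascent (unless supplied); the hemoglobin-concentration
#' signal of the ROI with the highest cardiac-band SNR (overridable) is
#' band-pass filtered, decomposed by empirical mode decomposition, the
#' cardiac intrinsic mode function is selected through the Hilbert stage,
#' and heartbeat peaks, R-R intervals and the Poincare summary are derived
#' from it.
#'
#' @param video a [FrameStack-class].
#' @param roiMap an [ROIMap-class].
#' @param weights optional [BitplaneWeights-class]; selected when `NULL`.
#' @param band cardiac band in Hz.
#' @param trainFraction training fraction for weight selection.
#' @param roi optional ROI name to force instead of the highest-SNR ROI.
#' @param snrTolerance,maxIterations passed to [selectBitplaneWeights()].
#' @return List with `selection` ([SelectionReport-class] or `NULL`),
#'   `weights`, `roi`, `roiSNR` (per-ROI cardiac SNR, dB), `hc`
#'   ([HCSignal-class], filtered), `imfs`, `principal` (selected IMF,
#'   index, frequency), `peaks`, `rri`, `poincare`.
#' @export
toiPipeline <- function(video, roiMap, weights = NULL, band = c(0.7, 4.0),
                        trainFraction = 0.8, roi = NULL,
                        snrTolerance = 0.5, maxIterations = 24L) {
    stopifnot(is(video, "FrameStack"), is(roiMap, "ROIMap"))
    B <- bitplaneROIMeans(video, roiMap)
    fsHz <- fps(video)

    selection <- NULL
    if (is.null(weights)) {
        selection <- selectBitplaneWeights(
            B, fs = fsHz, band = band, trainFraction = trainFraction,
            snrTolerance = snrTolerance, maxIterations = maxIterations)
        if (!selection@converged)
            stop("toi_extract: no cardiac component (selection did not converge)")
        weights <- selection@weights
    }
    w <- weightVector(weights)

    roiSNR <- vapply(B, function(m) {
        s <- as.numeric(m %*% w)
        if (stats::sd(s) == 0) return(-Inf)
        snrObjective(s, fsHz, band)
    }, numeric(1))
    if (is.null(roi)) roi <- names(roiSNR)[which.max(roiSNR)]

    hc <- composeSignal(B[[roi]], weights, fps = fsHz, roiName = roi)
    if (hc@degenerate) stop("toi_extract: degenerate (all-zero) weights")
    filtered <- bandpassFilter(hc, band)
    imfs <- emd(filtered)
    principal <- principalFrequency(imfs, band)
    peaks <- reconstructPeaks(principal$imf, fsHz, band,
                              principalHz = principal$frequency)
    rri <- rriFromPeaks(peaks)
    list(selection = selection, weights = weights, roi = roi,
         roiSNR = roiSNR, hc = filtered, imfs = imfs,
         principal = principal, peaks = peaks, rri = rri,
         poincare = poincare(rri))
}

#' Run the ECG reference branch
#'
#' R-wave detection followed by R-R intervals and the Poincare summary.
#'
#' @param record an [ECGRecord-class].
#' @param ... passed to [detectRPeaks()].
#' @return List with `peaks`, `rri`, `poincare`.
#' @export
ecgPipeline <- function(record, ...) {
    peaks <- detectRPeaks(record, ...)
    rri <- rriFromPeaks(peaks)
    list(peaks = peaks, rri = rri, poincare = poincare(rri))
}

#' Compare the TOI and ECG branches of one subject
#'
#' Runs both branches and, when `outDir` is given, writes the two Poincare
#' summaries as JSON (`toi_summary.json`, `ecg_summary.json`).
#'
#' @param video a [FrameStack-class].
#' @param roiMap an [ROIMap-class].
#' @param ecg an [ECGRecord-class].
#' @param outDir optional output directory.
#' @param ... passed to [toiPipeline()].
#' @return List with `toi` and `ecg` branch results.
#' @export
runCompare <- function(video, roiMap, ecg, outDir = NULL, ...) {
    toi <- withCallingHandlers(
        toiPipeline(video, roiMap, ...),
        error = function(e) stop("toi branch: ", conditionMessage(e)))
    ref <- withCallingHandlers(
        ecgPipeline(ecg),
        error = function(e) stop("ecg branch: ", conditionMessage(e)))
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        writePoincareSummary(toi$poincare,
                             file.path(outDir, "toi_summary.json"), "TOI")
        writePoincareSummary(ref$poincare,
                             file.path(outDir, "ecg_summary.json"), "ECG")
    }
    list(toi = toi, ecg = ref)
}

#' Batch comparison over a subject manifest
#'
#' The manifest is a data.frame (or CSV path) with columns `subject_id`,
#' `video_path`, `roi_path`, `ecg_path`. Each subject is run through both
#' branches; Bland-Altman/correlation agreement reports are then computed
#' for heart rate and for SD1/SD2 across subjects (differences TOI minus
#' ECG). Any branch failure is re-raised with the subject and stage in the
#' message.
#'
#' @param manifest data.frame or CSV path.
#' @param outDir optional directory for per-subject summaries and the
#'   agreement JSONs.
#' @param ... passed to [toiPipeline()].
#' @return List with `measurements` (one row per subject) and `agreement`
#'   (list of [AgreementReport-class] for `heart_rate_bpm` and `sd_ratio`).
#' @export
runCompareBatch <- function(manifest, outDir = NULL, ...) {
    if (is.character(manifest)) manifest <- utils::read.csv(manifest)
    need <- c("subject_id", "video_path", "roi_path", "ecg_path")
    if (!all(need %in% names(manifest)))
        stop("manifest must have columns ", paste(need, collapse = ", "))
    rows <- lapply(seq_len(nrow(manifest)), function(i) {
        id <- manifest$subject_id[i]
        res <- tryCatch({
            video <- readFrameStack(manifest$video_path[i])
            roiMap <- readROIConfig(manifest$roi_path[i])
            ecg <- readECGRecord(manifest$ecg_path[i])
            runCompare(video, roiMap, ecg,
                       outDir = if (is.null(outDir)) NULL else
                           file.path(outDir, id), ...)
        }, error = function(e)
            stop(sprintf("subject %s: %s", id, conditionMessage(e)),
                 call. = FALSE))
        data.frame(subject_id = id,
                   toi_hr = summaryHeartRate(res$toi$poincare),
                   ecg_hr = summaryHeartRate(res$ecg$poincare),
                   toi_sd_ratio = sdRatio(res$toi$poincare),
                   ecg_sd_ratio = sdRatio(res$ecg$poincare))
    })
    meas <- do.call(rbind, rows)
    agreement <- list(
        heart_rate_bpm = blandAltman(meas$toi_hr, meas$ecg_hr,
                                     label = "heart_rate_bpm"),
        sd_ratio = blandAltman(meas$toi_sd_ratio, meas$ecg_sd_ratio,
                               label = "sd_ratio"))
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        utils::write.csv(meas, file.path(outDir, "measurements.csv"),
                         row.names = FALSE)
        writeAgreementReport(agreement$heart_rate_bpm,
                             file.path(outDir, "agreement_heart_rate.json"))
        writeAgreementReport(agreement$sd_ratio,
                             file.path(outDir, "agreement_sd_ratio.json"))
    }
    list(measurements = meas, agreement = agreement)
}

#' Write per-ROI hemoglobin-concentration signals to CSV
#'
#' Columns `t_s` then one column per ROI.
#'
#' @param signals named list of [HCSignal-class] objects on a common grid.
#' @param path output CSV path.
#' @export
writeHCSignals <- function(signals, path) {
    fsHz <- signals[[1]]@fps
    d <- data.frame(t_s = (seq_along(signals[[1]]@values) - 1) / fsHz)
    for (nm in names(signals)) d[[nm]] <- signals[[nm]]@values
    utils::write.csv(d, path, row.names = FALSE)
    invisible(path)
}
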