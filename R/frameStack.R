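#' Construct a FrameStack
#'
#' @param frames integer array `T x H x W x 3` of 8-bit RGB samples
#'   (channels ordered R, G, B).
#' @param fps frame rate in frames/second (acquisition default: 60).
#' @return A [FrameStack-class].
#' @examples
#' fr <- array(0L, c(4, 2, 2, 3))
#' fs <- FrameStack(fr, fps = 60)
#' nFrames(fs)
#' @export
FrameStack <- function(frames, fps = 60) {
    storage.mode(frames) <- "integer"
    new("FrameStack", frames = frames, fps = as.numeric(fps))
}

#' @rdname FrameStack-accessors
#' @export
setMethod("fps", "FrameStack", function(x) x@fps)

#' @rdname FrameStack-accessors
#' @export
setMethod("fps", "HCSignal", function(x) x@fps)

#' @rdname FrameStack-accessors
#' @export
setMethod("fps", "ECGRecord", function(x) x@fs)

#' @rdname FrameStack-accessors
#' @export
setMethod("nFrames", "FrameStack", function(x) dim(x@frames)[1])

#' @rdname FrameStack-accessors
#' @export
setMethod("frameDim", "FrameStack", function(x) dim(x@frames)[2:3])

#' @rdname FrameStack-accessors
#' @export
setMethod("duration", "FrameStack", function(x) nFrames(x) / fps(x))

#' Extract raw frame data
#'
#' @param x a [FrameStack-class].
#' @return The underlying `T x H x W x 3` integer array.
#' @export
frameData <- function(x) {
    stopifnot(is(x, "FrameStack"))
    x@frames
}

setMethod("show", "FrameStack", function(object) {
    d <- dim(object@frames)
    cat(sprintf("FrameStack: %d frames of %dx%d RGB @ %g fps (%.1f s)\n",
                d[1], d[2], d[3], object@fps, d[1] / object@fps))
})

#' Read / write a lossless frame-stack archive
#'
#' Video enters the pipeline as an uncompressed frame archive (an RDS file
#' holding the `T x H x W x 3` uint8 array under `frames` and the frame rate
#' under `fps`). A lossless representation is required because lossy video
#' codecs perturb the low-order bitplanes that carry the hemoglobin signal.
#'
#' @param path file path of the archive.
#' @return `readFrameStack` returns a [FrameStack-class]; `writeFrameStack`
#'   returns `path` invisibly.
#' @export
readFrameStack <- function(path) {
    if (!file.exists(path)) stop("frame archive not found: ", path)
    x <- readRDS(path)
    if (!is.list(x) || is.null(x$frames) || is.null(x$fps))
        stop("frame archive must contain 'frames' and 'fps'")
    FrameStack(x$frames, x$fps)
}

#' @rdname readFrameStack
#' @param x a [FrameStack-class] to write.
#' @export
writeFrameStack <- function(x, path) {
    stopifnot(is(x, "FrameStack"))
    saveRDS(list(frames = x@frames, fps = x@fps), path)
    invisible(path)
}

## ---- bitplane decomposition -------------------------------------------------

#' Decompose an RGB frame into its 24 bitplanes
#'
#' A bitplane is the binary image formed by a single bit position of one
#' colour channel across all pixels: an 8-bit RGB frame yields 24 of them.
#' Bit 0 is the least significant.
#'
#' @param frame integer array `H x W x 3` with values in 0..255.
#' @return Named list of 24 binary (0/1) integer `H x W` matrices, names
#'   [bitplaneLabels()] ("R0".."B7").
#' @examples
#' fr <- array(5L, c(2, 2, 3))  # 5 = 00000101
#' pl <- decomposeBitplanes(fr)
#' pl$G0[1, 1]; pl$G2[1, 1]; pl$G1[1, 1]
#' @export
decomposeBitplanes <- function(frame) {
    d <- dim(frame)
    if (length(d) != 3L || d[3] != 3L)
        stop("frame must be an H x W x 3 RGB image")
    if (any(frame != round(frame)) || min(frame) < 0 || max(frame) > 255)
        stop("frame must hold 8-bit integer samples in [0, 255]")
    storage.mode(frame) <- "integer"
    planes <- vector("list", 24L)
    names(planes) <- bitplaneLabels()
    for (ci in 1:3) {
        ch <- frame[, , ci]
        for (b in 0:7) {
            p <- (bitwAnd(ch, bitwShiftL(1L, b)) != 0L) + 0L
            dim(p) <- d[1:2]
            planes[[paste0(CHANNELS[ci], b)]] <- p
        }
    }
    planes
}

#' Reconstruct an 8-bit channel from its 8 bitplanes
#'
#' Inverse of [decomposeBitplanes()] for one channel: the positional sum
#' `sum_b 2^b * plane(b)` restores the original samples exactly.
#'
#' @param planes list of 8 binary `H x W` matrices in bit order 0 (LSB) to 7.
#' @return Integer `H x W` matrix.
#' @export
reconstructChannel <- function(planes) {
    if (length(planes) != 8L)
        stop("exactly 8 bitplanes are required")
    out <- 0L
    for (b in 0:7) {
        p <- planes[[b + 1L]]
        if (!all(p %in% c(0L, 1L))) stop("bitplane values must be 0 or 1")
        out <- out + bitwShiftL(1L, b) * p
    }
    storage.mode(out) <- "integer"
    dim(out) <- dim(planes[[1]])
    out
}

#' Average a per-pixel signal video over a region of interest
#'
#' Pixel averaging within an ROI is the first SNR-raising step of the
#' transdermal pipeline: one value per frame, the arithmetic mean over the
#' masked pixels.
#'
#' @param signalVideo numeric array `T x H x W` of per-pixel scalar frames.
#' @param roi logical `H x W` mask, non-empty, same shape as the frames.
#' @return Numeric vector of length `T`.
#' @export
averageROI <- function(signalVideo, roi) {
    d <- dim(signalVideo)
    if (length(d) != 3L) stop("signalVideo must be a T x H x W array")
    if (!identical(dim(roi), d[2:3]))
        stop("ROI mask shape must match the frame shape")
    idx <- which(roi)
    if (length(idx) == 0L) stop("ROI mask is empty")
    dim(signalVideo) <- c(d[1], d[2] * d[3])
    rowMeans(signalVideo[, idx, drop = FALSE])
}

#' Per-ROI mean time series of every bitplane
#'
#' For each region the 24 bitplanes are averaged over the masked pixels in
#' every frame, giving a `T x 24` matrix (columns in [bitplaneLabels()]
#' order) whose entries are the fraction of set bits. Because bitplane
#' composition is linear, downstream signal composition and selection operate
#' on these matrices without revisiting the pixels.
#'
#' @param x a [FrameStack-class].
#' @param roiMap a [ROIMap-class] whose masks match the frame shape.
#' @return Named list (one per ROI) of `T x 24` numeric matrices.
#' @export
bitplaneROIMeans <- function(x, roiMap) {
    stopifnot(is(x, "FrameStack"), is(roiMap, "ROIMap"))
    d <- dim(x@frames)
    if (!identical(dim(roiMap@masks[[1]]), d[2:3]))
        stop("ROI mask shape must match the frame shape")
    labs <- bitplaneLabels()
    out <- vector("list", length(roiMap@masks))
    names(out) <- names(roiMap@masks)
    for (r in seq_along(out)) {
        idx <- which(roiMap@masks[[r]])
        M <- matrix(0, nrow = d[1], ncol = 24L, dimnames = list(NULL, labs))
        for (ci in 1:3) {
            ch <- x@frames[, , , ci]
            dim(ch) <- c(d[1], d[2] * d[3])
            sub <- ch[, idx, drop = FALSE]
            for (b in 0:7) {
                bm <- bitwAnd(sub, bitwShiftL(1L, b)) != 0L
                dim(bm) <- dim(sub)   # bitwAnd drops dim attributes
                M[, paste0(CHANNELS[ci], b)] <- rowMeans(bm)
            }
        }
        out[[r]] <- M
    }
    out
}
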