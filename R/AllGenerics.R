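#' @rdname FrameStack-accessors
#' @export
setGeneric("fps", function(x) standardGeneric("fps"))

#' @rdname FrameStack-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname FrameStack-accessors
#' @export
setGeneric("frameDim", function(x) standardGeneric("frameDim"))

#' @rdname FrameStack-accessors
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' @rdname ROIMap-accessors
#' @export
setGeneric("roiNames", function(x) standardGeneric("roiNames"))

#' @rdname ROIMap-accessors
#' @export
setGeneric("roiMask", function(x, name) standardGeneric("roiMask"))

#' @rdname PeakTrain-accessors
#' @export
setGeneric("peakTimes", function(x) standardGeneric("peakTimes"))

#' @rdname RRISeries-accessors
#' @export
setGeneric("intervals", function(x) standardGeneric("intervals"))

#' @rdname RRISeries-accessors
#' @export
setGeneric("sourceTag", function(x) standardGeneric("sourceTag"))

#' Accessors for FrameStack objects
#'
#' `fps` returns the frame rate, `nFrames` the number of frames, `frameDim`
#' the `c(H, W)` pixel shape, and `duration` the recording length in seconds.
#'
#' @param x a [FrameStack-class] (or other object with a frame rate).
#' @name FrameStack-accessors
NULL

#' Accessors for ROIMap objects
#'
#' `roiNames` lists the region names; `roiMask` extracts one logical mask.
#'
#' @param x a [ROIMap-class].
#' @param name region name.
#' @name ROIMap-accessors
NULL

#' Accessors for PeakTrain objects
#'
#' @param x a [PeakTrain-class].
#' @name PeakTrain-accessors
NULL

#' Accessors for RRISeries objects
#'
#' `intervals` returns the R-R intervals in milliseconds; `sourceTag` the
#' originating branch ("TOI", "ECG" or "truth").
#'
#' @param x an [RRISeries-class] or [PeakTrain-class].
#' @name RRISeries-accessors
NULL
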