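#' The nine facial regions of interest
#'
#' Names of the nine standard facial regions used by the transdermal
#' pipeline.
#'
#' @return Character vector of nine region names.
#' @export
faceROINames <- function() {
    c("Forehead Small", "Nose Between Eyes", "Nose Bridge Full",
      "Nose Tip Small", "Right Cheek Narrow", "Left Cheek Narrow",
      "Upper Lip", "Lower Lip", "Chin Small")
}

#' Construct an ROIMap from logical masks
#'
#' Pixel coordinates are row-major and 0-based in configuration files; masks
#' are logical matrices of the frame shape. ROIs are supplied (from a config
#' file or a synthetic truth bundle), never detected: face localisation is
#' out of scope.
#'
#' @param masks named list of logical `H x W` matrices.
#' @return An [ROIMap-class].
#' @export
ROIMap <- function(masks) new("ROIMap", masks = masks)

#' @rdname ROIMap-accessors
#' @export
setMethod("roiNames", "ROIMap", function(x) names(x@masks))

#' @rdname ROIMap-accessors
#' @export
setMethod("roiMask", "ROIMap", function(x, name) {
    if (!name %in% names(x@masks)) stop(sprintf("no ROI named '%s'", name))
    x@masks[[name]]
})

setMethod("show", "ROIMap", function(object) {
    d <- dim(object@masks[[1]])
    cat(sprintf("ROIMap: %d regions on a %dx%d frame\n",
                length(object@masks), d[1], d[2]))
    px <- vapply(object@masks, sum, numeric(1))
    for (i in seq_along(px))
        cat(sprintf("  %-20s %d px\n", names(px)[i], px[i]))
})

#' Build an ROIMap from half-open rectangles
#'
#' Rectangles are given in 0-based pixel coordinates, `x` along the width
#' (columns) and `y` along the height (rows), covering `[x0, x1) x [y0, y1)`.
#'
#' @param rects named list, each element `list(x0=, y0=, x1=, y1=)`.
#' @param frameShape integer `c(H, W)`.
#' @return An [ROIMap-class]; the rectangle definitions are retained so the
#'   map can be written back with [writeROIConfig()].
#' @export
roiMapFromRects <- function(rects, frameShape) {
    H <- frameShape[1]; W <- frameShape[2]
    masks <- lapply(rects, function(r) {
        if (r$x0 < 0 || r$y0 < 0 || r$x1 > W || r$y1 > H ||
            r$x1 <= r$x0 || r$y1 <= r$y0)
            stop("rectangle out of frame bounds or empty")
        m <- matrix(FALSE, H, W)
        m[(r$y0 + 1):r$y1, (r$x0 + 1):r$x1] <- TRUE
        m
    })
    out <- ROIMap(masks)
    attr(out, "rects") <- rects
    out
}

#' Read / write an ROI configuration file
#'
#' The JSON layout is
#' `{"rois": {"<name>": {"type": "rect", "x0":, "y0":, "x1":, "y1":}},
#'   "frame_shape": [H, W]}` with half-open rectangles in 0-based pixel
#' coordinates.
#'
#' @param path JSON file path.
#' @return `readROIConfig` returns an [ROIMap-class].
#' @export
readROIConfig <- function(path) {
    if (!file.exists(path)) stop("ROI config not found: ", path)
    cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE)
    if (is.null(cfg$rois) || is.null(cfg$frame_shape))
        stop("ROI config must contain 'rois' and 'frame_shape'")
    rects <- lapply(cfg$rois, function(r) {
        if (!identical(r$type, "rect"))
            stop("only 'rect' ROIs are supported")
        r
    })
    roiMapFromRects(rects, as.integer(cfg$frame_shape))
}

#' @rdname readROIConfig
#' @param roiMap an [ROIMap-class] built from rectangles.
#' @export
writeROIConfig <- function(roiMap, path) {
    rects <- attr(roiMap, "rects")
    if (is.null(rects))
        stop("only rectangle-based ROI maps can be written")
    d <- dim(roiMap@masks[[1]])
    cfg <- list(
        rois = lapply(rects, function(r)
            list(type = "rect", x0 = r$x0, y0 = r$y0, x1 = r$x1, y1 = r$y1)),
        frame_shape = d)
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Default layout of the nine facial ROIs
#'
#' Places the nine regions proportionally on an `H x W` frame the way they
#' sit on a frontal face: forehead at the top, nose regions down the
#' mid-line, cheeks either side, lips and chin below.
#'
#' @param frameShape integer `c(H, W)` (at least 16 x 16).
#' @return An [ROIMap-class] with the nine regions of [faceROINames()].
#' @export
defaultFaceROIs <- function(frameShape) {
    H <- frameShape[1]; W <- frameShape[2]
    if (H < 16 || W < 16) stop("frame must be at least 16 x 16 pixels")
    r <- function(fx0, fy0, fx1, fy1)
        list(x0 = floor(fx0 * W), y0 = floor(fy0 * H),
             x1 = max(floor(fx0 * W) + 1, floor(fx1 * W)),
             y1 = max(floor(fy0 * H) + 1, floor(fy1 * H)))
    rects <- list(
        "Forehead Small"     = r(0.30, 0.05, 0.70, 0.18),
        "Nose Between Eyes"  = r(0.42, 0.22, 0.58, 0.32),
        "Nose Bridge Full"   = r(0.44, 0.32, 0.56, 0.50),
        "Nose Tip Small"     = r(0.42, 0.50, 0.58, 0.58),
        "Right Cheek Narrow" = r(0.08, 0.40, 0.28, 0.62),
        "Left Cheek Narrow"  = r(0.72, 0.40, 0.92, 0.62),
        "Upper Lip"          = r(0.35, 0.62, 0.65, 0.70),
        "Lower Lip"          = r(0.35, 0.72, 0.65, 0.80),
        "Chin Small"         = r(0.40, 0.84, 0.60, 0.95))
    roiMapFromRects(rects, frameShape)
}
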