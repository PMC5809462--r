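#' Bland-Altman agreement with Pearson correlation
#'
#' Method-agreement statistics over paired per-subject measurements.
#' Differences are method A minus method B (TOI minus ECG): bias is the mean
#' difference and the 95% limits of agreement are bias +/- 1.96 times the
#' sample standard deviation of the differences (large-sample normal limits,
#' no small-sample t correction). Pearson's product-moment correlation of
#' the paired values is reported alongside.
#'
#' @param a numeric, method A (TOI) measurements.
#' @param b numeric, method B (ECG) measurements, pairwise aligned with `a`.
#' @param label measure being compared (e.g. `"heart_rate_bpm"`,
#'   `"sd_ratio"`).
#' @return An [AgreementReport-class]. `pearsonR` is `NA` when either
#'   series is constant (the correlation is undefined there).
#' @examples
#' blandAltman(c(10, 12, 11, 13), c(11, 11, 12, 12))
#' @export
blandAltman <- function(a, b, label = NA_character_) {
    if (length(a) != length(b)) stop("paired series must have equal length")
    n <- length(a)
    if (n < 3L) stop("at least 3 pairs are required")
    d <- a - b
    bias <- mean(d)
    s <- stats::sd(d)
    r <- if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else
        stats::cor(a, b)
    new("AgreementReport", bias = bias, loaLower = bias - 1.96 * s,
        loaUpper = bias + 1.96 * s, pearsonR = r, n = as.integer(n),
        label = label)
}

#' Pearson correlation of paired measurements
#'
#' @param a,b paired numeric series (n >= 3, both non-constant).
#' @return The product-moment correlation coefficient.
#' @export
pearsonR <- function(a, b) {
    if (length(a) != length(b)) stop("paired series must have equal length")
    if (length(a) < 3L) stop("at least 3 pairs are required")
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
        stop("correlation undefined for a constant series")
    stats::cor(a, b)
}

#' Accessors for AgreementReport
#' @param x an [AgreementReport-class].
#' @name AgreementReport-accessors
#' @export
agreementBias <- function(x) { stopifnot(is(x, "AgreementReport")); x@bias }

#' @rdname AgreementReport-accessors
#' @export
agreementLimits <- function(x) {
    stopifnot(is(x, "AgreementReport"))
    c(lower = x@loaLower, upper = x@loaUpper)
}

#' @rdname AgreementReport-accessors
#' @export
agreementR <- function(x) { stopifnot(is(x, "AgreementReport")); x@pearsonR }

setMethod("show", "AgreementReport", function(object) {
    cat(sprintf(
        "AgreementReport%s: bias %.3f, 95%% LoA [%.3f, %.3f], r = %s (n=%d)\n",
        if (is.na(object@label)) "" else sprintf(" (%s)", object@label),
        object@bias, object@loaLower, object@loaUpper,
        if (is.na(object@pearsonR)) "NA" else sprintf("%.3f", object@pearsonR),
        object@n))
})

#' Serialise an AgreementReport to JSON
#'
#' @param x an [AgreementReport-class].
#' @param path output path.
#' @export
writeAgreementReport <- function(x, path) {
    stopifnot(is(x, "AgreementReport"))
    jsonlite::write_json(list(
        label = x@label, bias = x@bias, loa_lower = x@loaLower,
        loa_upper = x@loaUpper, pearson_r = x@pearsonR, n = x@n,
        difference_convention = "TOI minus ECG"),
        path, auto_unbox = TRUE, digits = NA, na = "null")
    invisible(path)
}
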