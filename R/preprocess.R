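#' @include AllGenerics.R
NULL

#' @rdname discardInitial
#' @export
setMethod("discardInitial", "LumiSeries", function(x, hours = 24) {
    stopifnot(length(hours) == 1L, hours >= 0)
    keep <- x@timesH >= hours
    if (sum(keep) < 2L)
        stop(sprintf("discarding %g h leaves fewer than 2 points for sample '%s'",
                     hours, x@sampleId), call. = FALSE)
    out <- x
    out@timesH <- x@timesH[keep]
    out@cps <- x@cps[keep]
    if (!is.na(out@ddOnsetH))
        out@ddOnsetH <- max(out@ddOnsetH, min(out@timesH))
    validObject(out)
    out
})

#' @rdname discardInitial
#' @export
setMethod("discardInitial", "LumiSet", function(x, hours = 24) {
    out <- LumiSet(lapply(as.list(x), discardInitial, hours = hours))
    metadata(out) <- metadata(x)
    out
})

#' @rdname extractDD
#' @export
setMethod("extractDD", "LumiSeries", function(x) {
    if (is.na(x@ddOnsetH))
        stop(sprintf("sample '%s' has no DD onset set", x@sampleId),
             call. = FALSE)
    keep <- x@timesH >= x@ddOnsetH
    if (!any(keep))
        stop(sprintf("no points at or after DD onset for sample '%s'",
                     x@sampleId), call. = FALSE)
    out <- x
    out@timesH <- x@timesH[keep] - x@ddOnsetH
    out@cps <- x@cps[keep]
    out@ddOnsetH <- 0
    validObject(out)
    out
})

#' @rdname extractDD
#' @export
setMethod("extractDD", "LumiSet", function(x) {
    out <- LumiSet(lapply(as.list(x), extractDD))
    metadata(out) <- metadata(x)
    out
})

## centred moving average on (possibly irregular) times; the window is
## truncated at the series edges so every point keeps a trend estimate
.movingAverage <- function(t, y, windowH) {
    half <- windowH / 2
    lo <- findInterval(t - half, t, left.open = TRUE) + 1L
    hi <- findInterval(t + half, t)
    cs <- c(0, cumsum(y))
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' @rdname detrendMovingAverage
#' @export
setMethod("detrendMovingAverage", "LumiSeries",
    function(x, windowH = 24, mode = c("subtract", "divide")) {
    mode <- match.arg(mode)
    stopifnot(windowH > 0)
    if (length(x) < 2L || diff(range(x@timesH)) < windowH)
        stop(sprintf(
            "series '%s' spans %.1f h, less than the %.1f h window; use a smaller window",
            x@sampleId, if (length(x)) diff(range(x@timesH)) else 0, windowH),
            call. = FALSE)
    trend <- .movingAverage(x@timesH, x@cps, windowH)
    resid <- if (mode == "subtract") x@cps - trend else {
        if (any(trend <= 0))
            stop(sprintf("non-positive trend for sample '%s'; divide mode needs a positive baseline",
                         x@sampleId), call. = FALSE)
        x@cps / trend
    }
    new("DetrendedSeries", sampleId = x@sampleId, timesH = x@timesH,
        residuals = resid, trend = trend, windowH = windowH, mode = mode,
        temperatureC = x@temperatureC, annotations = x@annotations)
})

#' @rdname detrendMovingAverage
#' @export
setMethod("detrendMovingAverage", "LumiSet",
    function(x, windowH = 24, mode = c("subtract", "divide")) {
    mode <- match.arg(mode)
    lapply(as.list(x), detrendMovingAverage, windowH = windowH, mode = mode)
})

setMethod("show", "DetrendedSeries", function(object) {
    cat("DetrendedSeries '", object@sampleId, "': ", length(object@timesH),
        " points, ", object@windowH, " h window (", object@mode, ")\n",
        sep = "")
})

#' Reconstruct the original values of a detrended series
#'
#' @param d a [DetrendedSeries].
#' @return numeric vector equal to the detrended input's counts.
#' @export
reconstruct <- function(d) {
    stopifnot(is(d, "DetrendedSeries"))
    if (d@mode == "subtract") d@residuals + d@trend else d@residuals * d@trend
}
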