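#' @include AllClasses.R
NULL

#' @rdname LumiSeries-class
#' @param x,object a `LumiSeries` (or, where noted, a `LumiSet`).
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname LumiSeries-class
#' @export
setGeneric("timesH", function(x) standardGeneric("timesH"))

#' @rdname LumiSeries-class
#' @export
setGeneric("cps", function(x) standardGeneric("cps"))

#' @rdname LumiSeries-class
#' @export
setGeneric("ddOnsetH", function(x) standardGeneric("ddOnsetH"))

#' @rdname LumiSeries-class
#' @export
setGeneric("temperatureC", function(x) standardGeneric("temperatureC"))

#' @rdname LumiSeries-class
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' Discard the start of a recording
#'
#' Removes all points earlier than `hours` from the start of the recording
#' (typically the first LD entrainment cycle, which reflects the driving
#' light cycle rather than the free-running clock). Times keep the original
#' clock; they are not re-zeroed.
#'
#' @param x a [LumiSeries] or [LumiSet].
#' @param hours non-negative number of hours to discard (default 24, one
#'   full LD cycle).
#' @return an object of the same class as `x`.
#' @export
setGeneric("discardInitial", function(x, hours = 24) standardGeneric("discardInitial"))

#' Extract the free-running (DD) segment
#'
#' Keeps only points at or after the DD onset and re-zeroes time so DD onset
#' is `t = 0`. The free-running period must be estimated on this segment
#' only, because entrained oscillations track the Zeitgeber, not the clock.
#'
#' @param x a [LumiSeries] (with `ddOnsetH` set) or [LumiSet].
#' @return an object of the same class as `x`, times re-zeroed.
#' @export
setGeneric("extractDD", function(x) standardGeneric("extractDD"))

#' Detrend with a centred moving average
#'
#' The trend at each time point is the mean of all observations within
#' `windowH / 2` hours on either side (the window shrinks at the edges so no
#' data are lost). With the default 24-h window a circadian oscillation
#' averages out over the window and survives in the residuals, while the
#' slow baseline (substrate depletion) is removed.
#'
#' @param x a [LumiSeries] (or [LumiSet], returning a list).
#' @param windowH window width in hours (default 24).
#' @param mode `"subtract"` (residual = value - trend; default) or
#'   `"divide"` (residual = value / trend, a unitless relative amplitude).
#' @return a [DetrendedSeries] (or list of them).
#' @export
setGeneric("detrendMovingAverage",
    function(x, windowH = 24, mode = c("subtract", "divide"))
        standardGeneric("detrendMovingAverage"))

#' Mean expression level
#'
#' Arithmetic mean of the raw counts-per-second values of the analysed
#' series — the "mean CPS" column of the cohort report.
#'
#' @param x a [LumiSeries].
#' @return mean CPS, a single number.
#' @export
setGeneric("meanLevel", function(x) standardGeneric("meanLevel"))

#' @rdname Q10Result-class
#' @param x a `Q10Result`.
#' @export
setGeneric("q10", function(x) standardGeneric("q10"))
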