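#' @include AllGenerics.R
NULL

#' @rdname LumiSeries-class
#' @export
setMethod("sampleId", "LumiSeries", function(x) x@sampleId)

#' @rdname LumiSeries-class
#' @export
setMethod("timesH", "LumiSeries", function(x) x@timesH)

#' @rdname LumiSeries-class
#' @export
setMethod("cps", "LumiSeries", function(x) x@cps)

#' @rdname LumiSeries-class
#' @export
setMethod("ddOnsetH", "LumiSeries", function(x) x@ddOnsetH)

#' @rdname LumiSeries-class
#' @export
setMethod("temperatureC", "LumiSeries", function(x) x@temperatureC)

#' @rdname LumiSeries-class
#' @export
setMethod("annotations", "LumiSeries", function(x) x@annotations)

#' @rdname LumiSeries-class
#' @export
setMethod("length", "LumiSeries", function(x) length(x@timesH))

#' @rdname LumiSeries-class
#' @export
setMethod("sampleId", "LumiSet",
    function(x) vapply(x, function(s) s@sampleId, character(1), USE.NAMES = FALSE))

setMethod("show", "LumiSeries", function(object) {
    n <- length(object@timesH)
    cat("LumiSeries '", object@sampleId, "': ", n, " points", sep = "")
    if (n) cat(sprintf(", %.1f-%.1f h", min(object@timesH), max(object@timesH)))
    if (!is.na(object@ddOnsetH))
        cat(sprintf(", DD onset %.1f h", object@ddOnsetH))
    if (!is.na(object@temperatureC))
        cat(sprintf(", %g degC", object@temperatureC))
    cat("\n")
    if (n)
        cat(sprintf("  cps: mean %.1f, range [%.1f, %.1f]\n",
                    mean(object@cps), min(object@cps), max(object@cps)))
    if (length(object@annotations))
        cat("  annotations:", paste(names(object@annotations), collapse = ", "), "\n")
})

setMethod("show", "LumiSet", function(object) {
    cat("LumiSet of", length(object), "series\n")
    if (length(object)) {
        ids <- sampleId(object)
        shown <- head(ids, 5L)
        cat("  ", paste(shown, collapse = ", "),
            if (length(ids) > 5L) ", ..." else "", "\n", sep = "")
    }
})

#' Convert series to the long data format
#'
#' @param x a [LumiSeries] or [LumiSet].
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return data.frame with columns `sample_id`, `time_h`, `cps`.
#' @export
as.data.frame.LumiSeries <- function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(sample_id = rep(x@sampleId, length(x@timesH)),
               time_h = x@timesH, cps = x@cps)
}

#' @rdname as.data.frame.LumiSeries
#' @export
as.data.frame.LumiSet <- function(x, row.names = NULL, optional = FALSE, ...) {
    do.call(rbind, c(lapply(as.list(x), as.data.frame.LumiSeries),
                     list(make.row.names = FALSE)))
}

setMethod("show", "SimParams", function(object) {
    cat("SimParams: period", object@periodH, "h, amplitude",
        object@amplitudeCps, "CPS, damping", object@dampingPerH, "/h\n")
    cat("  baseline", object@baselineCps, "CPS decaying at",
        object@trendDecayPerH, "/h; phase", object@phaseH, "h\n")
    cat("  noise:", object@noiseModel,
        if (object@noiseModel == "gaussian") sprintf("(sd %g)", object@noiseSdCps) else "",
        "\n")
    cat(sprintf("  %g h LD + %g h DD at %g h sampling\n",
                object@ldHours, object@ddHours, object@samplingIntervalH))
})

setMethod("show", "CohortDesign", function(object) {
    cat("CohortDesign:", object@nPerTemperature, "samples at each of",
        paste(object@temperatures, collapse = ", "), "degC\n")
    cat(sprintf("  true tau(T): %.2f h at %g degC, Q10 = %g, between-sample SD %g h\n",
                object@tauRefH, object@tRefC, object@q10True, object@tauSdH))
    cat("  genotype", object@genotype, "| tissue", object@tissue,
        "| seed", object@rngSeed, "\n")
})

setMethod("show", "RhythmFit", function(object) {
    cat("RhythmFit '", object@sampleId, "'\n", sep = "")
    cat(sprintf("  tau = %.2f h, amplitude = %.1f CPS, damping = %.4f /h, phase = %.2f h\n",
                object@tauH, object@amplitudeCps, object@dampingPerH, object@phaseH))
    cat(sprintf("  error = %.3f (1 - r), mean level = %.1f CPS, %d points, converged: %s\n",
                object@error, object@meanCps, object@nPoints, object@converged))
})

setMethod("show", "Q10Result", function(object) {
    cat(sprintf("Q10 = %.2f  [tau %.2f h at %g degC vs %.2f h at %g degC]\n",
                object@q10, object@tauColdH, object@tColdC,
                object@tauWarmH, object@tWarmC))
})

#' @rdname Q10Result-class
#' @export
setMethod("q10", "Q10Result", function(x) x@q10)

setMethod("show", "EffectSize", function(object) {
    cat(sprintf("EffectSize: %s minus %s\n", object@testLabel, object@controlLabel))
    cat(sprintf("  mean difference %.3f, %g%% CI [%.3f, %.3f] (%s, %d resamples)\n",
                object@meanDifference, 100 * object@ciLevel,
                object@ciLow, object@ciHigh, object@method, object@nBoot))
    cat("  crosses zero:", object@crossesZero, "\n")
})
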