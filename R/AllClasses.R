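#' @import methods
#' @importFrom S4Vectors SimpleList metadata metadata<-
#' @importFrom utils head
#' @importClassesFrom S4Vectors SimpleList
NULL

## ---------------------------------------------------------------------------
## LumiSeries: one sample's bioluminescence trace
## ---------------------------------------------------------------------------

#' LumiSeries: a single bioluminescence time series
#'
#' One sample's luciferase reporter trace: photon counts per second (CPS)
#' recorded at strictly increasing times, annotated with the time at which
#' constant darkness (DD) begins and the recording temperature. Times are
#' hours from the start of the recording; gaps are allowed (missing readings
#' are simply absent, not interpolated).
#'
#' @slot sampleId single character identifier.
#' @slot timesH numeric, strictly increasing, hours from recording start.
#' @slot cps numeric, non-negative counts per second, same length as `timesH`.
#' @slot ddOnsetH hours at which constant darkness begins (`NA` if unknown);
#'   when set it must fall within the recorded time range.
#' @slot temperatureC recording temperature in deg C (`NA` if unknown).
#' @slot annotations free-form named list (genotype, tissue, true simulation
#'   parameters, ...).
#'
#' @examples
#' ts <- LumiSeries("w1", timesH = 0:47, cps = 100 + 10 * cos(2 * pi * 0:47 / 24),
#'                  ddOnsetH = 24)
#' ts
#' @export
setClass("LumiSeries",
    representation(
        sampleId = "character",
        timesH = "numeric",
        cps = "numeric",
        ddOnsetH = "numeric",
        temperatureC = "numeric",
        annotations = "list"
    ),
    prototype(
        sampleId = NA_character_,
        timesH = numeric(0),
        cps = numeric(0),
        ddOnsetH = NA_real_,
        temperatureC = NA_real_,
        annotations = list()
    )
)

setValidity("LumiSeries", function(object) {
    msg <- character(0)
    if (length(object@sampleId) != 1L || is.na(object@sampleId))
        msg <- c(msg, "sampleId must be a single non-missing string")
    if (length(object@timesH) != length(object@cps))
        msg <- c(msg, "timesH and cps must have the same length")
    if (anyNA(object@timesH))
        msg <- c(msg, "timesH must not contain NA")
    if (length(object@timesH) > 1L && any(diff(object@timesH) <= 0))
        msg <- c(msg, "timesH must be strictly increasing")
    if (anyNA(object@cps) || any(object@cps < 0))
        msg <- c(msg, "cps must be non-negative and non-missing")
    if (length(object@ddOnsetH) != 1L)
        msg <- c(msg, "ddOnsetH must be a single number (or NA)")
    if (length(object@timesH) && !is.na(object@ddOnsetH) &&
        (object@ddOnsetH < min(object@timesH) ||
         object@ddOnsetH > max(object@timesH)))
        msg <- c(msg, "ddOnsetH must lie within the recorded time range")
    if (length(msg)) msg else TRUE
})

#' @rdname LumiSeries-class
#' @param sampleId,timesH,cps,ddOnsetH,temperatureC,annotations see slots.
#' @export
LumiSeries <- function(sampleId, timesH, cps, ddOnsetH = NA_real_,
                       temperatureC = NA_real_, annotations = list()) {
    new("LumiSeries", sampleId = as.character(sampleId),
        timesH = as.numeric(timesH), cps = as.numeric(cps),
        ddOnsetH = as.numeric(ddOnsetH),
        temperatureC = as.numeric(temperatureC),
        annotations = annotations)
}

## ---------------------------------------------------------------------------
## LumiSet: a collection of LumiSeries
## ---------------------------------------------------------------------------

#' LumiSet: a collection of bioluminescence time series
#'
#' A `SimpleList` of [LumiSeries] objects, named by sample id. Cohort-level
#' metadata (e.g. the sample table of a simulated cohort) lives in
#' `S4Vectors::metadata()`.
#'
#' @export
setClass("LumiSet", contains = "SimpleList",
    prototype = prototype(elementType = "LumiSeries"))

setValidity("LumiSet", function(object) {
    msg <- character(0)
    ids <- vapply(object, function(x) x@sampleId, character(1))
    if (length(ids) && anyDuplicated(ids))
        msg <- c(msg, "sample ids must be unique within a LumiSet")
    if (length(msg)) msg else TRUE
})

#' @rdname LumiSet-class
#' @param ... `LumiSeries` objects, or a single list of them.
#' @export
LumiSet <- function(...) {
    elts <- list(...)
    if (length(elts) == 1L && is.list(elts[[1L]]) && !is(elts[[1L]], "LumiSeries"))
        elts <- elts[[1L]]
    names(elts) <- vapply(elts, function(x) x@sampleId, character(1))
    new("LumiSet", SimpleList(elts))
}

## ---------------------------------------------------------------------------
## DetrendedSeries
## ---------------------------------------------------------------------------

#' DetrendedSeries: a series split into slow trend and rhythmic residual
#'
#' Output of [detrendMovingAverage()]. The input is reconstructed exactly as
#' `residuals + trend` (mode `"subtract"`) or `residuals * trend` (mode
#' `"divide"`).
#'
#' @slot sampleId sample identifier.
#' @slot timesH times of the retained window, hours.
#' @slot residuals detrended values (sign free).
#' @slot trend removed baseline at each time.
#' @slot windowH moving-average window width, hours.
#' @slot mode `"subtract"` or `"divide"`.
#' @slot temperatureC carried over from the input series.
#' @slot annotations carried over from the input series.
#' @export
setClass("DetrendedSeries",
    representation(
        sampleId = "character",
        timesH = "numeric",
        residuals = "numeric",
        trend = "numeric",
        windowH = "numeric",
        mode = "character",
        temperatureC = "numeric",
        annotations = "list"
    )
)

setValidity("DetrendedSeries", function(object) {
    msg <- character(0)
    n <- length(object@timesH)
    if (length(object@residuals) != n || length(object@trend) != n)
        msg <- c(msg, "timesH, residuals and trend must have equal lengths")
    if (n > 1L && any(diff(object@timesH) <= 0))
        msg <- c(msg, "timesH must be strictly increasing")
    if (!object@mode %in% c("subtract", "divide"))
        msg <- c(msg, "mode must be 'subtract' or 'divide'")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## SimParams
## ---------------------------------------------------------------------------

#' SimParams: parameters of the synthetic oscillator
#'
#' Deterministic signal model evaluated at recording time `t` (hours), with
#' `t0` the DD onset (end of the entrainment segment):
#' \deqn{s(t) = b\,e^{-k t} + A\,e^{-\lambda (t - t_0)}
#'   \cos\!\big(2\pi\,(t - t_0 - \phi)/\tau\big)}
#' where `b` is the baseline (CPS), `k` the substrate-depletion trend decay
#' (1/h), `A` the oscillation amplitude (CPS), `lambda` the damping rate
#' (1/h, negative = growing), `tau` the period (h) and `phi` the peak offset
#' relative to DD onset (h). With `phi = 0`, a 24-h oscillation under a
#' 12:12 LD schedule peaks at lights-off (= DD onset) and troughs at
#' lights-on. Counting noise is applied per `noiseModel` and the result is
#' clipped at zero.
#'
#' @slot periodH oscillation period tau, hours (> 0).
#' @slot amplitudeCps oscillation amplitude, CPS (>= 0).
#' @slot dampingPerH amplitude damping rate, 1/h (sign free; > 0 decays).
#' @slot phaseH peak offset relative to DD onset, hours.
#' @slot baselineCps baseline expression level, CPS (>= 0).
#' @slot trendDecayPerH exponential baseline decay, 1/h (>= 0).
#' @slot noiseModel one of `"none"`, `"gaussian"`, `"poisson"`.
#' @slot noiseSdCps SD of Gaussian noise, CPS (used only for `"gaussian"`).
#' @slot samplingIntervalH sampling interval, hours (> 0, < periodH / 4).
#' @slot ldHours retained entrainment (LD) segment length, hours (>= 0).
#' @slot ddHours free-run (DD) segment length, hours (>= 2 * periodH).
#' @export
setClass("SimParams",
    representation(
        periodH = "numeric",
        amplitudeCps = "numeric",
        dampingPerH = "numeric",
        phaseH = "numeric",
        baselineCps = "numeric",
        trendDecayPerH = "numeric",
        noiseModel = "character",
        noiseSdCps = "numeric",
        samplingIntervalH = "numeric",
        ldHours = "numeric",
        ddHours = "numeric"
    )
)

setValidity("SimParams", function(object) {
    msg <- character(0)
    chk1 <- function(x, nm) {
        if (length(slot(object, x)) != 1L || is.na(slot(object, x)))
            msg <<- c(msg, sprintf("%s must be a single non-missing number", nm))
    }
    for (s in c("periodH", "amplitudeCps", "dampingPerH", "phaseH",
                "baselineCps", "trendDecayPerH", "noiseSdCps",
                "samplingIntervalH", "ldHours", "ddHours")) chk1(s, s)
    if (length(msg)) return(msg)
    if (object@periodH <= 0) msg <- c(msg, "periodH must be > 0")
    if (object@amplitudeCps < 0) msg <- c(msg, "amplitudeCps must be >= 0")
    if (object@baselineCps < 0) msg <- c(msg, "baselineCps must be >= 0")
    if (object@trendDecayPerH < 0) msg <- c(msg, "trendDecayPerH must be >= 0")
    if (object@noiseSdCps < 0) msg <- c(msg, "noiseSdCps must be >= 0")
    if (object@ldHours < 0) msg <- c(msg, "ldHours must be >= 0")
    if (object@samplingIntervalH <= 0)
        msg <- c(msg, "samplingIntervalH must be > 0")
    if (length(object@noiseModel) != 1L ||
        !object@noiseModel %in% c("none", "gaussian", "poisson"))
        msg <- c(msg, "noiseModel must be one of 'none', 'gaussian', 'poisson'")
    if (object@ddHours < 2 * object@periodH)
        msg <- c(msg, "ddHours must be >= 2 * periodH (fitting needs two cycles)")
    if (object@samplingIntervalH >= object@periodH / 4)
        msg <- c(msg, "samplingIntervalH must be < periodH / 4")
    if (length(msg)) msg else TRUE
})

#' @rdname SimParams-class
#' @param periodH,amplitudeCps,dampingPerH,phaseH,baselineCps,trendDecayPerH
#'   see slots.
#' @param noiseModel,noiseSdCps,samplingIntervalH,ldHours,ddHours see slots.
#' @export
simParams <- function(periodH = 24, amplitudeCps = 100, dampingPerH = 0.005,
                      phaseH = 0, baselineCps = 150, trendDecayPerH = 0.005,
                      noiseModel = c("poisson", "gaussian", "none"),
                      noiseSdCps = 0, samplingIntervalH = 1,
                      ldHours = 24, ddHours = 96) {
    noiseModel <- match.arg(noiseModel)
    new("SimParams", periodH = periodH, amplitudeCps = amplitudeCps,
        dampingPerH = dampingPerH, phaseH = phaseH,
        baselineCps = baselineCps, trendDecayPerH = trendDecayPerH,
        noiseModel = noiseModel, noiseSdCps = noiseSdCps,
        samplingIntervalH = samplingIntervalH,
        ldHours = ldHours, ddHours = ddHours)
}

## ---------------------------------------------------------------------------
## CohortDesign
## ---------------------------------------------------------------------------

#' CohortDesign: a simulated multi-temperature cohort
#'
#' Describes a cohort of synthetic oscillators recorded at several constant
#' temperatures. Each sample's true period is drawn as
#' \deqn{\tau(T) = \tau_{ref}\, q_{10}^{-(T - T_{ref})/10} + N(0, \sigma_\tau)}
#' so the cohort embodies a known temperature-to-period relation against
#' which the full pipeline can be checked.
#'
#' @slot temperatures recording temperatures, deg C.
#' @slot nPerTemperature samples per temperature (>= 1).
#' @slot tauRefH reference period at `tRefC`, hours.
#' @slot tRefC reference temperature, deg C.
#' @slot q10True true Q10 of the period (> 0; 1 = perfectly compensated).
#' @slot tauSdH between-sample SD of the true period, hours.
#' @slot params `SimParams` template (its `periodH` is overridden per sample).
#' @slot genotype,tissue labels written into the sample metadata.
#' @slot rngSeed base seed; per-sample seeds are derived by a counter scheme
#'   so each sample is reproducible independently of generation order.
#' @export
setClass("CohortDesign",
    representation(
        temperatures = "numeric",
        nPerTemperature = "integer",
        tauRefH = "numeric",
        tRefC = "numeric",
        q10True = "numeric",
        tauSdH = "numeric",
        params = "SimParams",
        genotype = "character",
        tissue = "character",
        rngSeed = "integer"
    )
)

setValidity("CohortDesign", function(object) {
    msg <- character(0)
    if (!length(object@temperatures) || anyNA(object@temperatures))
        msg <- c(msg, "temperatures must be a non-empty numeric vector")
    if (length(object@nPerTemperature) != 1L || is.na(object@nPerTemperature) ||
        object@nPerTemperature < 1L)
        msg <- c(msg, "nPerTemperature must be a single integer >= 1")
    if (length(object@q10True) != 1L || is.na(object@q10True) ||
        object@q10True <= 0)
        msg <- c(msg, "q10True must be a single number > 0")
    if (length(object@tauRefH) != 1L || is.na(object@tauRefH) ||
        object@tauRefH <= 0)
        msg <- c(msg, "tauRefH must be a single number > 0")
    if (length(object@tauSdH) != 1L || is.na(object@tauSdH) ||
        object@tauSdH < 0)
        msg <- c(msg, "tauSdH must be a single number >= 0")
    if (length(msg)) msg else TRUE
})

#' @rdname CohortDesign-class
#' @param temperatures,nPerTemperature,tauRefH,tRefC,q10True,tauSdH see slots.
#' @param params,genotype,tissue,rngSeed see slots.
#' @export
cohortDesign <- function(temperatures = c(18, 21, 25, 29),
                         nPerTemperature = 25L, tauRefH = 21, tRefC = 18,
                         q10True = 0.85, tauSdH = 0.5,
                         params = simParams(), genotype = "sim-luc",
                         tissue = "haltere", rngSeed = 1L) {
    new("CohortDesign", temperatures = as.numeric(temperatures),
        nPerTemperature = as.integer(nPerTemperature),
        tauRefH = tauRefH, tRefC = tRefC, q10True = q10True,
        tauSdH = tauSdH, params = params, genotype = genotype,
        tissue = tissue, rngSeed = as.integer(rngSeed))
}

## ---------------------------------------------------------------------------
## FitConfig
## ---------------------------------------------------------------------------

#' FitConfig: settings for the damped-cosine fit
#'
#' @slot tauBoundsH admissible period range, hours. The default `[16, 40]`
#'   spans both the shortest (~20 h) and longest (~32 h) rhythms the assay
#'   is expected to produce.
#' @slot tauGridStepH spacing of the multi-start period grid, hours.
#' @slot dampingBoundsPerH admissible damping range, 1/h; the negative lower
#'   bound admits growing (non-dampening) oscillations.
#' @slot nRefine number of best grid starts refined by the nonlinear
#'   optimiser (all grid starts are scored first).
#' @slot maxIterations optimiser iteration cap.
#' @slot tol relative SSE tolerance used both for optimiser convergence and
#'   for declaring two starts tied (ties broken toward tau nearest 24 h).
#' @export
setClass("FitConfig",
    representation(
        tauBoundsH = "numeric",
        tauGridStepH = "numeric",
        dampingBoundsPerH = "numeric",
        nRefine = "integer",
        maxIterations = "integer",
        tol = "numeric"
    )
)

setValidity("FitConfig", function(object) {
    msg <- character(0)
    if (length(object@tauBoundsH) != 2L || diff(object@tauBoundsH) <= 0 ||
        object@tauBoundsH[1L] <= 0)
        msg <- c(msg, "tauBoundsH must be ordered positive bounds [min, max]")
    if (length(object@tauGridStepH) != 1L || object@tauGridStepH <= 0)
        msg <- c(msg, "tauGridStepH must be > 0")
    if (length(object@dampingBoundsPerH) != 2L ||
        diff(object@dampingBoundsPerH) <= 0)
        msg <- c(msg, "dampingBoundsPerH must be ordered bounds [min, max]")
    if (object@nRefine < 1L) msg <- c(msg, "nRefine must be >= 1")
    if (length(msg)) msg else TRUE
})

#' @rdname FitConfig-class
#' @param tauBoundsH,tauGridStepH,dampingBoundsPerH,nRefine,maxIterations,tol
#'   see slots.
#' @export
fitConfig <- function(tauBoundsH = c(16, 40), tauGridStepH = 1,
                      dampingBoundsPerH = c(-0.05, 0.10), nRefine = 5L,
                      maxIterations = 200L, tol = 1e-8) {
    new("FitConfig", tauBoundsH = as.numeric(tauBoundsH),
        tauGridStepH = tauGridStepH,
        dampingBoundsPerH = as.numeric(dampingBoundsPerH),
        nRefine = as.integer(nRefine),
        maxIterations = as.integer(maxIterations), tol = tol)
}

## ---------------------------------------------------------------------------
## RhythmFit
## ---------------------------------------------------------------------------

#' RhythmFit: result of a damped-cosine fit
#'
#' @slot sampleId sample identifier.
#' @slot tauH estimated free-running period, hours.
#' @slot amplitudeCps fitted oscillation amplitude at DD onset, CPS (>= 0).
#' @slot dampingPerH fitted damping rate, 1/h.
#' @slot phaseH fitted peak phase in `[0, tauH)`, hours after DD onset.
#' @slot offsetCps fitted constant offset of the detrended data.
#' @slot error one minus the Pearson correlation between fitted curve and
#'   detrended data; in `[0, 2]`, lower = more trustworthy period.
#' @slot meanCps mean expression level (CPS) of the analysed raw series.
#' @slot converged whether the optimiser converged.
#' @slot nPoints number of fitted points.
#' @slot timesH,dataValues,fittedValues the fitted window, for plotting.
#' @export
setClass("RhythmFit",
    representation(
        sampleId = "character",
        tauH = "numeric",
        amplitudeCps = "numeric",
        dampingPerH = "numeric",
        phaseH = "numeric",
        offsetCps = "numeric",
        error = "numeric",
        meanCps = "numeric",
        converged = "logical",
        nPoints = "integer",
        timesH = "numeric",
        dataValues = "numeric",
        fittedValues = "numeric"
    )
)

setValidity("RhythmFit", function(object) {
    msg <- character(0)
    if (!is.na(object@error) && (object@error < 0 || object@error > 2))
        msg <- c(msg, "error must lie in [0, 2]")
    if (!is.na(object@amplitudeCps) && object@amplitudeCps < 0)
        msg <- c(msg, "amplitudeCps must be >= 0")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Q10Result
## ---------------------------------------------------------------------------

#' Q10Result: temperature-compensation coefficient from two (tau, T) pairs
#'
#' `q10 = (tauCold / tauWarm) ^ (10 / (tWarm - tCold))`. Values near 1
#' indicate a temperature-compensated clock; values below 1 indicate
#' over-compensation (the rhythm slows as temperature rises).
#'
#' @slot tauColdH,tColdC period (h) and temperature (deg C) of the cold group.
#' @slot tauWarmH,tWarmC period and temperature of the warm group.
#' @slot q10 the coefficient, full precision.
#' @export
setClass("Q10Result",
    representation(
        tauColdH = "numeric",
        tColdC = "numeric",
        tauWarmH = "numeric",
        tWarmC = "numeric",
        q10 = "numeric"
    )
)

setValidity("Q10Result", function(object) {
    msg <- character(0)
    if (object@tWarmC <= object@tColdC)
        msg <- c(msg, "tWarmC must exceed tColdC")
    if (object@tauColdH <= 0 || object@tauWarmH <= 0)
        msg <- c(msg, "periods must be > 0")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## EffectSize
## ---------------------------------------------------------------------------

#' EffectSize: bootstrap mean difference between two groups
#'
#' Unpaired mean difference `mean(test) - mean(control)` with a bootstrap
#' resampling distribution and confidence interval, in the estimation
#' statistics style: the effect size and its interval are reported instead
#' of a p value; an interval crossing zero plays the role of "no detectable
#' difference".
#'
#' @slot controlLabel,testLabel group labels.
#' @slot meanDifference observed `mean(test) - mean(control)`.
#' @slot ciLow,ciHigh confidence interval bounds.
#' @slot nControl,nTest group sizes.
#' @slot nBoot number of bootstrap resamples.
#' @slot ciLevel confidence level (default 0.95).
#' @slot method `"bca"` or `"percentile"`.
#' @slot resamples the bootstrap distribution of the mean difference.
#' @slot crossesZero whether the interval contains zero.
#' @export
setClass("EffectSize",
    representation(
        controlLabel = "character",
        testLabel = "character",
        meanDifference = "numeric",
        ciLow = "numeric",
        ciHigh = "numeric",
        nControl = "integer",
        nTest = "integer",
        nBoot = "integer",
        ciLevel = "numeric",
        method = "character",
        resamples = "numeric",
        crossesZero = "logical"
    )
)

setValidity("EffectSize", function(object) {
    msg <- character(0)
    if (object@ciLevel <= 0 || object@ciLevel >= 1)
        msg <- c(msg, "ciLevel must lie in (0, 1)")
    if (!object@method %in% c("bca", "percentile"))
        msg <- c(msg, "method must be 'bca' or 'percentile'")
    if (length(msg)) msg else TRUE
})
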