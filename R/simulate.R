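#' @include AllClasses.R
NULL

## Counter-based per-sample seed: reproducible regardless of the order in
## which cohort samples are generated. Arithmetic in doubles, exact far below
## 2^53; result kept inside the 32-bit integer range set.seed() accepts.
.sampleSeed <- function(baseSeed, index) {
    m <- 2147483647
    as.integer((as.numeric(baseSeed) %% m + (as.numeric(index) * 1000003) %% m) %% m)
}

## Deterministic expected signal at recording times t (hours from recording
## start); ddOnsetH marks the end of the entrainment segment.
.expectedSignal <- function(params, t) {
    t0 <- params@ldHours
    params@baselineCps * exp(-params@trendDecayPerH * t) +
        params@amplitudeCps * exp(-params@dampingPerH * (t - t0)) *
            cos(2 * pi * (t - t0 - params@phaseH) / params@periodH)
}

#' Simulate one bioluminescence recording
#'
#' Generates a damped circadian oscillation riding on an exponentially
#' decaying baseline — the shape of a luciferase reporter trace in which
#' substrate depletion pulls the mean level down while the clock drives the
#' oscillation. See [SimParams-class] for the signal model. The recording
#' starts with `ldHours` of entrainment (same waveform, phase-locked so
#' that, with the default phase, the trough falls at lights-on), followed by
#' `ddHours` of free run; `ddOnsetH` is set to the LD/DD transition.
#'
#' Noise: `"poisson"` draws counts with the expected signal as rate (photon
#' counting), `"gaussian"` adds N(0, `noiseSdCps`), `"none"` returns the
#' deterministic signal. Negative expected or noisy values are clipped to 0
#' with a warning.
#'
#' @param params a [SimParams-class] object.
#' @param seed integer seed; identical seeds give identical traces.
#' @param sampleIdText sample identifier for the resulting series.
#' @return a [LumiSeries] with `annotations$truePeriodH` recording the
#'   generating period.
#' @examples
#' ts <- simulateSeries(simParams(noiseModel = "none"), seed = 1)
#' ts
#' @export
simulateSeries <- function(params, seed, sampleIdText = "sim1") {
    stopifnot(is(params, "SimParams"))
    validObject(params)
    t <- seq(0, params@ldHours + params@ddHours, by = params@samplingIntervalH)
    mu <- .expectedSignal(params, t)
    nNeg <- sum(mu < 0)
    if (nNeg)
        warning(sprintf("%d expected counts < 0 clipped to 0 for sample '%s'",
                        nNeg, sampleIdText))
    muPos <- pmax(mu, 0)
    y <- switch(params@noiseModel,
        none = muPos,
        poisson = {
            set.seed(as.integer(seed))
            as.numeric(stats::rpois(length(t), muPos))
        },
        gaussian = {
            set.seed(as.integer(seed))
            pmax(muPos + stats::rnorm(length(t), sd = params@noiseSdCps), 0)
        })
    LumiSeries(sampleIdText, t, y, ddOnsetH = params@ldHours,
               annotations = list(truePeriodH = params@periodH,
                                  noiseModel = params@noiseModel))
}

#' Simulate an arrhythmic recording
#'
#' The clock-less control: the same baseline trend and noise as
#' [simulateSeries()] but with the oscillation amplitude forced to zero,
#' emulating reporter expression in a null-mutant background in which the
#' molecular clock does not run. Downstream, such series should fail any
#' sensible rhythm-quality cutoff.
#'
#' @inheritParams simulateSeries
#' @return a [LumiSeries].
#' @export
simulateArrhythmic <- function(params, seed, sampleIdText = "arr1") {
    stopifnot(is(params, "SimParams"))
    flat <- params
    flat@amplitudeCps <- 0
    out <- simulateSeries(flat, seed, sampleIdText = sampleIdText)
    out@annotations$truePeriodH <- NA_real_
    out@annotations$arrhythmic <- TRUE
    out
}

#' Expected period at a temperature under a Q10 relation
#'
#' \deqn{\tau(T) = \tau_{ref} \, q_{10}^{-(T - T_{ref})/10}}
#' With `q10 < 1` the period lengthens as temperature rises
#' (over-compensation); with `q10 = 1` it is constant (perfect
#' compensation).
#'
#' @param tauRefH reference period, hours.
#' @param tRefC reference temperature, deg C.
#' @param q10True Q10 coefficient (> 0).
#' @param temperatureC temperature(s) at which to evaluate, deg C.
#' @return expected period(s), hours.
#' @examples
#' tauAtTemperature(21, 18, 0.85, 29) # about 25.1 h
#' @export
tauAtTemperature <- function(tauRefH, tRefC, q10True, temperatureC) {
    stopifnot(q10True > 0, tauRefH > 0)
    tauRefH * q10True^(-(temperatureC - tRefC) / 10)
}

#' Draw the true periods of a cohort
#'
#' One period per sample: the Q10-determined expectation at the sample's
#' temperature plus Normal(0, `tauSdH`) between-sample variation. Uses the
#' same counter-based per-sample seeds as [simulateCohort()], so the drawn
#' periods match the generated cohort exactly.
#'
#' @param design a [CohortDesign-class].
#' @return data.frame with columns `sample_id`, `temperature_c`,
#'   `true_tau_h`.
#' @export
drawTruePeriods <- function(design) {
    stopifnot(is(design, "CohortDesign"))
    validObject(design)
    grid <- expand.grid(rep = seq_len(design@nPerTemperature),
                        temperature_c = design@temperatures)
    idx <- seq_len(nrow(grid))
    ## even counter values seed the period draw, odd ones the trace noise,
    ## so the two random streams of a sample stay distinct
    tau <- vapply(idx, function(i) {
        set.seed(.sampleSeed(design@rngSeed, 2 * i))
        tauAtTemperature(design@tauRefH, design@tRefC, design@q10True,
                         grid$temperature_c[i]) +
            stats::rnorm(1, 0, design@tauSdH)
    }, numeric(1))
    data.frame(sample_id = sprintf("s%04d_T%g", idx, grid$temperature_c),
               temperature_c = grid$temperature_c, true_tau_h = tau)
}

#' Simulate a multi-temperature cohort
#'
#' Generates `nPerTemperature` recordings at each design temperature. Each
#' sample's true period is drawn via [drawTruePeriods()]; the rest of the
#' signal follows the design's [SimParams-class] template. The returned
#' [LumiSet] carries a sample table in `S4Vectors::metadata(.)$samples`
#' (sample_id, genotype, tissue, temperature_c, dd_onset_h, true_tau_h) —
#' the ground truth for closed-loop recovery checks.
#'
#' @param design a [CohortDesign-class].
#' @return a [LumiSet].
#' @examples
#' design <- cohortDesign(temperatures = c(18, 29), nPerTemperature = 2L,
#'                        params = simParams(noiseModel = "none"))
#' coh <- simulateCohort(design)
#' S4Vectors::metadata(coh)$samples
#' @export
simulateCohort <- function(design) {
    stopifnot(is(design, "CohortDesign"))
    validObject(design)
    truth <- drawTruePeriods(design)
    series <- lapply(seq_len(nrow(truth)), function(i) {
        p <- design@params
        p@periodH <- truth$true_tau_h[i]
        s <- simulateSeries(p, seed = .sampleSeed(design@rngSeed, 2 * i + 1),
                            sampleIdText = truth$sample_id[i])
        s@temperatureC <- truth$temperature_c[i]
        s@annotations$genotype <- design@genotype
        s@annotations$tissue <- design@tissue
        s
    })
    out <- LumiSet(series)
    metadata(out)$samples <- data.frame(
        sample_id = truth$sample_id,
        genotype = design@genotype,
        tissue = design@tissue,
        temperature_c = truth$temperature_c,
        dd_onset_h = design@params@ldHours,
        true_tau_h = truth$true_tau_h)
    out
}
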