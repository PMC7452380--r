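#' @include AllClasses.R AllGenerics.R
NULL

## Variable-projection objective: for fixed (tau, lambda) the model
##   a e^{-lambda t} cos(w t) + b e^{-lambda t} sin(w t) + c,  w = 2 pi / tau
## is linear in (a, b, c); profile them out by linear least squares.
## When the data were detrended by subtracting a moving average, the same
## (linear) filter is applied to the oscillatory regressors: the data and
## the model then carry identical edge distortion, which would otherwise
## bias the period estimate.
.vpDesign <- function(t, tau, lambda, filterWindowH = NULL) {
    w <- 2 * pi / tau
    e <- exp(-lambda * t)
    ec <- e * cos(w * t)
    es <- e * sin(w * t)
    if (!is.null(filterWindowH)) {
        ec <- ec - .movingAverage(t, ec, filterWindowH)
        es <- es - .movingAverage(t, es, filterWindowH)
    }
    cbind(ec, es, 1)
}

.vpSSE <- function(par, t, y, filterWindowH = NULL) {
    X <- .vpDesign(t, par[1L], par[2L], filterWindowH)
    fit <- stats::.lm.fit(X, y)
    sum(fit$residuals^2)
}

#' Rhythm-quality error: one minus the Pearson correlation
#'
#' The fit error used throughout: `1 - cor(fit, data)`, ranging over
#' `[0, 2]` — 0 for a perfect fit, 1 for an uninformative one, 2 for a fit
#' in antiphase with the data. Lower error means a more trustworthy period
#' estimate. If either argument has zero variance the fit carries no rhythm
#' information and the error is 1, with a warning.
#'
#' @param fittedValues fitted curve sampled at the data times.
#' @param dataValues detrended data values, same length (>= 3).
#' @return a single number in `[0, 2]`.
#' @examples
#' computeFitError(sin(1:50), sin(1:50))   # 0
#' computeFitError(-sin(1:50), sin(1:50))  # 2
#' @export
computeFitError <- function(fittedValues, dataValues) {
    stopifnot(length(fittedValues) == length(dataValues),
              length(dataValues) >= 3L)
    if (stats::sd(fittedValues) == 0 || stats::sd(dataValues) == 0) {
        warning("zero variance in fit or data; error set to 1 (uninformative fit)")
        return(1)
    }
    1 - stats::cor(fittedValues, dataValues)
}

#' Fit a damped cosine to a detrended series
#'
#' Least-squares fit of
#' \deqn{r(t) \approx A\, e^{-\lambda t} \cos\big(2\pi (t - \phi)/\tau\big) + c}
#' to the detrended residuals, estimating the free-running period `tau`,
#' amplitude `A`, damping `lambda`, peak phase `phi` and offset `c`.
#'
#' Period fitting has severe local optima (every integer fraction/multiple
#' of the true period is a basin), so the fit is multi-start: every period
#' on a grid spanning `tauBoundsH` at `tauGridStepH` spacing is scored by
#' profiling out the linear parameters (`A cos`, `A sin`, `c` regression) at
#' `lambda = 0`; the best `nRefine` grid starts are then refined over
#' `(tau, lambda)` by bounded quasi-Newton optimisation, with the linear
#' parameters re-profiled at every step. The lowest final SSE wins; starts
#' tied within relative tolerance `tol` are resolved toward the period
#' nearest 24 h. The rhythm-quality `error` is computed by
#' [computeFitError()] on the fitted window.
#'
#' When the input was detrended by moving-average subtraction, the model's
#' oscillatory regressors are passed through the same filter before
#' comparison, so the edge distortion that the truncated window imprints on
#' the data appears identically in the model and cancels instead of biasing
#' the period. The reported amplitude, phase and damping describe the
#' underlying (unfiltered) cosine.
#'
#' @param d a [DetrendedSeries] (see [detrendMovingAverage()]). The data
#'   must span at least two minimal periods (`2 * tauBoundsH[1]`) and 16
#'   points.
#' @param cfg a [FitConfig-class] (defaults: period bounds 16-40 h, 1-h
#'   grid, damping in [-0.05, 0.10] per hour).
#' @return a [RhythmFit-class]; if every start fails, `converged` is `FALSE`
#'   and `error` is 1.
#' @examples
#' ts <- simulateSeries(simParams(noiseModel = "none", ldHours = 0), seed = 1)
#' fit <- fitDampedCosine(detrendMovingAverage(ts))
#' fit
#' @export
fitDampedCosine <- function(d, cfg = fitConfig()) {
    stopifnot(is(d, "DetrendedSeries"), is(cfg, "FitConfig"))
    validObject(cfg)
    t <- d@timesH
    y <- d@residuals
    n <- length(t)
    if (n < 16L)
        stop(sprintf("sample '%s': %d points; at least 16 required",
                     d@sampleId, n), call. = FALSE)
    span <- diff(range(t))
    if (span < 2 * cfg@tauBoundsH[1L])
        stop(sprintf(
            "sample '%s' spans %.1f h; at least %.1f h (two minimal periods) required",
            d@sampleId, span, 2 * cfg@tauBoundsH[1L]), call. = FALSE)

    grid <- seq(cfg@tauBoundsH[1L], cfg@tauBoundsH[2L], by = cfg@tauGridStepH)
    if (grid[length(grid)] < cfg@tauBoundsH[2L])
        grid <- c(grid, cfg@tauBoundsH[2L])
    ## match the detrending filter inside the fit (subtract mode only; the
    ## divide-mode transform is not linear, so its model is left unfiltered)
    fw <- if (d@mode == "subtract") d@windowH else NULL

    ## stage 1: cheap linear score of every grid start at lambda = 0
    sse0 <- vapply(grid, function(tau) .vpSSE(c(tau, 0), t, y, fw), numeric(1))
    starts <- grid[order(sse0)][seq_len(min(cfg@nRefine, length(grid)))]

    ## stage 2: nonlinear refinement over (tau, lambda)
    fits <- lapply(starts, function(tau0) {
        tryCatch(
            stats::optim(c(tau0, 0), .vpSSE, t = t, y = y, filterWindowH = fw,
                         method = "L-BFGS-B",
                         lower = c(cfg@tauBoundsH[1L], cfg@dampingBoundsPerH[1L]),
                         upper = c(cfg@tauBoundsH[2L], cfg@dampingBoundsPerH[2L]),
                         control = list(maxit = cfg@maxIterations,
                                        factr = cfg@tol / .Machine$double.eps)),
            error = function(e) NULL)
    })
    ok <- !vapply(fits, is.null, logical(1))
    if (!any(ok)) {
        warning(sprintf("all fit starts failed for sample '%s'", d@sampleId))
        return(new("RhythmFit", sampleId = d@sampleId, tauH = NA_real_,
                   amplitudeCps = NA_real_, dampingPerH = NA_real_,
                   phaseH = NA_real_, offsetCps = NA_real_, error = 1,
                   meanCps = NA_real_, converged = FALSE, nPoints = n,
                   timesH = t, dataValues = y, fittedValues = rep(NA_real_, n)))
    }
    fits <- fits[ok]
    sse <- vapply(fits, function(f) f$value, numeric(1))
    ## ties within relative tol broken toward tau nearest 24 h
    tied <- sse <= min(sse) * (1 + cfg@tol)
    cand <- which(tied)
    tauCand <- vapply(fits[cand], function(f) f$par[1L], numeric(1))
    best <- fits[[cand[which.min(abs(tauCand - 24))]]]

    converged <- best$convergence == 0L
    if (!converged) {
        ## L-BFGS-B can stop with a line-search error at (or very near) an
        ## optimum it cannot improve; a derivative-free polish either
        ## confirms the optimum or finishes the descent
        pol <- tryCatch(stats::optim(best$par, .vpSSE, t = t, y = y,
                                     filterWindowH = fw,
                                     control = list(maxit = 500L)),
                        error = function(e) NULL)
        if (!is.null(pol)) {
            if (pol$value < best$value) {
                par <- pmin(pmax(pol$par,
                                 c(cfg@tauBoundsH[1L], cfg@dampingBoundsPerH[1L])),
                            c(cfg@tauBoundsH[2L], cfg@dampingBoundsPerH[2L]))
                best$par <- par
                best$value <- .vpSSE(par, t, y, fw)
            }
            converged <- pol$convergence == 0L ||
                pol$value >= best$value - cfg@tol * (best$value + 1e-12)
        }
    }

    tau <- best$par[1L]
    lambda <- best$par[2L]
    X <- .vpDesign(t, tau, lambda, fw)
    coefs <- stats::.lm.fit(X, y)$coefficients
    a <- coefs[1L]; b <- coefs[2L]; cc <- coefs[3L]
    A <- sqrt(a^2 + b^2)
    w <- 2 * pi / tau
    phi <- (atan2(b, a) / w) %% tau
    fitted <- as.numeric(X %*% coefs)
    err <- computeFitError(fitted, y)
    new("RhythmFit", sampleId = d@sampleId, tauH = tau, amplitudeCps = A,
        dampingPerH = lambda, phaseH = phi, offsetCps = cc,
        error = err, meanCps = NA_real_,
        converged = converged, nPoints = n,
        timesH = t, dataValues = y, fittedValues = fitted)
}

#' @rdname meanLevel
#' @export
setMethod("meanLevel", "LumiSeries", function(x) {
    if (!length(x@cps)) stop("empty series", call. = FALSE)
    mean(x@cps)
})

#' Preprocess and fit one sample
#'
#' The per-sample pipeline stage: discard the initial entrainment window,
#' record the mean expression level of the analysed (post-discard) raw
#' series, extract the DD segment, detrend, and fit the damped cosine.
#'
#' @param ts a [LumiSeries] with `ddOnsetH` set.
#' @param cfg a [FitConfig-class].
#' @param discardInitialH hours discarded from the start (default 24, one
#'   LD cycle).
#' @param detrendWindowH,detrendMode passed to [detrendMovingAverage()].
#' @return a [RhythmFit-class] with `meanCps` filled in.
#' @export
fitSample <- function(ts, cfg = fitConfig(), discardInitialH = 24,
                      detrendWindowH = 24, detrendMode = "subtract") {
    trimmed <- discardInitial(ts, discardInitialH)
    ml <- meanLevel(trimmed)
    d <- detrendMovingAverage(extractDD(trimmed), windowH = detrendWindowH,
                              mode = detrendMode)
    fit <- fitDampedCosine(d, cfg)
    fit@meanCps <- ml
    fit
}

#' Fit every sample of a set
#'
#' Applies [fitSample()] to each series, collecting results (and the
#' genotype / tissue / temperature annotations) into a per-sample fits
#' table. Samples whose preprocessing or fit raises an error are reported
#' as non-converged rows with `error = NA` rather than aborting the cohort.
#'
#' @inheritParams fitSample
#' @param x a [LumiSet].
#' @return data.frame with one row per sample: `sample_id`, `genotype`,
#'   `tissue`, `temperature_c`, `tau_h`, `amplitude_cps`, `damping_per_h`,
#'   `phase_h`, `offset_cps`, `error`, `mean_cps`, `converged`, `n_points`.
#' @export
fitCohort <- function(x, cfg = fitConfig(), discardInitialH = 24,
                      detrendWindowH = 24, detrendMode = "subtract") {
    stopifnot(is(x, "LumiSet"))
    rows <- lapply(as.list(x), function(s) {
        ann <- s@annotations
        base <- data.frame(
            sample_id = s@sampleId,
            genotype = if (!is.null(ann$genotype)) ann$genotype else NA_character_,
            tissue = if (!is.null(ann$tissue)) ann$tissue else NA_character_,
            temperature_c = s@temperatureC)
        fit <- tryCatch(
            fitSample(s, cfg, discardInitialH, detrendWindowH, detrendMode),
            error = function(e) {
                warning(sprintf("fit failed for sample '%s': %s",
                                s@sampleId, conditionMessage(e)))
                NULL
            })
        if (is.null(fit))
            return(cbind(base, data.frame(
                tau_h = NA_real_, amplitude_cps = NA_real_,
                damping_per_h = NA_real_, phase_h = NA_real_,
                offset_cps = NA_real_, error = NA_real_, mean_cps = NA_real_,
                converged = FALSE, n_points = NA_integer_)))
        cbind(base, as.data.frame(fit))
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Tabulate a RhythmFit
#'
#' @param x a [RhythmFit-class].
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return one-row data.frame of the scalar fit fields.
#' @export
as.data.frame.RhythmFit <- function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(tau_h = x@tauH, amplitude_cps = x@amplitudeCps,
               damping_per_h = x@dampingPerH, phase_h = x@phaseH,
               offset_cps = x@offsetCps, error = x@error,
               mean_cps = x@meanCps, converged = x@converged,
               n_points = x@nPoints)
}
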