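test_that("fit error is one minus the Pearson correlation", {
    y <- sin(seq(0, 8 * pi, length.out = 100))
    expect_equal(computeFitError(y, y), 0)
    expect_equal(computeFitError(-y, y), 2)
    ## orthogonality of sin and cos over whole cycles (brute-force r)
    t <- seq(0, 48, by = 0.5)[-97]
    s <- sin(2 * pi * t / 24)
    co <- cos(2 * pi * t / 24)
    expect_equal(computeFitError(s, co), 1 - cor(s, co))
    expect_lt(abs(computeFitError(s, co) - 1), 1e-10)
    expect_warning(e <- computeFitError(rep(1, 10), 1:10), "zero variance")
    expect_equal(e, 1)
})

test_that("fit error is invariant under positive affine transforms", {
    set.seed(4)
    a <- rnorm(50)
    b <- a + rnorm(50, sd = 0.3)
    e0 <- computeFitError(a, b)
    expect_equal(computeFitError(2.5 * a + 7, b), e0, tolerance = 1e-12)
    expect_equal(computeFitError(a, 0.1 * b - 3), e0, tolerance = 1e-12)
})

test_that("a noiseless 24-h oscillation is recovered essentially exactly", {
    ts <- simulateSeries(simParams(noiseModel = "none", dampingPerH = 0,
                                   trendDecayPerH = 0), seed = 1)
    fit <- fitSample(ts)
    expect_lt(abs(fit@tauH - 24), 0.01)
    expect_lt(fit@error, 0.001)
    expect_true(fit@converged)
    expect_equal(fit@amplitudeCps, 100, tolerance = 0.05)
    ## phase is reported in [0, tau); a peak at DD onset may wrap to just
    ## below tau
    expect_lt(min(fit@phaseH, fit@tauH - fit@phaseH), 0.1)
})

test_that("a long-period damped oscillation is recovered", {
    ts <- simulateSeries(simParams(periodH = 30, dampingPerH = 0.01,
                                   noiseModel = "none", ddHours = 120), seed = 2)
    fit <- fitSample(ts)
    expect_lt(abs(fit@tauH - 30), 0.1)
    expect_equal(fit@dampingPerH, 0.01, tolerance = 0.25)
})

test_that("the period estimate is invariant to scale and offset", {
    ts <- makeRhythmic(seed = 8, noise = "gaussian", sd = 10)
    tau0 <- fitSample(ts)@tauH
    scaled <- LumiSeries("s", timesH(ts), 3 * cps(ts) + 250, ddOnsetH = 24)
    expect_equal(fitSample(scaled)@tauH, tau0, tolerance = 1e-4)
})

test_that("the fit agrees with a brute-force periodogram scan", {
    for (tau in c(20.5, 26, 31)) {
        ts <- simulateSeries(simParams(periodH = tau, noiseModel = "none",
                                       ddHours = 96), seed = 1)
        d <- detrendMovingAverage(extractDD(discardInitial(ts, 24)))
        fit <- fitDampedCosine(d)
        scan <- oraclePeriodScan(d@timesH, d@residuals)
        expect_lt(abs(fit@tauH - scan), 1)  # within one grid bin
    }
})

test_that("white-noise series fit badly", {
    errs <- vapply(1:5, function(i)
        fitSample(simulateArrhythmic(simParams(), seed = 100 + i))@error,
        numeric(1))
    expect_true(all(errs > 0.5))
})

test_that("data requirements are enforced", {
    short <- new("DetrendedSeries", sampleId = "s", timesH = 0:20,
                 residuals = rnorm(21), trend = rep(0, 21), windowH = 24,
                 mode = "subtract", temperatureC = NA_real_,
                 annotations = list())
    expect_error(fitDampedCosine(short), "two minimal periods")
    tiny <- new("DetrendedSeries", sampleId = "s", timesH = seq(0, 70, by = 7),
                residuals = rnorm(11), trend = rep(0, 11), windowH = 24,
                mode = "subtract", temperatureC = NA_real_,
                annotations = list())
    expect_error(fitDampedCosine(tiny), "16 required")
})

test_that("mean level matches raw averages and the analytic time average", {
    expect_equal(meanLevel(LumiSeries("s", 0:9, rep(100, 10))), 100)
    expect_equal(meanLevel(LumiSeries("s", 0:1, c(0, 100))), 50)
    ## noiseless damped signal vs its continuous-time average (quadrature)
    p <- simParams(noiseModel = "none")
    ts <- discardInitial(simulateSeries(p, seed = 1), 24)
    f <- function(t) oracleSignal(t, 24, 100, 0.005, 0, 150, 0.005, 24)
    avg <- integrate(f, 24, 120, subdivisions = 2000L)$value / 96
    expect_equal(meanLevel(ts), avg, tolerance = 0.01)
})

test_that("cohort fitting collects annotations and survives bad samples", {
    design <- cohortDesign(temperatures = c(18, 29), nPerTemperature = 2L,
                           params = simParams(noiseModel = "gaussian",
                                              noiseSdCps = 10),
                           rngSeed = 3L)
    coh <- simulateCohort(design)
    fits <- fitCohort(coh)
    expect_equal(nrow(fits), 4L)
    expect_setequal(fits$temperature_c, c(18, 18, 29, 29))
    expect_true(all(fits$converged))
    md <- S4Vectors::metadata(coh)$samples
    expect_equal(fits$tau_h, md$true_tau_h, tolerance = 0.05)
    ## a sample too short to fit is reported, not fatal
    broken <- LumiSet(c(as.list(coh),
                        list(LumiSeries("stub", 0:30, rep(5, 31), ddOnsetH = 0))))
    expect_warning(fits2 <- fitCohort(broken), "fit failed .*stub")
    expect_equal(nrow(fits2), 5L)
    expect_false(fits2$converged[5L])
})
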