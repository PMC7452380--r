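test_that("noiseless series reproduce the closed-form signal exactly", {
    p <- simParams(periodH = 24, amplitudeCps = 80, dampingPerH = 0.01,
                   phaseH = 3, baselineCps = 200, trendDecayPerH = 0.004,
                   noiseModel = "none")
    ts <- simulateSeries(p, seed = 1)
    expected <- oracleSignal(timesH(ts), 24, 80, 0.01, 3, 200, 0.004,
                             ldHours = 24)
    expect_equal(cps(ts), expected, tolerance = 1e-12)
    expect_identical(ddOnsetH(ts), 24)
    expect_true(all(diff(timesH(ts)) > 0))
})

test_that("degenerate parameters give a constant series at the baseline", {
    p <- simParams(amplitudeCps = 0, trendDecayPerH = 0, noiseModel = "none")
    ts <- simulateSeries(p, seed = 1)
    expect_true(all(cps(ts) == 150))
})

test_that("an undamped 24-h oscillation peaks every 24 h", {
    p <- simParams(periodH = 24, dampingPerH = 0, trendDecayPerH = 0,
                   noiseModel = "none", phaseH = 0)
    y <- cps(simulateSeries(p, seed = 1))
    t <- timesH(simulateSeries(p, seed = 1))
    peaks <- t[which(diff(sign(diff(y))) == -2) + 1L]
    expect_equal(diff(peaks), rep(24, length(peaks) - 1L))
})

test_that("seeding is reproducible and Poisson noise is unbiased", {
    p <- simParams(noiseModel = "poisson")
    a <- simulateSeries(p, seed = 42)
    b <- simulateSeries(p, seed = 42)
    expect_identical(cps(a), cps(b))
    d <- simulateSeries(p, seed = 43)
    expect_false(identical(cps(a), cps(d)))
    ## Monte-Carlo mean against the deterministic signal mean: the grand
    ## mean over k traces has SE sqrt(mean(mu)/ (n k)) for Poisson counts
    mu <- oracleSignal(timesH(a), 24, 100, 0.005, 0, 150, 0.005, 24)
    k <- 40
    grand <- mean(vapply(seq_len(k), function(i)
        mean(cps(simulateSeries(p, seed = 1000 + i))), numeric(1)))
    se <- sqrt(mean(mu) / (length(mu) * k))
    expect_lt(abs(grand - mean(mu)), 3 * se)
})

test_that("generated counts are never negative, whatever the noise", {
    for (nm in c("none", "gaussian", "poisson")) {
        p <- simParams(amplitudeCps = 300, baselineCps = 50,
                       noiseModel = nm, noiseSdCps = 80)
        expect_warning(ts <- simulateSeries(p, seed = 7), "clipped")
        expect_true(all(cps(ts) >= 0))
    }
})

test_that("invalid parameters are rejected with the offending field named", {
    expect_error(simParams(ddHours = 30), "ddHours")
    expect_error(simParams(samplingIntervalH = 8), "samplingIntervalH")
    expect_error(simParams(periodH = -1), "periodH")
    expect_error(simParams(amplitudeCps = -5), "amplitudeCps")
})

test_that("arrhythmic series are trend plus noise only", {
    p <- simParams(trendDecayPerH = 0.01, noiseModel = "none")
    ts <- simulateArrhythmic(p, seed = 1)
    expect_equal(cps(ts), 150 * exp(-0.01 * timesH(ts)), tolerance = 1e-12)
    expect_true(annotations(ts)$arrhythmic)
    ## reproducibility
    p2 <- simParams()
    expect_identical(cps(simulateArrhythmic(p2, 5)),
                     cps(simulateArrhythmic(p2, 5)))
})

test_that("an arrhythmic trace fails any sensible error cutoff", {
    fit <- fitSample(simulateArrhythmic(simParams(), seed = 11))
    expect_gt(fit@error, 0.5)
})

test_that("the temperature-to-period relation evaluates correctly", {
    expect_equal(tauAtTemperature(24, 25, 1, c(18, 21, 25, 29)), rep(24, 4))
    ## 21 h at 18 degC with Q10 = 0.85, evaluated at 29 degC
    expect_equal(tauAtTemperature(21, 18, 0.85, 29), 21 * 0.85^(-1.1),
                 tolerance = 1e-12)
    expect_equal(round(tauAtTemperature(21, 18, 0.85, 29), 2), 25.11)
})

test_that("drawn cohort periods converge to the Q10 relation (LLN)", {
    design <- cohortDesign(temperatures = 25, nPerTemperature = 10000L,
                           tauRefH = 21, tRefC = 18, q10True = 0.85,
                           tauSdH = 0.5, rngSeed = 2L)
    truth <- drawTruePeriods(design)
    expect_equal(nrow(truth), 10000L)
    target <- tauAtTemperature(21, 18, 0.85, 25)
    expect_lt(abs(mean(truth$true_tau_h) - target), 3 * 0.5 / sqrt(10000))
})

test_that("simulated cohorts carry ground-truth metadata and are reproducible", {
    design <- cohortDesign(temperatures = c(18, 29), nPerTemperature = 2L,
                           params = simParams(noiseModel = "none"),
                           rngSeed = 9L)
    coh <- simulateCohort(design)
    md <- S4Vectors::metadata(coh)$samples
    expect_equal(nrow(md), 4L)
    expect_setequal(md$temperature_c, c(18, 18, 29, 29))
    expect_true(all(c("true_tau_h", "dd_onset_h", "genotype", "tissue")
                    %in% names(md)))
    ## identical design -> identical traces
    coh2 <- simulateCohort(design)
    expect_identical(cps(coh[[1]]), cps(coh2[[1]]))
    expect_identical(cps(coh[[4]]), cps(coh2[[4]]))
    ## the recorded truth matches the generating period annotation
    expect_equal(annotations(coh[[2]])$truePeriodH, md$true_tau_h[2])
})
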