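# Independent oracles used across the suite. These deliberately avoid the
# package's fitting path: the periodogram is a plain linear regression scan,
# the bootstrap enumeration is exhaustive, and the signal oracle evaluates
# the closed form directly.

# Closed-form expected signal, written out independently of the generator.
oracleSignal <- function(t, periodH, amplitudeCps, dampingPerH, phaseH,
                         baselineCps, trendDecayPerH, ldHours) {
    t0 <- ldHours
    baselineCps * exp(-trendDecayPerH * t) +
        amplitudeCps * exp(-dampingPerH * (t - t0)) *
            cos(2 * pi * (t - t0 - phaseH) / periodH)
}

# Brute-force periodogram: R^2 of a cos+sin regression at each trial period;
# returns the period with the highest explained variance.
oraclePeriodScan <- function(t, y, periods = seq(16, 40, by = 0.05)) {
    r2 <- vapply(periods, function(p) {
        w <- 2 * pi / p
        summary(lm(y ~ cos(w * t) + sin(w * t)))$r.squared
    }, numeric(1))
    periods[which.max(r2)]
}

# Exhaustive two-group bootstrap for groups of size 2: all resample pairs of
# each group with multinomial weights, giving the exact distribution of the
# resampled mean difference.
oracleExhaustiveBoot <- function(control, test) {
    stopifnot(length(control) == 2L, length(test) == 2L)
    groupMeans <- function(g)
        data.frame(m = c(g[1], mean(g), g[2]), w = c(0.25, 0.5, 0.25))
    gc <- groupMeans(control)
    gt <- groupMeans(test)
    d <- outer(gt$m, gc$m, "-")
    w <- outer(gt$w, gc$w)
    o <- order(as.vector(d))
    data.frame(diff = as.vector(d)[o], w = as.vector(w)[o])
}

# Exact quantile of the enumerated distribution (smallest value with
# CDF >= p).
oracleQuantile <- function(dist, p) {
    cdf <- cumsum(dist$w)
    dist$diff[which(cdf >= p - 1e-12)[1L]]
}

# Small rhythmic test series shared by several files.
makeRhythmic <- function(seed = 1, periodH = 24, noise = "none", sd = 0,
                         ddHours = 96) {
    simulateSeries(simParams(periodH = periodH, noiseModel = noise,
                             noiseSdCps = sd, ddHours = ddHours), seed = seed)
}
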