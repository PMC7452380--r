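makeFits <- function(errors, tissue = "haltere", tau = 24, cps = 100) {
    data.frame(sample_id = sprintf("s%d", seq_along(errors)),
               genotype = "g", tissue = tissue, temperature_c = 25,
               tau_h = tau, error = errors, mean_cps = cps, converged = TRUE)
}

test_that("error cutoffs keep the trustworthy fits", {
    fits <- makeFits(c(0.1, 0.45, 0.6))
    expect_equal(nrow(filterFits(fits, errorCutoff = 0.5)), 2L)
    expect_equal(nrow(filterFits(fits, errorCutoff = 0.7)), 3L)
    expect_equal(attr(filterFits(fits, errorCutoff = 0.5), "excluded"), 1L)
    expect_warning(none <- filterFits(fits, errorCutoff = 0.05),
                   "no fits pass")
    expect_equal(nrow(none), 0L)
    ## non-converged fits are dropped regardless of error
    fits$converged[1L] <- FALSE
    expect_equal(nrow(filterFits(fits, errorCutoff = 0.7)), 2L)
})

test_that("the cutoff follows the assay class when not overridden", {
    fits <- rbind(makeFits(c(0.6, 0.4), tissue = "haltere"),
                  makeFits(c(0.6, 0.4), tissue = "whole_fly"))
    kept <- filterFits(fits)
    ## 0.6 passes the whole-fly cutoff (0.7) but not the culture cutoff (0.5)
    expect_equal(nrow(kept), 3L)
    expect_equal(sum(kept$tissue == "whole_fly"), 2L)
})

test_that("group summaries report mean and SEM per group", {
    fits <- makeFits(c(0.1, 0.1, 0.1), tau = c(23, 24, 25))
    s <- summarizeGroups(fits)
    expect_equal(s$n, 3L)
    expect_equal(s$tau_mean_h, 24)
    expect_equal(s$tau_sem_h, 1 / sqrt(3), tolerance = 1e-12)
    ## single fit: SEM undefined
    s1 <- summarizeGroups(makeFits(0.1))
    expect_true(is.na(s1$tau_sem_h))
    expect_equal(s1$tau_mean_h, 24)
    ## identical values: SEM zero
    s0 <- summarizeGroups(makeFits(c(0.2, 0.2), tau = c(24, 24)))
    expect_equal(s0$tau_sem_h, 0)
})

test_that("Q10 arithmetic matches the defining formula", {
    ## the flagship haltere protein-reporter contrast: 21.0 h at 18 degC
    ## vs 25.2 h at 29 degC gives an over-compensated Q10 of 0.85
    expect_equal(round(q10(computeQ10(21.0, 18, 25.2, 29)), 2), 0.85)
    expect_equal(q10(computeQ10(24, 18, 24, 29)), 1)
    expect_equal(q10(computeQ10(20, 20, 25, 30)), 0.8)  # exponent exactly 1
    expect_error(computeQ10(24, 25, 24, 25), "exceed")
    expect_error(computeQ10(-1, 18, 24, 29), "positive")
})

test_that("Q10 via periods equals Q10 via rates, and is monotone", {
    set.seed(2)
    for (i in 1:20) {
        tc <- runif(1, 18, 22); tw <- tc + runif(1, 2, 12)
        tauC <- runif(1, 18, 30); tauW <- runif(1, 18, 30)
        viaPeriod <- q10(computeQ10(tauC, tc, tauW, tw))
        viaRate <- ((1 / tauW) / (1 / tauC))^(10 / (tw - tc))
        expect_equal(viaPeriod, viaRate, tolerance = 1e-12)
    }
    q <- vapply(seq(22, 30, by = 2), function(tw)
        q10(computeQ10(21, 18, tw, 29)), numeric(1))
    expect_true(all(diff(q) < 0))
})

test_that("Q10 composes geometrically across a temperature ladder", {
    tau1 <- 21; tau2 <- 23.1; tau3 <- 25.2
    q13 <- q10(computeQ10(tau1, 18, tau3, 29))
    q12 <- q10(computeQ10(tau1, 18, tau2, 25))
    q23 <- q10(computeQ10(tau2, 25, tau3, 29))
    composed <- (q12^(25 - 18) * q23^(29 - 25))^(1 / (29 - 18))
    expect_equal(q13, composed, tolerance = 1e-12)
})

test_that("period differences across temperatures are signed hours", {
    expect_equal(deltaTau(21.0, 25.2), 4.2)
    expect_equal(deltaTau(22.1, 24.8), 2.7)
    expect_equal(deltaTau(24, 24), 0)
    expect_lt(deltaTau(24.8, 23.2), 0)  # speeding up with warmth
})

test_that("Q10 per group defaults to the temperature extremes", {
    summary <- data.frame(genotype = rep(c("g1", "g2"), each = 3),
                          tissue = "haltere",
                          temperature_c = rep(c(18, 25, 29), 2),
                          n = 5L,
                          tau_mean_h = c(21.04, 24.01, 25.24,
                                         24.0, 24.0, 24.0),
                          tau_sem_h = 0.1, error_mean = 0.1, error_sem = 0.01,
                          cps_mean = 100, cps_sem = 10)
    qt <- q10FromSummary(summary)
    expect_equal(nrow(qt), 2L)
    expect_equal(qt$t_cold_c, c(18, 18))
    expect_equal(qt$t_warm_c, c(29, 29))
    expect_equal(qt$q10[qt$genotype == "g2"], 1)
    ## printed-precision path rounds the means first
    qp <- q10FromSummary(summary, usePrintedPrecision = TRUE)
    expect_equal(qp$tau_cold_h[1L], 21.0)
    expect_equal(qp$q10[1L], q10(computeQ10(21.0, 18, 25.2, 29)))
    ## explicit pair not present in a group is skipped with a warning
    w <- capture_warnings(q10FromSummary(summary, tColdC = 18, tWarmC = 21))
    expect_match(w, "skipped", all = TRUE)
})
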