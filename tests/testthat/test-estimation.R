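test_that("mean differences are signed test-minus-control", {
    expect_equal(meanDifference(c(1, 2, 3), c(1, 2, 3)), 0)
    expect_equal(meanDifference(c(1, 2), c(4, 6)), 3.5)
    expect_equal(meanDifference(c(4, 6), c(1, 2)),
                 -meanDifference(c(1, 2), c(4, 6)))
    expect_error(meanDifference(numeric(0), 1:3), "non-empty")
})

test_that("bootstrap resampling is deterministic for a fixed seed", {
    a <- rnorm(10); b <- rnorm(12, 1)
    e1 <- bootstrapCI(a, b, nBoot = 300, seed = 11)
    e2 <- bootstrapCI(a, b, nBoot = 300, seed = 11)
    expect_identical(e1@resamples, e2@resamples)
    expect_identical(c(e1@ciLow, e1@ciHigh), c(e2@ciLow, e2@ciHigh))
    e3 <- bootstrapCI(a, b, nBoot = 300, seed = 12)
    expect_false(identical(e1@resamples, e3@resamples))
})

test_that("size-2 percentile intervals match exhaustive enumeration", {
    control <- c(1, 5); test <- c(10, 20)
    exact <- oracleExhaustiveBoot(control, test)
    es <- bootstrapCI(control, test, nBoot = 20000, method = "percentile",
                      seed = 3)
    ## the extreme resamples each carry probability 1/16 > 2.5%, so both
    ## exact 95% quantiles sit at the distribution's extremes
    expect_equal(es@ciLow, oracleQuantile(exact, 0.025))
    expect_equal(es@ciHigh, oracleQuantile(exact, 0.975))
    expect_equal(es@meanDifference, 15 - 3)
    ## the resample distribution only contains enumerated values
    expect_true(all(es@resamples %in% exact$diff))
})

test_that("identical constant groups give a point interval at zero", {
    es <- bootstrapCI(c(5, 5), c(5, 5), nBoot = 100, seed = 1)
    expect_equal(c(es@ciLow, es@ciHigh), c(0, 0))
    expect_true(es@crossesZero)
    expect_error(bootstrapCI(5, c(1, 2)), "at least 2")
})

test_that("BCa intervals agree with an independent implementation", {
    skip_if_not_installed("boot")
    set.seed(21)
    control <- rnorm(15, 10, 2)
    test <- rnorm(20, 12, 2)
    mine <- bootstrapCI(control, test, nBoot = 9999, seed = 5)
    dat <- data.frame(y = c(control, test),
                      g = rep(c(0, 1), c(15, 20)))
    stat <- function(d, i) {
        di <- d[i, ]
        mean(di$y[di$g == 1]) - mean(di$y[di$g == 0])
    }
    set.seed(6)
    bo <- boot::boot(dat, stat, R = 9999, strata = dat$g)
    bci <- boot::boot.ci(bo, type = "bca")$bca[4:5]
    ## independent resampling streams: agreement to Monte-Carlo accuracy
    expect_equal(mine@ciLow, bci[1], tolerance = 0.1)
    expect_equal(mine@ciHigh, bci[2], tolerance = 0.1)
})

test_that("percentile interval width shrinks roughly as 1/sqrt(n)", {
    widths <- vapply(c(10, 40, 160), function(n) {
        set.seed(n)
        es <- bootstrapCI(rnorm(n), rnorm(n), nBoot = 2000,
                          method = "percentile", seed = n + 1)
        es@ciHigh - es@ciLow
    }, numeric(1))
    expect_true(all(diff(widths) < 0))
    expect_gt(widths[1] / widths[2], 1.3)
    expect_lt(widths[1] / widths[2], 3.1)
})

test_that("shared-control comparisons preserve order and labels", {
    set.seed(9)
    values <- c(rnorm(8, 21), rnorm(8, 22), rnorm(8, 24), rnorm(8, 25))
    labels <- rep(c("18", "21", "25", "29"), each = 8)
    es <- sharedControl(values, labels, controlLabel = "18", nBoot = 400,
                        seed = 2)
    expect_length(es, 3L)
    expect_identical(names(es), c("21", "25", "29"))
    expect_true(all(vapply(es, function(e) e@controlLabel == "18", logical(1))))
    ## reproducible as a set
    es2 <- sharedControl(values, labels, controlLabel = "18", nBoot = 400,
                         seed = 2)
    expect_identical(effectsTable(es), effectsTable(es2))
    expect_error(sharedControl(values, labels, controlLabel = "20"),
                 "not present")
    expect_warning(only <- sharedControl(values[1:8], labels[1:8], "18"),
                   "only the control")
    expect_length(only, 0L)
})

test_that("crossing zero tracks the interval ends", {
    set.seed(13)
    same <- bootstrapCI(rnorm(25), rnorm(25), nBoot = 1000, seed = 1)
    expect_identical(same@crossesZero, same@ciLow <= 0 && same@ciHigh >= 0)
    far <- bootstrapCI(rnorm(25), rnorm(25, 5), nBoot = 1000, seed = 1)
    expect_false(far@crossesZero)
    expect_true(far@ciLow <= far@meanDifference &&
                far@meanDifference <= far@ciHigh)
})
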