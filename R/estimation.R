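#' @include AllClasses.R
NULL

#' Unpaired mean difference
#'
#' `mean(test) - mean(control)`: the effect size of estimation statistics,
#' in the units of the input (hours for periods, CPS for expression
#' levels).
#'
#' @param control,test non-empty numeric vectors.
#' @return a single number.
#' @export
meanDifference <- function(control, test) {
    if (!length(control) || !length(test))
        stop("both groups must be non-empty", call. = FALSE)
    mean(test) - mean(control)
}

## nBoot resampled means of x, as a vector (vectorised over resamples)
.resampleMeans <- function(x, nBoot) {
    n <- length(x)
    colMeans(matrix(x[sample.int(n, n * nBoot, replace = TRUE)], nrow = n))
}

## delete-one jackknife of the mean difference, over both groups
.jackknifeMD <- function(control, test) {
    nC <- length(control)
    nT <- length(test)
    sC <- sum(control)
    sT <- sum(test)
    c(mean(test) - (sC - control) / (nC - 1),
      (sT - test) / (nT - 1) - mean(control))
}

#' Bootstrap confidence interval for a mean difference
#'
#' Resamples both groups independently with replacement `nBoot` times,
#' forming the bootstrap distribution of `mean(test) - mean(control)`. The
#' interval is bias-corrected and accelerated (BCa; default) or plain
#' percentile. BCa corrects the percentile interval for median bias of the
#' bootstrap distribution (z0) and for skew via the jackknife acceleration;
#' with no bias and no skew it reduces to the percentile interval.
#'
#' Deterministic for a fixed `seed`. Degenerate inputs (both groups
#' constant and equal) give the point interval. If the BCa correction is
#' undefined (all resamples identical, or zero jackknife spread) the
#' percentile interval is returned with a warning and `method` set
#' accordingly.
#'
#' @param control,test numeric vectors, each of length >= 2.
#' @param nBoot number of bootstrap resamples (default 5000).
#' @param ciLevel confidence level (default 0.95).
#' @param method `"bca"` (default) or `"percentile"`.
#' @param seed optional integer seed.
#' @param controlLabel,testLabel labels stored in the result.
#' @return an [EffectSize-class].
#' @examples
#' es <- bootstrapCI(rnorm(20), rnorm(20, 1), nBoot = 500, seed = 1)
#' es
#' @export
bootstrapCI <- function(control, test, nBoot = 5000, ciLevel = 0.95,
                        method = c("bca", "percentile"), seed = NULL,
                        controlLabel = "control", testLabel = "test") {
    method <- match.arg(method)
    if (length(control) < 2L || length(test) < 2L)
        stop("each group needs at least 2 observations", call. = FALSE)
    stopifnot(nBoot >= 2, ciLevel > 0, ciLevel < 1)
    if (!is.null(seed)) set.seed(as.integer(seed))
    theta <- meanDifference(control, test)
    boots <- .resampleMeans(test, nBoot) - .resampleMeans(control, nBoot)
    alpha <- (1 - ciLevel) / 2
    probs <- c(alpha, 1 - alpha)
    usedMethod <- method
    if (method == "bca") {
        pBelow <- (sum(boots < theta) + 0.5 * sum(boots == theta)) / nBoot
        jk <- .jackknifeMD(control, test)
        dev <- mean(jk) - jk
        denom <- sum(dev^2)
        if (pBelow <= 0 || pBelow >= 1 || denom == 0) {
            if (stats::sd(boots) > 0)
                warning("BCa correction undefined; falling back to percentile interval")
            usedMethod <- "percentile"
        } else {
            z0 <- stats::qnorm(pBelow)
            a <- sum(dev^3) / (6 * denom^1.5)
            zq <- stats::qnorm(probs)
            probs <- stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
        }
    }
    ci <- unname(stats::quantile(boots, probs, type = 7))
    if (ci[1L] > theta || ci[2L] < theta)
        warning("confidence interval does not bracket the observed mean difference (pathological resampling)")
    new("EffectSize", controlLabel = controlLabel, testLabel = testLabel,
        meanDifference = theta, ciLow = ci[1L], ciHigh = ci[2L],
        nControl = length(control), nTest = length(test),
        nBoot = as.integer(nBoot), ciLevel = ciLevel, method = usedMethod,
        resamples = boots, crossesZero = ci[1L] <= 0 && ci[2L] >= 0)
}

#' Shared-control effect sizes
#'
#' Compares every non-control group against one common control — the
#' estimation-statistics analogue of an ANOVA with multiple comparisons
#' against a reference group. One [EffectSize-class] is produced per
#' non-control group, in input (first-appearance) order; the control group
#' is resampled afresh for each comparison. No multiplicity adjustment is
#' applied to the intervals: each is a plain per-comparison interval.
#'
#' @param values numeric vector of observations (e.g. per-sample periods).
#' @param labels group label per observation.
#' @param controlLabel label of the shared control group.
#' @param nBoot,ciLevel,method passed to [bootstrapCI()].
#' @param seed optional base seed; comparison `k` uses `seed + k`, so the
#'   whole set is reproducible.
#' @return named list of [EffectSize-class], one per non-control group
#'   (empty, with a warning, if only the control is present).
#' @export
sharedControl <- function(values, labels, controlLabel, nBoot = 5000,
                          ciLevel = 0.95, method = c("bca", "percentile"),
                          seed = NULL) {
    method <- match.arg(method)
    stopifnot(length(values) == length(labels))
    labels <- as.character(labels)
    if (!controlLabel %in% labels)
        stop("control label '", controlLabel, "' not present", call. = FALSE)
    control <- values[labels == controlLabel]
    others <- setdiff(unique(labels), controlLabel)
    if (!length(others)) {
        warning("only the control group present; no comparisons to make")
        return(list())
    }
    out <- lapply(seq_along(others), function(k) {
        bootstrapCI(control, values[labels == others[k]],
                    nBoot = nBoot, ciLevel = ciLevel, method = method,
                    seed = if (is.null(seed)) NULL else seed + k,
                    controlLabel = controlLabel, testLabel = others[k])
    })
    names(out) <- others
    out
}

#' Tabulate a list of effect sizes
#'
#' @param effects list of [EffectSize-class] (e.g. from [sharedControl()]).
#' @return data.frame, one row per comparison.
#' @export
effectsTable <- function(effects) {
    rows <- lapply(effects, function(e)
        data.frame(control = e@controlLabel, test = e@testLabel,
                   mean_difference = e@meanDifference,
                   ci_low = e@ciLow, ci_high = e@ciHigh,
                   n_control = e@nControl, n_test = e@nTest,
                   n_boot = e@nBoot, ci_level = e@ciLevel,
                   method = e@method, crosses_zero = e@crossesZero))
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
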