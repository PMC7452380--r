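#' @include AllClasses.R
NULL

#' Filter fits by rhythm-quality cutoff
#'
#' Keeps converged fits whose error (1 - r) is below the cutoff. The
#' defaults follow the two assay classes: isolated-tissue culture
#' recordings are held to `error < 0.5`, whole-animal recordings (where
#' movement and position add noise) to the laxer `error < 0.7`; the class
#' is chosen per row from the `tissue` column (`"whole_fly"` uses the
#' whole-animal cutoff). Pass `errorCutoff` to override with a single
#' cutoff for all rows.
#'
#' @param fits data.frame from [fitCohort()] (needs `error`, `converged`
#'   and, unless `errorCutoff` is given, `tissue`).
#' @param errorCutoff single cutoff in (0, 2], or `NULL` for the per-tissue
#'   defaults.
#' @param tissueCultureCutoff,wholeFlyCutoff the per-class defaults.
#' @return the retained rows, with attribute `excluded` (count of dropped
#'   fits). Warns if nothing survives.
#' @export
filterFits <- function(fits, errorCutoff = NULL, tissueCultureCutoff = 0.5,
                       wholeFlyCutoff = 0.7) {
    stopifnot(is.data.frame(fits))
    if (!is.null(errorCutoff)) {
        stopifnot(errorCutoff > 0, errorCutoff <= 2)
        cut <- rep(errorCutoff, nrow(fits))
    } else {
        tissue <- if ("tissue" %in% names(fits)) fits$tissue else
            rep(NA_character_, nrow(fits))
        cut <- ifelse(!is.na(tissue) & tissue == "whole_fly",
                      wholeFlyCutoff, tissueCultureCutoff)
    }
    keep <- !is.na(fits$error) & fits$error < cut & fits$converged
    out <- fits[keep, , drop = FALSE]
    attr(out, "excluded") <- sum(!keep)
    if (!nrow(out) && nrow(fits))
        warning("no fits pass the error cutoff")
    out
}

.semNA <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_

#' Summarise fits per experimental group
#'
#' Means and standard errors of the period, fit error and mean expression
#' level per group (default genotype x tissue x temperature). SEM is the
#' sample SD (n - 1 denominator) over sqrt(n); it is reported as `NA` for
#' groups of one.
#'
#' @param fits data.frame of (filtered) fits, see [filterFits()].
#' @param by grouping columns (default
#'   `c("genotype", "tissue", "temperature_c")`).
#' @return data.frame with one row per non-empty group: the grouping
#'   columns plus `n`, `tau_mean_h`, `tau_sem_h`, `error_mean`,
#'   `error_sem`, `cps_mean`, `cps_sem`.
#' @examples
#' fits <- data.frame(genotype = "g", tissue = "haltere", temperature_c = 25,
#'                    tau_h = c(23, 24, 25), error = 0.1, mean_cps = 100,
#'                    converged = TRUE)
#' summarizeGroups(fits)
#' @export
summarizeGroups <- function(fits, by = c("genotype", "tissue", "temperature_c")) {
    stopifnot(is.data.frame(fits), all(by %in% names(fits)))
    if (!nrow(fits)) {
        warning("no fits to summarise")
        return(data.frame())
    }
    key <- interaction(fits[by], drop = TRUE, lex.order = TRUE)
    rows <- lapply(split(fits, key), function(g) {
        cbind(g[1L, by, drop = FALSE],
              data.frame(n = nrow(g),
                         tau_mean_h = mean(g$tau_h),
                         tau_sem_h = .semNA(g$tau_h),
                         error_mean = mean(g$error),
                         error_sem = .semNA(g$error),
                         cps_mean = mean(g$mean_cps),
                         cps_sem = .semNA(g$mean_cps)))
    })
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    out[do.call(order, out[by]), , drop = FALSE]
}

#' Q10 temperature-compensation coefficient
#'
#' \deqn{Q_{10} = \left(\tau_{cold} / \tau_{warm}\right)^{10/(T_{warm} - T_{cold})}}
#' The factor by which the clock's rate changes per 10 deg C of warming.
#' `q10 = 1`: the period is temperature compensated; `q10 < 1`: the rhythm
#' slows as temperature rises (over-compensation); `q10 > 1`: it speeds up.
#'
#' @param tauColdH period at the colder temperature, hours (> 0).
#' @param tColdC colder temperature, deg C.
#' @param tauWarmH period at the warmer temperature, hours (> 0).
#' @param tWarmC warmer temperature, deg C (must exceed `tColdC`).
#' @return a [Q10Result-class]; extract the coefficient with [q10()].
#' @examples
#' q10(computeQ10(21.0, 18, 25.2, 29)) # ~0.85: over-compensated
#' @export
computeQ10 <- function(tauColdH, tColdC, tauWarmH, tWarmC) {
    if (tWarmC <= tColdC)
        stop("tWarmC must exceed tColdC", call. = FALSE)
    if (tauColdH <= 0 || tauWarmH <= 0)
        stop("periods must be positive", call. = FALSE)
    new("Q10Result", tauColdH = tauColdH, tColdC = tColdC,
        tauWarmH = tauWarmH, tWarmC = tWarmC,
        q10 = (tauColdH / tauWarmH)^(10 / (tWarmC - tColdC)))
}

#' Period change between two temperatures
#'
#' Signed difference `tauWarmH - tauColdH` in hours; positive when the
#' rhythm slows at the warmer temperature, negative when it speeds up.
#'
#' @param tauColdH,tauWarmH periods in hours (> 0); vectorised.
#' @return hours.
#' @export
deltaTau <- function(tauColdH, tauWarmH) {
    stopifnot(all(tauColdH > 0), all(tauWarmH > 0))
    tauWarmH - tauColdH
}

#' Q10 per group from a cohort summary
#'
#' Computes one Q10 per genotype x tissue from the group mean periods at
#' two temperatures — by default the lowest and highest temperature present
#' for that group. `usePrintedPrecision = TRUE` rounds the mean periods to
#' 1 decimal first, mirroring how a printed results table would be read
#' back; the default uses full precision.
#'
#' @param summary data.frame from [summarizeGroups()].
#' @param tColdC,tWarmC optional explicit temperature pair; groups lacking
#'   either temperature are skipped with a warning.
#' @param usePrintedPrecision round mean periods to 1 decimal before the
#'   Q10 computation (default `FALSE`).
#' @return data.frame with one row per genotype x tissue: `genotype`,
#'   `tissue`, `t_cold_c`, `tau_cold_h`, `t_warm_c`, `tau_warm_h`,
#'   `delta_tau_h`, `q10`.
#' @export
q10FromSummary <- function(summary, tColdC = NULL, tWarmC = NULL,
                           usePrintedPrecision = FALSE) {
    stopifnot(is.data.frame(summary), nrow(summary) > 0)
    key <- interaction(summary$genotype, summary$tissue, drop = TRUE,
                       lex.order = TRUE)
    rows <- lapply(split(summary, key), function(g) {
        tc <- if (is.null(tColdC)) min(g$temperature_c) else tColdC
        tw <- if (is.null(tWarmC)) max(g$temperature_c) else tWarmC
        iC <- match(tc, g$temperature_c)
        iW <- match(tw, g$temperature_c)
        if (is.na(iC) || is.na(iW) || tc >= tw) {
            warning(sprintf("group %s/%s lacks a usable temperature pair; skipped",
                            g$genotype[1L], g$tissue[1L]))
            return(NULL)
        }
        tauC <- g$tau_mean_h[iC]
        tauW <- g$tau_mean_h[iW]
        if (usePrintedPrecision) {
            tauC <- round(tauC, 1)
            tauW <- round(tauW, 1)
        }
        data.frame(genotype = g$genotype[1L], tissue = g$tissue[1L],
                   t_cold_c = tc, tau_cold_h = tauC,
                   t_warm_c = tw, tau_warm_h = tauW,
                   delta_tau_h = deltaTau(tauC, tauW),
                   q10 = q10(computeQ10(tauC, tc, tauW, tw)))
    })
    do.call(rbind, c(rows[!vapply(rows, is.null, logical(1))],
                     list(make.row.names = FALSE)))
}
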