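#' @include AllClasses.R
NULL

.defaultConfig <- function() {
    list(
        seed = 1L,
        input = NULL,        # list(long_csv =, metadata_csv =) or NULL
        simulate = NULL,     # cohortDesign()-style fields or NULL
        discard_initial_h = 24,
        detrend = list(window_h = 24, mode = "subtract"),
        fit = list(tau_bounds_h = c(16, 40), tau_grid_step_h = 1,
                   damping_bounds_per_h = c(-0.05, 0.10), n_refine = 5L),
        filter = list(tissue_culture_cutoff = 0.5, whole_fly_cutoff = 0.7,
                      error_cutoff = NULL),
        q10 = list(t_cold_c = NULL, t_warm_c = NULL,
                   use_printed_precision = FALSE),
        effects = list(control = NULL, n_boot = 5000, ci_level = 0.95,
                       method = "bca"),
        output_dir = NULL
    )
}

.mergeConfig <- function(base, user) {
    for (nm in names(user)) {
        if (is.list(base[[nm]]) && is.list(user[[nm]]))
            base[[nm]] <- .mergeConfig(base[[nm]], user[[nm]])
        else
            base[[nm]] <- user[[nm]]
    }
    base
}

#' Read a pipeline configuration file
#'
#' YAML file whose keys mirror [runPipeline()]'s defaults; unspecified keys
#' keep their defaults. See the package vignette for the full schema.
#'
#' @param path YAML file path.
#' @return a complete config list.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path))
        stop("config file not found: ", path, call. = FALSE)
    .mergeConfig(.defaultConfig(), yaml::read_yaml(path))
}

.designFromConfig <- function(sim, seed) {
    pf <- sim$params
    if (is.null(pf)) pf <- list()
    params <- simParams(
        periodH = pf$period_h %||% 24,
        amplitudeCps = pf$amplitude_cps %||% 100,
        dampingPerH = pf$damping_per_h %||% 0.005,
        phaseH = pf$phase_h %||% 0,
        baselineCps = pf$baseline_cps %||% 150,
        trendDecayPerH = pf$trend_decay_per_h %||% 0.005,
        noiseModel = pf$noise_model %||% "poisson",
        noiseSdCps = pf$noise_sd_cps %||% 0,
        samplingIntervalH = pf$sampling_interval_h %||% 1,
        ldHours = pf$ld_hours %||% 24,
        ddHours = pf$dd_hours %||% 96)
    cohortDesign(
        temperatures = sim$temperatures %||% c(18, 21, 25, 29),
        nPerTemperature = sim$n_per_temperature %||% 25L,
        tauRefH = sim$tau_ref_h %||% 21,
        tRefC = sim$t_ref_c %||% 18,
        q10True = sim$q10_true %||% 0.85,
        tauSdH = sim$tau_sd_h %||% 0.5,
        params = params,
        genotype = sim$genotype %||% "sim-luc",
        tissue = sim$tissue %||% "haltere",
        rngSeed = sim$rng_seed %||% seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
             call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Read (or simulate) a cohort, trim the entrainment window, extract the DD
#' free run, detrend, fit the damped cosine per sample, filter by the error
#' cutoffs, summarise per group, compute per-group Q10 coefficients, and
#' compute shared-control bootstrap effect sizes of the period across
#' temperatures (control = configured label, or the lowest temperature).
#' Deterministic for a fixed config.
#'
#' If `config$output_dir` is set, writes `fits.csv` (per-sample fits),
#' `report.csv` (group summary with Q10), `effects.csv` (shared-control
#' comparisons) and `pipeline.log` (per-stage sample bookkeeping, cutoffs,
#' seed) into it.
#'
#' @param config config list (see [readRunConfig()]); either a path or a
#'   list. Must provide `input` (long + metadata CSV paths) or `simulate`
#'   (cohort design fields).
#' @return invisibly, a list with `fits`, `retained`, `summary`, `q10`,
#'   `effects` (list of [EffectSize-class] per genotype x tissue), and
#'   `log` (character vector).
#' @examples
#' cfg <- list(simulate = list(temperatures = c(18, 29),
#'                             n_per_temperature = 3L,
#'                             params = list(noise_model = "none")),
#'             effects = list(n_boot = 200))
#' res <- runPipeline(cfg)
#' res$q10
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- readRunConfig(config)
    config <- .mergeConfig(.defaultConfig(), config)
    seed <- as.integer(config$seed)
    logLines <- c(sprintf("seed: %d", seed))
    addLog <- function(...) logLines <<- c(logLines, sprintf(...))

    ## --- input ------------------------------------------------------------
    cohort <- .stage("input", {
        if (!is.null(config$simulate)) {
            design <- .designFromConfig(config$simulate, seed)
            simulateCohort(design)
        } else if (!is.null(config$input)) {
            set <- readLongCSV(config$input$long_csv)
            md <- readSampleMetadata(config$input$metadata_csv)
            joinMetadata(set, md, strict = config$input$strict %||% TRUE)
        } else stop("config needs either 'input' or 'simulate'")
    })
    addLog("input: %d samples", length(cohort))

    ## --- preprocess + fit -------------------------------------------------
    cfgFit <- fitConfig(
        tauBoundsH = config$fit$tau_bounds_h,
        tauGridStepH = config$fit$tau_grid_step_h,
        dampingBoundsPerH = config$fit$damping_bounds_per_h,
        nRefine = config$fit$n_refine)
    fits <- .stage("fit", fitCohort(cohort, cfg = cfgFit,
        discardInitialH = config$discard_initial_h,
        detrendWindowH = config$detrend$window_h,
        detrendMode = config$detrend$mode))
    addLog("fit: %d fitted, %d converged", nrow(fits), sum(fits$converged))

    ## --- filter -----------------------------------------------------------
    retained <- .stage("filter", filterFits(fits,
        errorCutoff = config$filter$error_cutoff,
        tissueCultureCutoff = config$filter$tissue_culture_cutoff,
        wholeFlyCutoff = config$filter$whole_fly_cutoff))
    addLog("filter: %d retained, %d excluded (cutoffs: culture %.2f, whole fly %.2f)",
           nrow(retained), attr(retained, "excluded"),
           config$filter$tissue_culture_cutoff, config$filter$whole_fly_cutoff)

    ## --- summarise + Q10 --------------------------------------------------
    summary <- q10Table <- data.frame()
    effects <- list()
    if (nrow(retained)) {
        summary <- .stage("summarize", summarizeGroups(retained))
        q10Table <- .stage("q10", q10FromSummary(summary,
            tColdC = config$q10$t_cold_c, tWarmC = config$q10$t_warm_c,
            usePrintedPrecision = config$q10$use_printed_precision))
        addLog("summarize: %d groups; q10: %d genotype x tissue pairs",
               nrow(summary), if (is.null(q10Table)) 0L else nrow(q10Table))

        ## --- shared-control effect sizes on tau, per genotype x tissue ----
        effects <- .stage("effects", {
            key <- interaction(retained$genotype, retained$tissue,
                               drop = TRUE, lex.order = TRUE)
            es <- lapply(split(retained, key), function(g) {
                temps <- sort(unique(g$temperature_c))
                if (length(temps) < 2L || min(table(g$temperature_c)) < 2L)
                    return(NULL)
                ctrl <- config$effects$control %||% as.character(min(temps))
                sharedControl(g$tau_h, as.character(g$temperature_c),
                    controlLabel = as.character(ctrl),
                    nBoot = config$effects$n_boot,
                    ciLevel = config$effects$ci_level,
                    method = config$effects$method, seed = seed)
            })
            es[!vapply(es, is.null, logical(1))]
        })
        addLog("effects: %d shared-control comparison sets", length(effects))
    } else {
        addLog("summarize: skipped (no retained fits)")
    }

    ## --- outputs ----------------------------------------------------------
    if (!is.null(config$output_dir)) {
        dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
        outp <- function(f) file.path(config$output_dir, f)
        utils::write.csv(fits, outp("fits.csv"), row.names = FALSE)
        writeReportCSV(if (nrow(summary)) summary else
            data.frame(genotype = character(0), tissue = character(0),
                       temperature_c = numeric(0), n = integer(0),
                       tau_mean_h = numeric(0), tau_sem_h = numeric(0),
                       error_mean = numeric(0), error_sem = numeric(0),
                       cps_mean = numeric(0), cps_sem = numeric(0)),
            outp("report.csv"), q10Table)
        allES <- unlist(effects, recursive = FALSE)
        esTab <- if (length(allES)) effectsTable(allES) else
            data.frame(control = character(0), test = character(0),
                       mean_difference = numeric(0))
        esTab$seed <- rep(seed, nrow(esTab))
        utils::write.csv(esTab, outp("effects.csv"), row.names = FALSE)
        writeLines(logLines, outp("pipeline.log"))
    }
    invisible(list(fits = fits, retained = retained, summary = summary,
                   q10 = q10Table, effects = effects, log = logLines))
}
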