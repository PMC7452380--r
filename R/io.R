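#' @include AllClasses.R
NULL

.numOrStop <- function(x, col, lineOffset = 1L) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) & !(is.na(x) | trimws(x) == ""))
    if (length(bad))
        stop(sprintf("non-numeric value '%s' in column '%s' at line %d",
                     x[bad[1L]], col, bad[1L] + lineOffset), call. = FALSE)
    out
}

#' Read bioluminescence series from a long-format CSV
#'
#' Expects a header `sample_id,time_h,cps` (extra columns are ignored). One
#' [LumiSeries] is built per distinct `sample_id`, rows sorted by time.
#' Negative counts and duplicate (sample, time) rows are rejected; rows with
#' an empty `cps` cell are dropped (missing readings).
#'
#' @param path CSV file path.
#' @return a [LumiSet] (empty, with a warning, if the file has no data rows).
#' @seealso [writeLongCSV()], [readPlateCSV()]
#' @export
readLongCSV <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    need <- c("sample_id", "time_h", "cps")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
             call. = FALSE)
    if (!nrow(df)) {
        warning("no data rows in ", path)
        return(LumiSet(list()))
    }
    df$time_h <- .numOrStop(df$time_h, "time_h")
    df$cps <- .numOrStop(df$cps, "cps")
    if (anyNA(df$time_h))
        stop("empty time_h cell at line ",
             which(is.na(df$time_h))[1L] + 1L, call. = FALSE)
    if (any(df$cps < 0, na.rm = TRUE))
        stop("negative counts at line ",
             which(!is.na(df$cps) & df$cps < 0)[1L] + 1L, call. = FALSE)
    df <- df[!is.na(df$cps), , drop = FALSE]
    series <- lapply(split(df, factor(df$sample_id, levels = unique(df$sample_id))),
        function(d) {
            d <- d[order(d$time_h), , drop = FALSE]
            if (anyDuplicated(d$time_h))
                stop(sprintf("duplicate time %g for sample '%s'",
                             d$time_h[duplicated(d$time_h)][1L],
                             d$sample_id[1L]), call. = FALSE)
            LumiSeries(d$sample_id[1L], d$time_h, d$cps)
        })
    LumiSet(unname(series))
}

#' Write series to a long-format CSV
#'
#' @param x a [LumiSet] or [LumiSeries].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeLongCSV <- function(x, path) {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read a wide plate-reader export
#'
#' One row per well: first column the well/sample id, remaining columns
#' successive readings at a fixed interval. Reading `k` is assigned time
#' `startH + (k - 1) * intervalH`; blank cells are treated as missing
#' readings and dropped. Ragged rows (differing column counts) are an error.
#'
#' @param path CSV file path (no header).
#' @param intervalH sampling interval in hours.
#' @param startH time of the first reading (default 0).
#' @return a [LumiSet].
#' @export
readPlateCSV <- function(path, intervalH, startH = 0) {
    stopifnot(intervalH > 0)
    nf <- utils::count.fields(path, sep = ",", quote = "\"",
                              blank.lines.skip = TRUE)
    if (length(unique(nf)) > 1L)
        stop(sprintf("ragged rows in %s: %d fields at line %d vs %d at line 1",
                     path, nf[which(nf != nf[1L])[1L]],
                     which(nf != nf[1L])[1L], nf[1L]), call. = FALSE)
    df <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
    if (ncol(df) < 2L)
        stop("plate file needs a well id column plus at least one reading",
             call. = FALSE)
    series <- lapply(seq_len(nrow(df)), function(i) {
        vals <- .numOrStop(unlist(df[i, -1L], use.names = FALSE),
                           sprintf("row %d readings", i), lineOffset = 0L)
        t <- startH + (seq_along(vals) - 1L) * intervalH
        keep <- !is.na(vals)
        if (any(vals[keep] < 0))
            stop(sprintf("negative counts in row %d of %s", i, path),
                 call. = FALSE)
        LumiSeries(df[i, 1L], t[keep], vals[keep])
    })
    LumiSet(series)
}

#' Read a sample-metadata CSV
#'
#' Required columns: `sample_id`, `genotype`, `tissue`, `temperature_c`.
#' Optional: `dd_onset_h` (hours at which constant darkness begins) and any
#' further columns, which are carried along.
#'
#' @param path CSV file path.
#' @return data.frame, one row per sample.
#' @export
readSampleMetadata <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "genotype", "tissue", "temperature_c")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("missing metadata column(s): ", paste(miss, collapse = ", "),
             call. = FALSE)
    if (anyDuplicated(df$sample_id))
        stop("duplicate sample_id in metadata: ",
             df$sample_id[duplicated(df$sample_id)][1L], call. = FALSE)
    df
}

#' Join measurements with sample metadata
#'
#' Attaches genotype, tissue, temperature and (if present) DD onset from a
#' metadata table to each series. Under `strict = TRUE` every series must
#' have a metadata row; otherwise unmatched series are dropped with a
#' warning.
#'
#' @param x a [LumiSet].
#' @param metadata data.frame as returned by [readSampleMetadata()].
#' @param strict error on unmatched sample ids (default `TRUE`).
#' @return the annotated [LumiSet].
#' @export
joinMetadata <- function(x, metadata, strict = TRUE) {
    stopifnot(is(x, "LumiSet"), is.data.frame(metadata))
    if (anyDuplicated(metadata$sample_id))
        stop("duplicate sample_id in metadata", call. = FALSE)
    ids <- sampleId(x)
    unmatched <- setdiff(ids, metadata$sample_id)
    if (length(unmatched)) {
        if (strict)
            stop("series without metadata: ",
                 paste(unmatched, collapse = ", "), call. = FALSE)
        warning("dropping series without metadata: ",
                paste(unmatched, collapse = ", "))
        x <- LumiSet(as.list(x)[!ids %in% unmatched])
        ids <- sampleId(x)
    }
    rows <- match(ids, metadata$sample_id)
    ann <- lapply(seq_along(ids), function(i) {
        s <- x[[i]]
        m <- metadata[rows[i], , drop = FALSE]
        s@temperatureC <- as.numeric(m$temperature_c)
        if (!is.null(m$dd_onset_h) && !is.na(m$dd_onset_h))
            s@ddOnsetH <- as.numeric(m$dd_onset_h)
        s@annotations$genotype <- as.character(m$genotype)
        s@annotations$tissue <- as.character(m$tissue)
        validObject(s)
        s
    })
    out <- LumiSet(ann)
    metadata(out)$samples <- metadata[rows, , drop = FALSE]
    out
}

#' Write a cohort-report CSV
#'
#' The report mirrors the layout of a per-group results table: one row per
#' genotype x tissue x temperature with n, tau mean +/- SEM, error mean +/-
#' SEM, CPS mean +/- SEM and the group's Q10. Period means are rounded to 1
#' decimal and Q10 to 2 decimals (printed precision); use the returned
#' objects from [summarizeGroups()] / [q10FromSummary()] for full precision.
#'
#' @param summary data.frame from [summarizeGroups()].
#' @param path output file path.
#' @param q10Table optional data.frame from [q10FromSummary()]; its `q10`
#'   value is attached to every row of the matching genotype x tissue.
#' @return `path`, invisibly.
#' @export
writeReportCSV <- function(summary, path, q10Table = NULL) {
    out <- summary
    out$tau_mean_h <- round(out$tau_mean_h, 1)
    out$tau_sem_h <- round(out$tau_sem_h, 2)
    out$error_mean <- round(out$error_mean, 2)
    out$error_sem <- round(out$error_sem, 2)
    out$cps_mean <- round(out$cps_mean, 1)
    out$cps_sem <- round(out$cps_sem, 1)
    out$q10 <- rep(NA_real_, nrow(out))
    if (!is.null(q10Table) && nrow(q10Table)) {
        key <- paste(out$genotype, out$tissue)
        qkey <- paste(q10Table$genotype, q10Table$tissue)
        out$q10 <- round(q10Table$q10[match(key, qkey)], 2)
    }
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
    invisible(path)
}
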