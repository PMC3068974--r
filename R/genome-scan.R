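# Marker-by-marker survival scans at a stride. Tested markers are indices
# 1, 1+stride, 1+2*stride, ... within each chromosome: smoothing makes
# neighboring markers' statistics strongly correlated, so testing one of
# every `stride` markers loses little information.

.testedIndices <- function(chrom, stride) {
    runs <- .chromRuns(chrom)
    unlist(lapply(split(seq_along(chrom), runs), function(ix) {
        ix[seq(1L, length(ix), by = stride)]
    }), use.names = FALSE)
}

.scanFrame <- function(x, idx) {
    rd <- rowData(x)
    data.frame(marker_id = rownames(x)[idx],
               chromosome = as.character(rd$chromosome)[idx],
               position = as.numeric(rd$position)[idx],
               stringsAsFactors = FALSE)
}

#' Genome-wide log-rank scan on copy-number groups
#'
#' At every tested marker, samples are split into Deletion / No-change /
#' Gain groups by the marker's (smoothed) copy number and the k-group
#' log-rank test is applied; the track score is -log10(p), so 3 corresponds
#' to p = 0.001. Markers with fewer than two nonempty groups carry a missing
#' score (not zero). Apply [smoothCopyNumber()] (and optionally
#' [scaleModeToTwo()]) before scanning.
#'
#' @param x a [CNExperiment-class], usually smoothed.
#' @param data a [SurvivalData-class] aligned with `x`'s samples.
#' @param stride test one of every `stride` consecutive markers, restarting
#'   at each chromosome (default 10).
#' @param delThresh,gainThresh copy thresholds for grouping (defaults
#'   1.5 / 2.5).
#' @param minExpected per-group expected-events gate for the `eligible`
#'   flag (default 5).
#' @return a [ScanResult-class] with per-marker score, statistic, p-value,
#'   eligibility and group sizes.
#' @export
scanLogrank <- function(x, data, stride = 10L, delThresh = 1.5,
                        gainThresh = 2.5, minExpected = 5) {
    stopifnot(is(x, "CNExperiment"), is(data, "SurvivalData"))
    if (length(data) != ncol(x))
        .stopf("survival data must cover the %d samples", ncol(x))
    stride <- as.integer(stride)
    if (is.na(stride) || stride < 1L) .stopf("stride must be >= 1")
    cc <- completeCases(data)
    if (sum(cc) < 2) .stopf("fewer than 2 samples with survival data")
    idx <- .testedIndices(as.character(rowData(x)$chromosome), stride)

    groups <- assignCNGroups(copyNumbers(x)[idx, cc, drop = FALSE],
                             delThresh, gainThresh)
    lr <- cpp_logrank_scan(groups, data@time[cc], data@event[cc], 3L)
    stat <- as.numeric(lr$statistic)
    df <- as.integer(lr$df)
    p <- ifelse(df >= 1 & !is.na(stat),
                pchisq(stat, pmax(df, 1L), lower.tail = FALSE), NA_real_)
    testable <- !is.na(p)
    if (!any(testable)) .stopf("no testable marker genome-wide")

    expd <- lr$exp
    res <- .scanFrame(x, idx)
    res$score <- -log10(p)
    res$statistic <- ifelse(testable, stat, NA_real_)
    res$p_value <- p
    res$eligible <- testable &
        rowSums(!is.na(expd) & expd >= minExpected) >= 2
    res$df <- ifelse(testable, df, NA_integer_)
    res$nDeletion <- lr$n[, 1]
    res$nNoChange <- lr$n[, 2]
    res$nGain <- lr$n[, 3]
    new("ScanResult", results = res, method = "logrank", stride = stride,
        params = list(delThresh = delThresh, gainThresh = gainThresh,
                      minExpected = minExpected),
        nOmitted = as.integer(sum(!cc)))
}

#' Genome-wide Cox-regression scan on continuous copy number
#'
#' At every tested marker a Cox proportional-hazards model is fitted with
#' the marker's (smoothed) copy number as the covariate, optionally adjusted
#' for clinical covariates; the track score is the signed Wald z. Negative z
#' means longer survival as copy number increases. Non-converged or
#' degenerate fits (e.g. constant copy number) carry a missing score.
#'
#' @inheritParams scanLogrank
#' @param covariates optional character vector of `colData(x)` column names
#'   (numeric or binary) used as adjustment covariates, or a data.frame /
#'   matrix of per-sample values.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return a [ScanResult-class] with per-marker z score, beta, se, p-value.
#' @export
scanCox <- function(x, data, stride = 10L, covariates = NULL,
                    ties = c("breslow", "efron")) {
    stopifnot(is(x, "CNExperiment"), is(data, "SurvivalData"))
    ties <- match.arg(ties)
    if (length(data) != ncol(x))
        .stopf("survival data must cover the %d samples", ncol(x))
    stride <- as.integer(stride)
    if (is.na(stride) || stride < 1L) .stopf("stride must be >= 1")

    ex <- NULL
    if (!is.null(covariates)) {
        ex <- if (is.character(covariates)) {
            as.data.frame(colData(x))[, covariates, drop = FALSE]
        } else {
            as.data.frame(covariates)
        }
        ex <- data.frame(lapply(ex, as.numeric))
    }
    cc <- completeCases(data)
    if (!is.null(ex)) cc <- cc & complete.cases(ex)
    if (sum(cc) < 2) .stopf("fewer than 2 samples with complete data")
    if (sum(data@event[cc]) < 1) .stopf("no events among complete cases")
    idx <- .testedIndices(as.character(rowData(x)$chromosome), stride)

    time <- data@time[cc]
    event <- as.integer(data@event[cc])
    o <- order(time)
    covm <- copyNumbers(x)[idx, cc, drop = FALSE][, o, drop = FALSE]
    exm <- if (is.null(ex)) {
        matrix(0, nrow = sum(cc), ncol = 0)
    } else {
        as.matrix(ex[cc, , drop = FALSE])[o, , drop = FALSE]
    }
    cx <- cpp_cox_scan(covm, exm, time[o], event[o], ties == "efron",
                       1e-8, 50L)
    ok <- as.logical(cx$converged) & !is.na(cx$z)
    if (!any(ok)) .stopf("no testable marker genome-wide")

    res <- .scanFrame(x, idx)
    res$score <- ifelse(ok, cx$z, NA_real_)
    res$statistic <- ifelse(ok, cx$z, NA_real_)
    res$p_value <- ifelse(ok, 2 * pnorm(-abs(cx$z)), NA_real_)
    res$eligible <- ok
    res$beta <- ifelse(ok, cx$beta, NA_real_)
    res$se <- ifelse(ok, cx$se, NA_real_)
    res$n <- cx$n
    new("ScanResult", results = res, method = "cox", stride = stride,
        params = list(ties = ties,
                      covariates = if (is.null(ex)) character(0) else colnames(ex)),
        nOmitted = as.integer(sum(!cc)))
}

#' @rdname survscan-generics
#' @export
setMethod("scanTable", "ScanResult", function(x, ...) x@results)

#' @rdname survscan-generics
#' @export
setMethod("scanScores", "ScanResult", function(x, ...) {
    setNames(x@results$score, x@results$marker_id)
})

#' @rdname survscan-generics
#' @export
setMethod("nOmitted", "ScanResult", function(x, ...) x@nOmitted)

#' @export
setMethod("show", "ScanResult", function(object) {
    r <- object@results
    cat(sprintf("ScanResult (%s): %d tested markers (stride %d), %d sample(s) omitted\n",
                object@method, nrow(r), object@stride, object@nOmitted))
    sc <- if (object@method == "cox") abs(r$score) else r$score
    if (any(!is.na(sc))) {
        i <- which.max(sc)
        cat(sprintf("  top marker: %s (chr%s:%d), score %.3f\n",
                    r$marker_id[i], r$chromosome[i], r$position[i], r$score[i]))
    }
    invisible(NULL)
})

#' Write a scan track as a tab-delimited report
#'
#' @param scan a [ScanResult-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeScanTrack <- function(scan, path) {
    stopifnot(is(scan, "ScanResult"))
    write.table(scanTable(scan), path, sep = "\t", quote = FALSE,
                row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
    invisible(path)
}
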