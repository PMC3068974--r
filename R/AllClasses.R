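#' CNExperiment: genome-ordered copy-number container
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' markers x samples copy-number matrix (assay `"copynumber"`, linear copy
#' scale where diploid = 2), marker annotation in `rowData()` (columns
#' `chromosome` and `position`, optionally `gene` and `cytoband`) and sample
#' information in `colData()`. Rows are kept sorted by chromosome (1..22, X,
#' Y, then other labels) and position; the validity method enforces genome
#' order and rejects markers or samples whose values are entirely missing.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @seealso [CNExperiment()] for construction from plain objects,
#'   [smoothCopyNumber()], [scaleModeToTwo()], [scanLogrank()], [scanCox()].
#' @export
setClass("CNExperiment", contains = "SummarizedExperiment")

setValidity("CNExperiment", function(object) {
    rd <- rowData(object)
    if (!all(c("chromosome", "position") %in% colnames(rd)))
        return("rowData must contain 'chromosome' and 'position'")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        return("marker ids (rownames) must be present and unique")
    pos <- rd$position
    if (any(is.na(pos)) || any(pos < 0))
        return("positions must be nonnegative and non-missing")
    chr <- as.character(rd$chromosome)
    ord <- order(chromOrder(chr), pos)
    if (any(ord != seq_along(ord)))
        return("markers must be sorted by chromosome then position")
    if (nrow(object) > 0 && ncol(object) > 0) {
        v <- assay(object, "copynumber")
        if (any(rowSums(!is.na(v)) == 0))
            return("at least one marker has entirely missing values")
        if (any(colSums(!is.na(v)) == 0))
            return("at least one sample has entirely missing values")
    }
    TRUE
})

#' SurvivalData: right-censored outcomes for a set of samples
#'
#' Per-sample survival time and event indicator (1 = event, 0 = censored).
#' A sample with either field missing is treated as missing both and is
#' excluded from analyses as a non-complete case; the number omitted is
#' reported by every downstream test.
#'
#' @slot time numeric, nonnegative or NA.
#' @slot event integer in {0, 1} or NA.
#' @slot sampleId character, unique sample identifiers.
#' @export
setClass("SurvivalData",
    representation(time = "numeric", event = "integer", sampleId = "character"))

setValidity("SurvivalData", function(object) {
    n <- length(object@time)
    if (length(object@event) != n || length(object@sampleId) != n)
        return("time, event and sampleId must have equal length")
    if (anyDuplicated(object@sampleId))
        return("sample ids must be unique")
    ev <- object@event
    if (any(!is.na(ev) & !(ev %in% c(0L, 1L))))
        return("event must be 0 or 1 where present")
    tm <- object@time
    if (any(!is.na(tm) & tm < 0))
        return("time must be nonnegative where present")
    if (any(is.na(tm) != is.na(ev)))
        return("time and event must be both present or both missing")
    TRUE
})

#' KMCurve: product-limit estimates per group
#'
#' @slot curves named list, one data.frame per group with columns `time`,
#'   `nRisk`, `nEvent`, `nCensor`, `surv` (survival probability just after
#'   `time`).
#' @slot summary data.frame with per-group `group`, `n`, `observed`,
#'   `expected` (expected events from the log-rank decomposition over the
#'   pooled event times).
#' @slot nOmitted integer, samples dropped for missing survival data.
#' @export
setClass("KMCurve",
    representation(curves = "list", summary = "data.frame",
                   nOmitted = "integer"))

#' LogrankResult: k-group log-rank test
#'
#' @slot statistic chi-square statistic (full-covariance form, generalized
#'   inverse when singular).
#' @slot df degrees of freedom = nonempty groups - 1.
#' @slot pValue upper-tail chi-square probability.
#' @slot observed,expected named per-group observed / expected event counts.
#' @slot n named per-group complete-case sample counts.
#' @slot eligible TRUE when at least two groups have expected events >=
#'   `minExpected` (the display-gating rule; the statistic is computed
#'   regardless).
#' @slot minExpected the gating constant (default 5).
#' @slot nOmitted samples dropped for missing survival data.
#' @export
setClass("LogrankResult",
    representation(statistic = "numeric", df = "integer", pValue = "numeric",
                   observed = "numeric", expected = "numeric", n = "numeric",
                   eligible = "logical", minExpected = "numeric",
                   nOmitted = "integer"))

#' CoxResult: proportional-hazards fit
#'
#' @slot coef,se,z,p named vectors (first entry is the primary covariate;
#'   any adjustment covariates follow). z = coef/se, p two-sided normal.
#' @slot loglik length-2: null and maximized partial log-likelihood.
#' @slot converged FALSE on non-convergence or monotone likelihood.
#' @slot iterations Newton-Raphson iterations used.
#' @slot ties "breslow" or "efron".
#' @slot nEvents,nOmitted event count and complete-case omissions.
#' @export
setClass("CoxResult",
    representation(coef = "numeric", se = "numeric", z = "numeric",
                   p = "numeric", loglik = "numeric", converged = "logical",
                   iterations = "integer", ties = "character",
                   nEvents = "integer", nOmitted = "integer"))

#' ScanResult: per-marker survival association track
#'
#' @slot results data.frame, one row per tested marker: `marker_id`,
#'   `chromosome`, `position`, `score` (-log10 p for log-rank; signed Wald z
#'   for Cox), `statistic`, `p_value`, `eligible`, plus method-specific
#'   columns (group sizes or beta/se).
#' @slot method "logrank" or "cox".
#' @slot stride marker stride used (tested markers are every `stride`-th
#'   marker, restarting at each chromosome).
#' @slot params list of analysis parameters (thresholds, ties, ...).
#' @slot nOmitted samples dropped for missing survival data.
#' @export
setClass("ScanResult",
    representation(results = "data.frame", method = "character",
                   stride = "integer", params = "list", nOmitted = "integer"))

setValidity("ScanResult", function(object) {
    need <- c("marker_id", "chromosome", "position", "score", "statistic",
              "p_value", "eligible")
    if (!all(need %in% colnames(object@results)))
        return("results is missing required columns")
    if (!object@method %in% c("logrank", "cox"))
        return("method must be 'logrank' or 'cox'")
    sc <- object@results$score
    if (object@method == "logrank" && any(!is.na(sc) & sc < 0))
        return("log-rank scores (-log10 p) must be nonnegative")
    TRUE
})

#' PermutationNull: MaxT null distribution and genome-wide threshold
#'
#' @slot maxima per-permutation maximal score over tested markers
#'   (log-rank: -log10 p; Cox: |z|).
#' @slot threshold the ceiling(alpha * nPerm)-th largest maximum.
#' @slot alpha family-wise significance level.
#' @slot scheme "clinical" (permute (time, event) pairs across samples) or
#'   "blocks" (per-sample chromosome-block shuffling).
#' @slot nPerm number of permutations.
#' @slot K number of genome blocks (blocks scheme).
#' @slot observedMax maximal observed score.
#' @slot empiricalP add-one empirical genome-wide p,
#'   (1 + #\{perm max >= observed max\}) / (nPerm + 1).
#' @slot seed master seed used.
#' @export
setClass("PermutationNull",
    representation(maxima = "numeric", threshold = "numeric",
                   alpha = "numeric", scheme = "character", nPerm = "integer",
                   K = "integer", observedMax = "numeric",
                   empiricalP = "numeric", seed = "integer"))
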