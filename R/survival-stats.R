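# Product-limit estimation, k-group log-rank and Cox PH regression.
# The test statistics are computed in compiled code (src/core.cpp); these
# wrappers handle complete-case filtering, group bookkeeping and results.

# complete cases shared by survival data and optional per-sample extras
.ccMask <- function(data, ...) {
    m <- completeCases(data)
    for (v in list(...)) if (!is.null(v)) m <- m & !is.na(v)
    m
}

# groups as integer codes 1..k (0 excluded), with level labels
.groupCodes <- function(groups) {
    f <- if (is.factor(groups)) droplevels(groups) else factor(groups)
    codes <- as.integer(f)
    codes[is.na(codes)] <- 0L
    list(codes = codes, levels = levels(f))
}

#' Kaplan-Meier product-limit estimate per group
#'
#' At each distinct event time t with d events among n at risk, the group's
#' survival multiplies by (1 - d/n); times with only censoring reduce the
#' at-risk count but leave survival unchanged. Expected events per group come
#' from the log-rank decomposition over the pooled event times, so that
#' summed over groups the expected events equal the observed total exactly.
#' Samples with missing survival or a missing (NA) group label are omitted
#' and counted.
#'
#' @param data a [SurvivalData-class].
#' @param groups per-sample labels (factor or character); `NA` = excluded.
#'   Defaults to a single pooled group.
#' @return a [KMCurve-class].
#' @examples
#' km <- kmEstimate(SurvivalData(c(1, 2, 3, 4), c(1, 1, 0, 1)))
#' kmCurves(km)[[1]]$surv   # 0.75 0.50 0.50 0.00
#' @export
kmEstimate <- function(data, groups = NULL) {
    stopifnot(is(data, "SurvivalData"))
    n <- length(data)
    if (is.null(groups)) groups <- rep("all", n)
    if (length(groups) != n) .stopf("'groups' length must match the data")
    gc <- .groupCodes(groups)
    mask <- completeCases(data) & gc$codes > 0L
    if (!any(mask)) .stopf("no usable samples (empty group set)")
    nOm <- sum(!completeCases(data))

    time <- data@time[mask]
    event <- data@event[mask]
    codes <- gc$codes[mask]
    used <- sort(unique(codes))
    levs <- gc$levels[used]
    codes <- match(codes, used)
    k <- length(used)

    lr <- cpp_logrank_scan(matrix(codes, nrow = 1), time, event, k)
    curves <- vector("list", k)
    names(curves) <- levs
    for (g in seq_len(k)) {
        tg <- time[codes == g]
        eg <- event[codes == g]
        o <- order(tg)
        tg <- tg[o]; eg <- eg[o]
        ut <- unique(tg)
        nEvent <- vapply(ut, function(t) sum(eg[tg == t] == 1L), numeric(1))
        nCensor <- vapply(ut, function(t) sum(eg[tg == t] == 0L), numeric(1))
        nRisk <- length(tg) - c(0, cumsum(nEvent + nCensor))[seq_along(ut)]
        surv <- cumprod(1 - nEvent / nRisk)
        curves[[g]] <- data.frame(time = ut, nRisk = nRisk, nEvent = nEvent,
                                  nCensor = nCensor, surv = surv)
    }
    summary <- data.frame(group = levs,
                          n = as.integer(lr$n[1, ]),
                          observed = as.numeric(lr$obs[1, ]),
                          expected = as.numeric(lr$exp[1, ]),
                          stringsAsFactors = FALSE)
    new("KMCurve", curves = curves, summary = summary,
        nOmitted = as.integer(nOm))
}

#' @rdname survscan-generics
#' @export
setMethod("kmCurves", "KMCurve", function(x, ...) x@curves)

#' @rdname survscan-generics
#' @export
setMethod("kmSummary", "KMCurve", function(x, ...) x@summary)

#' @rdname survscan-generics
#' @export
setMethod("nOmitted", "KMCurve", function(x, ...) x@nOmitted)

#' @export
setMethod("show", "KMCurve", function(object) {
    cat("KMCurve:", length(object@curves), "group(s),",
        object@nOmitted, "sample(s) omitted for missing survival\n")
    print(object@summary, row.names = FALSE)
    invisible(NULL)
})

#' k-group log-rank test
#'
#' Compares observed to hypergeometric-expected event counts over the pooled
#' distinct event times, using the full covariance matrix of (O - E) on any
#' g-1 groups (generalized inverse when singular). df = nonempty groups - 1;
#' the p-value is the upper chi-square tail. The `eligible` flag implements
#' the display-gating rule: a p-value is quoted only when at least two groups
#' each have `minExpected` or more expected events; the statistic itself is
#' always computed.
#'
#' @param data a [SurvivalData-class].
#' @param groups per-sample labels; `NA` = excluded.
#' @param minExpected gating constant (default 5 expected events).
#' @return a [LogrankResult-class].
#' @examples
#' d <- SurvivalData(c(1, 2, 3, 10, 11, 12), rep(1, 6))
#' logrankTest(d, rep(c("A", "B"), each = 3))
#' @export
logrankTest <- function(data, groups, minExpected = 5) {
    stopifnot(is(data, "SurvivalData"))
    if (length(groups) != length(data))
        .stopf("'groups' length must match the data")
    gc <- .groupCodes(groups)
    mask <- completeCases(data) & gc$codes > 0L
    nOm <- sum(!completeCases(data))
    codes <- gc$codes[mask]
    used <- sort(unique(codes))
    if (length(used) < 2)
        .stopf("log-rank test needs at least 2 nonempty groups; no comparison possible")
    levs <- gc$levels[used]
    codes <- match(codes, used)
    k <- length(used)

    lr <- cpp_logrank_scan(matrix(codes, nrow = 1),
                           data@time[mask], data@event[mask], k)
    stat <- lr$statistic[1]
    df <- as.integer(lr$df[1])
    expd <- setNames(as.numeric(lr$exp[1, ]), levs)
    obs <- setNames(as.numeric(lr$obs[1, ]), levs)
    new("LogrankResult",
        statistic = stat, df = df,
        pValue = pchisq(stat, df, lower.tail = FALSE),
        observed = obs, expected = expd,
        n = setNames(as.numeric(lr$n[1, ]), levs),
        eligible = sum(expd >= minExpected) >= 2,
        minExpected = minExpected, nOmitted = as.integer(nOm))
}

#' @rdname survscan-generics
#' @export
setMethod("pValue", "LogrankResult", function(x, ...) x@pValue)

#' @rdname survscan-generics
#' @export
setMethod("statistic", "LogrankResult", function(x, ...) x@statistic)

#' @rdname survscan-generics
#' @export
setMethod("eligible", "LogrankResult", function(x, ...) x@eligible)

#' @rdname survscan-generics
#' @export
setMethod("nOmitted", "LogrankResult", function(x, ...) x@nOmitted)

#' @export
setMethod("show", "LogrankResult", function(object) {
    cat(sprintf("Log-rank test: chi-square = %.4g on %d df, p = %.4g%s\n",
                object@statistic, object@df, object@pValue,
                if (object@eligible) "" else
                    sprintf(" (ineligible: fewer than 2 groups with >= %g expected events)",
                            object@minExpected)))
    print(data.frame(group = names(object@n), n = object@n,
                     observed = object@observed, expected = object@expected,
                     row.names = NULL), row.names = FALSE)
    invisible(NULL)
})

#' Cox proportional-hazards regression
#'
#' Maximizes the Cox partial likelihood by Newton-Raphson (start beta = 0,
#' convergence on a log-likelihood change below `tol`, step halving on
#' decreases), with Breslow handling of tied event times by default (Efron
#' available). The primary covariate's Wald z = beta/se from the inverse
#' observed information is the marker score in genome scans; negative z
#' means less hazard (longer survival) as the covariate increases.
#' Monotone partial likelihoods (perfect separation) are flagged with
#' `converged = FALSE` rather than an error.
#'
#' @param data a [SurvivalData-class].
#' @param covariate numeric per-sample primary covariate (e.g. smoothed copy
#'   number at a marker); `NA` excludes the sample.
#' @param extra optional named list / data.frame of numeric adjustment
#'   covariates for multivariate regression.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param tol,maxit Newton-Raphson tolerance and iteration cap.
#' @return a [CoxResult-class].
#' @export
coxFit <- function(data, covariate, extra = NULL, ties = c("breslow", "efron"),
                   tol = 1e-8, maxit = 50L) {
    stopifnot(is(data, "SurvivalData"))
    ties <- match.arg(ties)
    covariate <- as.numeric(covariate)
    if (length(covariate) != length(data))
        .stopf("'covariate' length must match the data")
    ex <- NULL
    if (!is.null(extra)) {
        ex <- as.data.frame(extra)
        if (nrow(ex) != length(data))
            .stopf("'extra' covariates must match the data length")
    }
    mask <- .ccMask(data, covariate)
    if (!is.null(ex)) mask <- mask & complete.cases(ex)
    nOm <- sum(!mask)
    if (sum(mask) < 2) .stopf("fewer than 2 usable samples")

    time <- data@time[mask]
    event <- data@event[mask]
    if (sum(event) < 1) .stopf("no events among complete cases")
    X <- cbind(covariate = covariate[mask])
    if (!is.null(ex)) X <- cbind(X, as.matrix(ex[mask, , drop = FALSE]))
    if (any(apply(X, 2, sd) == 0)) .stopf("degenerate covariate (zero variance)")

    o <- order(time)
    fit <- cpp_cox(X[o, , drop = FALSE], time[o], as.integer(event[o]),
                   ties == "efron", tol, as.integer(maxit))
    cf <- setNames(as.numeric(fit$beta), colnames(X))
    se <- setNames(as.numeric(fit$se), colnames(X))
    z <- cf / se
    new("CoxResult",
        coef = cf, se = se, z = z, p = 2 * pnorm(-abs(z)),
        loglik = c(null = fit$loglik0, final = fit$loglik),
        converged = isTRUE(fit$converged),
        iterations = as.integer(fit$iter), ties = ties,
        nEvents = as.integer(sum(event)), nOmitted = as.integer(nOm))
}

#' @rdname survscan-generics
#' @export
setMethod("pValue", "CoxResult", function(x, ...) x@p)

#' @rdname survscan-generics
#' @export
setMethod("statistic", "CoxResult", function(x, ...) x@z)

#' @rdname survscan-generics
#' @export
setMethod("nOmitted", "CoxResult", function(x, ...) x@nOmitted)

#' Extract Cox coefficients
#' @param object a [CoxResult-class].
#' @param ... ignored.
#' @export
setMethod("coef", "CoxResult", function(object, ...) object@coef)

#' @export
setMethod("show", "CoxResult", function(object) {
    cat(sprintf("Cox PH fit (%s ties), %d events, %d iteration(s)%s\n",
                object@ties, object@nEvents, object@iterations,
                if (object@converged) "" else " [NOT CONVERGED]"))
    print(data.frame(coef = object@coef, se = object@se, z = object@z,
                     p = object@p))
    invisible(NULL)
})
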