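# Genome-wide significance by MaxT under two permutation schemes. Both
# break the genome-position-to-outcome linkage while keeping what must be
# kept: the clinical scheme preserves the copy-number matrix and permutes
# (time, event) pairs jointly; the block scheme preserves each sample's
# outcome and local copy-number correlation, relocating contiguous genome
# blocks per sample.

#' Chromosome-block permutation of one genome-ordered profile
#'
#' Cuts the genome-ordered profile at K-1 breakpoints drawn uniformly
#' without replacement from the L-1 internal boundaries, then rearranges the
#' K contiguous blocks by a uniform random permutation, preserving marker
#' order within each block. Blocks may span chromosome boundaries: the
#' partition is of the whole genome ordered by chromosome then position.
#' Uses the current R random-number state; seed with `set.seed()`.
#'
#' @param profile numeric vector in genome order.
#' @param K number of blocks, >= 2 and <= length(profile).
#' @return the permuted profile (same multiset of values).
#' @export
blockPermuteProfile <- function(profile, K) {
    L <- length(profile)
    K <- as.integer(K)
    if (is.na(K) || K < 2L) .stopf("K must be >= 2")
    if (K > L) .stopf("K = %d exceeds profile length %d", K, L)
    breaks <- sort(sample.int(L - 1L, K - 1L))
    .applyBlocks(profile, breaks, sample.int(K))
}

# deterministic core: breaks = sorted internal boundary indices (block i ends
# at breaks[i]); ord = order in which blocks are emitted
.applyBlocks <- function(profile, breaks, ord) {
    L <- length(profile)
    starts <- c(1L, breaks + 1L)
    ends <- c(breaks, L)
    idx <- unlist(lapply(ord, function(b) starts[b]:ends[b]),
                  use.names = FALSE)
    profile[idx]
}

# per-sample independent block permutation of a markers x samples matrix;
# returns the row-index matrix applied to each column
.blockPermuteMatrix <- function(values, K) {
    L <- nrow(values)
    out <- values
    for (j in seq_len(ncol(values))) {
        breaks <- sort(sample.int(L - 1L, K - 1L))
        idx <- .applyBlocks(seq_len(L), breaks, sample.int(K))
        out[, j] <- values[idx, j]
    }
    out
}

#' Joint permutation of clinical (time, event) pairs
#'
#' One uniform random permutation of sample indices is applied jointly to
#' the (time, event) pairs; sample identities, covariates and copy-number
#' data are untouched. Uses the current R random-number state.
#'
#' @param data a [SurvivalData-class].
#' @return a `SurvivalData` with permuted outcome pairs.
#' @export
permuteClinical <- function(data) {
    stopifnot(is(data, "SurvivalData"))
    perm <- sample.int(length(data))
    new("SurvivalData", time = data@time[perm], event = data@event[perm],
        sampleId = data@sampleId)
}

# maximal score of a scan results frame (|z| for cox, -log10 p for logrank)
.scanMax <- function(score, method) {
    s <- if (method == "cox") abs(score) else score
    s <- s[!is.na(s)]
    if (length(s) == 0) NA_real_ else max(s)
}

#' Genome-wide MaxT permutation threshold
#'
#' Reruns the identical scan on `nPerm` permuted datasets, records each
#' permutation's maximal score over eligible tested markers (|z| over
#' converged fits for Cox scans; -log10 p over markers passing the
#' expected-events gate, recomputed per permutation, for log-rank scans;
#' missing scores skipped), and derives the
#' genome-wide threshold at level `alpha` as the ceiling(alpha * nPerm)-th
#' largest maximum (with nPerm = 100 and alpha = 0.05, the 5th largest; the
#' classic "95th largest" corresponds to 1,900 permutations at the 0.05
#' level). An add-one empirical genome-wide p for the observed
#' maximum, (1 + #\{perm max >= observed max\}) / (nPerm + 1), is also
#' returned.
#'
#' Scheme `"clinical"` permutes the (time, event) pairs across samples;
#' scheme `"blocks"` relocates K contiguous genome blocks independently per
#' sample on the (already smoothed) matrix. Both schemes rerun the scan with
#' the observed scan's stride and parameters.
#'
#' @param observed the observed [ScanResult-class].
#' @param x the [CNExperiment-class] the observed scan was computed from
#'   (same smoothing).
#' @param data the [SurvivalData-class] used for the observed scan.
#' @param scheme `"clinical"` or `"blocks"`.
#' @param nPerm number of permutations; must be at least `ceiling(1/alpha)`.
#' @param K number of genome blocks for the blocks scheme (default 10).
#' @param alpha family-wise level (default 0.05).
#' @param seed master seed; the same seed reproduces the null exactly.
#' @return a [PermutationNull-class].
#' @export
maxtThreshold <- function(observed, x, data, scheme = c("clinical", "blocks"),
                          nPerm = 100L, K = 10L, alpha = 0.05,
                          seed = 1L) {
    stopifnot(is(observed, "ScanResult"), is(x, "CNExperiment"),
              is(data, "SurvivalData"))
    scheme <- match.arg(scheme)
    nPerm <- as.integer(nPerm)
    if (alpha <= 0 || alpha >= 1) .stopf("alpha must be in (0,1)")
    if (nPerm < ceiling(1 / alpha))
        .stopf("nPerm = %d is too small for alpha = %g (need >= %d)",
               nPerm, alpha, ceiling(1 / alpha))
    set.seed(as.integer(seed))

    method <- observed@method
    stride <- observed@stride
    prm <- observed@params
    cc <- completeCases(data)
    idx <- .testedIndices(as.character(rowData(x)$chromosome), stride)
    time <- data@time[cc]
    event <- as.integer(data@event[cc])
    full <- copyNumbers(x)[, cc, drop = FALSE]

    scanOnce <- function(vals, tt, ee) {
        if (method == "logrank") {
            g <- assignCNGroups(vals[idx, , drop = FALSE],
                                prm$delThresh, prm$gainThresh)
            lr <- cpp_logrank_scan(g, tt, ee, 3L)
            st <- lr$statistic
            df <- lr$df
            p <- ifelse(df >= 1 & !is.na(st),
                        pchisq(st, pmax(df, 1), lower.tail = FALSE), NA_real_)
            # same eligibility gate as the observed scan, recomputed per
            # permutation: the chi-square tail is unusable for near-empty
            # groups, so genome-wide inference is restricted to markers
            # with >= 2 groups of minExpected expected events
            elig <- rowSums(!is.na(lr$exp) & lr$exp >= prm$minExpected) >= 2
            p[!elig] <- NA_real_
            .scanMax(-log10(p), "logrank")
        } else {
            o <- order(tt)
            cx <- cpp_cox_scan(vals[idx, o, drop = FALSE],
                               matrix(0, length(tt), 0),
                               tt[o], ee[o],
                               identical(prm$ties, "efron"), 1e-8, 50L)
            z <- ifelse(as.logical(cx$converged), cx$z, NA_real_)
            .scanMax(z, "cox")
        }
    }

    maxima <- numeric(nPerm)
    for (b in seq_len(nPerm)) {
        if (scheme == "clinical") {
            perm <- sample.int(length(time))
            maxima[b] <- scanOnce(full, time[perm], event[perm])
        } else {
            maxima[b] <- scanOnce(.blockPermuteMatrix(full, K), time, event)
        }
    }
    if (all(is.na(maxima))) .stopf("all permutation scans were degenerate")
    obsScore <- observed@results$score
    obsScore[!observed@results$eligible] <- NA_real_
    obsMax <- .scanMax(obsScore, method)
    if (is.na(obsMax)) .stopf("observed scan has no eligible marker")
    thr <- .thresholdFromMaxima(maxima, alpha)
    new("PermutationNull",
        maxima = maxima, threshold = thr, alpha = alpha, scheme = scheme,
        nPerm = nPerm, K = as.integer(K), observedMax = obsMax,
        empiricalP = (1 + sum(maxima >= obsMax, na.rm = TRUE)) / (nPerm + 1),
        seed = as.integer(seed))
}

.thresholdFromMaxima <- function(maxima, alpha) {
    m <- maxima[!is.na(maxima)]
    sort(m, decreasing = TRUE)[min(length(m), ceiling(alpha * length(maxima)))]
}

#' @rdname survscan-generics
#' @export
setMethod("maxima", "PermutationNull", function(x, ...) x@maxima)

#' @rdname survscan-generics
#' @param alpha optional alternative level at which to recompute the
#'   threshold from the stored maxima.
#' @export
setMethod("threshold", "PermutationNull", function(x, alpha = NULL, ...) {
    if (is.null(alpha)) return(x@threshold)
    .thresholdFromMaxima(x@maxima, alpha)
})

#' @rdname survscan-generics
#' @export
setMethod("empiricalP", "PermutationNull", function(x, ...) x@empiricalP)

#' @export
setMethod("show", "PermutationNull", function(object) {
    cat(sprintf(paste0("PermutationNull (%s scheme, %d permutations):\n",
                       "  genome-wide threshold at alpha = %g: %.4f\n",
                       "  observed max %.4f, empirical genome-wide p = %.4g\n"),
                object@scheme, object@nPerm, object@alpha, object@threshold,
                object@observedMax, object@empiricalP))
    invisible(NULL)
})

#' Supra-threshold genomic regions
#'
#' Maximal runs of consecutive tested markers whose score meets or exceeds
#' the genome-wide threshold (|z| for Cox scans), merged within a
#' chromosome and reported as 1-based inclusive intervals with the peak
#' marker and peak score. An empty result is a valid outcome.
#'
#' @param observed a [ScanResult-class].
#' @param null a [PermutationNull-class], or a bare numeric threshold.
#' @return a [GenomicRanges::GRanges] with metadata columns `peak_marker`,
#'   `peak_score`, `n_markers`.
#' @export
significantRegions <- function(observed, null) {
    stopifnot(is(observed, "ScanResult"))
    thr <- if (is(null, "PermutationNull")) null@threshold else as.numeric(null)
    r <- observed@results
    sc <- if (observed@method == "cox") abs(r$score) else r$score
    hit <- !is.na(sc) & r$eligible & sc >= thr
    if (!any(hit)) {
        return(GRanges(seqnames = character(0),
                       ranges = IRanges(start = integer(0), end = integer(0)),
                       peak_marker = character(0), peak_score = numeric(0),
                       n_markers = integer(0)))
    }
    # maximal runs of consecutive hit markers within a chromosome
    n <- nrow(r)
    grp <- cumsum(c(TRUE, !(hit[-1] & hit[-n] &
                            r$chromosome[-1] == r$chromosome[-n])))
    pieces <- split(which(hit), grp[hit])
    chr <- character(0); st <- numeric(0); en <- numeric(0)
    pm <- character(0); ps <- numeric(0); nm <- integer(0)
    for (ix in pieces) {
        chr <- c(chr, r$chromosome[ix[1]])
        st <- c(st, min(r$position[ix]))
        en <- c(en, max(r$position[ix]))
        peak <- ix[which.max(sc[ix])]
        pm <- c(pm, r$marker_id[peak])
        ps <- c(ps, r$score[peak])
        nm <- c(nm, length(ix))
    }
    GRanges(seqnames = chr, ranges = IRanges(start = st, end = en),
            peak_marker = pm, peak_score = ps, n_markers = nm)
}
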