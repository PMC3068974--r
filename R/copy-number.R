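#' Local median smoothing of copy-number profiles
#'
#' For each sample independently, every marker's value is replaced by the
#' median of the raw values in a window of `window` consecutive markers
#' centered on it (floor((window-1)/2) markers to the left, the rest to the
#' right), truncated at chromosome boundaries so windows never span
#' chromosomes. Missing values are excluded from each median; an all-missing
#' window yields a missing value. Smoothing borrows strength from the
#' spatial correlation of copy-number segments: a 10-marker median (the
#' classic default) removes single-marker noise spikes while preserving
#' segment-scale gains and losses.
#'
#' @param x a [CNExperiment-class].
#' @param window positive integer window size in markers (default 10).
#' @return a `CNExperiment` with the smoothed assay; `metadata()$smoothing`
#'   records the window.
#' @export
smoothCopyNumber <- function(x, window = 10L) {
    stopifnot(is(x, "CNExperiment"))
    window <- as.integer(window)
    if (is.na(window) || window < 1L) .stopf("window must be >= 1")
    runs <- .chromRuns(as.character(rowData(x)$chromosome))
    sm <- cpp_smooth(copyNumbers(x), as.integer(runs), window)
    dimnames(sm) <- dimnames(copyNumbers(x))
    assay(x, "copynumber") <- sm
    metadata(x)$smoothing <- list(window = window)
    x
}

#' Rescale a copy-number profile so its modal level is 2 copies
#'
#' Tumor ploidy is often unknown; in hyperdiploid genomes the most common
#' copy level sits above 2, and without correction normal chromosomes would
#' look like deletions. The modal copy level is estimated per sample as the
#' center of the highest-count bin of a fixed-width histogram (bin width 0.1
#' copy, bin centers at 0.0, 0.1, ..., 8.0; ties broken toward the lower
#' level), and the profile is multiplied by `2 / mode`.
#'
#' @param x a numeric profile (one sample's genome-ordered copies) or a
#'   [CNExperiment-class] (rescaled sample-wise).
#' @return same shape as the input; the estimated mode(s) are attached as
#'   attribute `"mode"` (vector input) or `metadata()$ploidyMode`.
#' @examples
#' p <- rep(3, 50)
#' scaleModeToTwo(p)[1]   # 2
#' @export
scaleModeToTwo <- function(x) {
    if (is(x, "CNExperiment")) {
        v <- copyNumbers(x)
        modes <- numeric(ncol(v))
        for (j in seq_len(ncol(v))) {
            sc <- scaleModeToTwo(v[, j])
            v[, j] <- sc
            modes[j] <- attr(sc, "mode")
        }
        assay(x, "copynumber") <- v
        metadata(x)$ploidyMode <- setNames(modes, colnames(v))
        return(x)
    }
    p <- as.numeric(x)
    ok <- !is.na(p)
    if (sum(ok) < 20)
        .stopf("profile needs at least 20 non-missing values for mode estimation")
    centers <- seq(0, 8, by = 0.1)
    breaks <- c(centers - 0.05, 8.05)
    inrange <- ok & p >= breaks[1] & p < breaks[length(breaks)]
    bins <- findInterval(p[inrange], breaks)
    counts <- tabulate(bins, nbins = length(centers))
    mode <- centers[which.max(counts)]
    if (mode <= 0.2)
        .stopf("degenerate profile: modal copy level %.2f <= 0.2", mode)
    out <- p * 2 / mode
    attributes(out) <- attributes(x)
    attr(out, "mode") <- mode
    out
}

#' Assign Deletion / No-change / Gain groups from copy numbers
#'
#' Samples at one marker are grouped by inferred copy number with inclusive
#' boundaries: Deletion (value <= `delThresh`), Gain (value >= `gainThresh`)
#' and NoChange strictly between. Missing values are unassignable and come
#' back as `NA`; they are excluded from that marker's test.
#'
#' @param values numeric vector (one marker across samples) or matrix
#'   (markers x samples).
#' @param delThresh,gainThresh copy thresholds, defaults 1.5 and 2.5 copies;
#'   must satisfy `delThresh < gainThresh`.
#' @return factor with levels `Deletion`, `NoChange`, `Gain` (vector input),
#'   or an integer matrix coded 1/2/3 with 0 for missing (matrix input, used
#'   by the genome scan).
#' @examples
#' assignCNGroups(c(1.2, 2.0, 3.1))
#' assignCNGroups(c(1.5, 2.5))   # boundaries are Deletion / Gain
#' @export
assignCNGroups <- function(values, delThresh = 1.5, gainThresh = 2.5) {
    if (delThresh >= gainThresh)
        .stopf("delThresh must be below gainThresh")
    code <- function(v) {
        g <- ifelse(is.na(v), 0L,
                    ifelse(v <= delThresh, 1L, ifelse(v >= gainThresh, 3L, 2L)))
        g
    }
    if (is.matrix(values)) {
        g <- code(values)
        dim(g) <- dim(values)
        dimnames(g) <- dimnames(values)
        storage.mode(g) <- "integer"
        return(g)
    }
    factor(c(NA, "Deletion", "NoChange", "Gain")[code(values) + 1L],
           levels = c("Deletion", "NoChange", "Gain"))
}
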