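# Static renderings of the two analysis views: Kaplan-Meier comparisons
# and genome score tracks. Base graphics; optional file output (png/svg).

.openDevice <- function(file, width, height) {
    ext <- tolower(tools::file_ext(file))
    switch(ext,
           png = grDevices::png(file, width = width, height = height,
                                units = "in", res = 150),
           svg = grDevices::svg(file, width = width, height = height),
           .stopf("unsupported figure format '%s' (use .png or .svg)", ext))
}

#' Kaplan-Meier plot with group legend
#'
#' Step-function survival curves per group with censoring tick marks. The
#' legend line per group is `"<group>: n=<n>, Exp=<expected>, Obs=<observed>"`.
#' The log-rank p-value is printed only when the test is eligible (at least
#' two groups with enough expected events); an ineligible or absent test
#' yields a figure without a p-value annotation.
#'
#' @param km a [KMCurve-class].
#' @param result optional [LogrankResult-class] for the p-value annotation.
#' @param file optional output path (`.png` or `.svg`); default draws on the
#'   current device.
#' @param main plot title.
#' @param col colors recycled over groups.
#' @param width,height device size in inches when `file` is given.
#' @return invisibly, a list with the legend lines and whether a p-value was
#'   drawn.
#' @export
plotKM <- function(km, result = NULL, file = NULL,
                   main = "Kaplan-Meier survival",
                   col = c("#1f77b4", "#d62728", "#2ca02c", "#9467bd",
                           "#8c564b"),
                   width = 6, height = 5) {
    stopifnot(is(km, "KMCurve"))
    if (!is.null(file)) {
        .openDevice(file, width, height)
        on.exit(grDevices::dev.off())
    }
    curves <- km@curves
    col <- rep_len(col, length(curves))
    xmax <- max(1, vapply(curves, function(cv) max(cv$time, 0),
                          numeric(1)))
    graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, 1),
                   xlab = "Time", ylab = "Survival probability", main = main)
    for (i in seq_along(curves)) {
        cv <- curves[[i]]
        xs <- c(0, rep(cv$time, each = 2))
        ys <- c(1, 1, rep(cv$surv, each = 2)[seq_len(max(0, 2 * nrow(cv) - 1))])
        graphics::lines(xs, ys, col = col[i], lwd = 2)
        cens <- cv$time[cv$nCensor > 0]
        if (length(cens)) {
            sv <- cv$surv[cv$nCensor > 0]
            graphics::points(cens, sv, pch = 3, col = col[i], cex = 0.8)
        }
    }
    sm <- km@summary
    legendLines <- sprintf("%s: n=%d, Exp=%.1f, Obs=%.0f", sm$group, sm$n,
                           sm$expected, sm$observed)
    graphics::legend("bottomleft", legend = legendLines, col = col, lwd = 2,
                     bty = "n", cex = 0.8)
    showP <- !is.null(result) && is(result, "LogrankResult") && result@eligible
    if (showP) {
        graphics::mtext(sprintf("log-rank p = %.3g", result@pValue), side = 3,
                        adj = 1, cex = 0.8)
    }
    if (km@nOmitted > 0) {
        graphics::mtext(sprintf("%d sample(s) omitted (missing survival)",
                                km@nOmitted),
                        side = 1, line = 4, adj = 0, cex = 0.7)
    }
    invisible(list(legend = legendLines, pShown = showP))
}

#' Genome score track plot
#'
#' Scores against genome position with chromosome boundaries marked.
#' Log-rank tracks show -log10 p in blue; Cox tracks show |z| with sign
#' encoded by color (red = positive = higher hazard with more copies,
#' blue = negative). When a permutation null is supplied its genome-wide
#' threshold is drawn as a horizontal red reference line. Chromosomes whose
#' tested markers all lack scores are annotated as empty.
#'
#' @param scan a [ScanResult-class].
#' @param null optional [PermutationNull-class] (or numeric threshold).
#' @param file optional output path (`.png` or `.svg`).
#' @param main plot title; defaults to the scan method.
#' @param width,height device size in inches when `file` is given.
#' @return invisibly, the data.frame of plotted points.
#' @export
plotScan <- function(scan, null = NULL, file = NULL, main = NULL,
                     width = 8, height = 4) {
    stopifnot(is(scan, "ScanResult"))
    if (!is.null(file)) {
        .openDevice(file, width, height)
        on.exit(grDevices::dev.off())
    }
    r <- scan@results
    isCox <- scan@method == "cox"
    y <- if (isCox) abs(r$score) else r$score
    chroms <- unique(r$chromosome)
    offs <- 0
    gx <- numeric(nrow(r))
    bounds <- numeric(0)
    centers <- numeric(0)
    for (ch in chroms) {
        ix <- which(r$chromosome == ch)
        gx[ix] <- offs + r$position[ix]
        w <- max(r$position[ix])
        centers <- c(centers, offs + w / 2)
        offs <- offs + w
        bounds <- c(bounds, offs)
    }
    ylab <- if (isCox) "|z| (Cox)" else "-log10 p (log-rank)"
    if (is.null(main))
        main <- sprintf("Genome-wide survival scan (%s)", scan@method)
    ymax <- max(c(y, if (!is.null(null))
        if (is(null, "PermutationNull")) null@threshold else null),
        na.rm = TRUE)
    graphics::plot(NA, xlim = c(0, offs), ylim = c(0, 1.05 * ymax),
                   xlab = "Genome position", ylab = ylab, main = main,
                   xaxt = "n")
    graphics::axis(1, at = centers, labels = chroms, tick = FALSE)
    graphics::abline(v = bounds[-length(bounds)], col = "grey80", lty = 3)
    colv <- if (isCox) ifelse(r$score >= 0, "#d62728", "#1f77b4") else "#1f77b4"
    ok <- !is.na(y)
    graphics::points(gx[ok], y[ok], col = colv[ok], pch = 16, cex = 0.5)
    for (i in seq_along(chroms)) {
        ix <- r$chromosome == chroms[i]
        if (all(is.na(y[ix])))
            graphics::text(centers[i], ymax / 2, "no scores", cex = 0.7,
                           col = "grey50", srt = 90)
    }
    if (!is.null(null)) {
        thr <- if (is(null, "PermutationNull")) null@threshold else null
        graphics::abline(h = thr, col = "red", lwd = 1.5)
        graphics::mtext(sprintf("genome-wide 0.05 threshold = %.2f", thr),
                        side = 3, adj = 1, cex = 0.7, col = "red")
    }
    invisible(data.frame(x = gx, y = y))
}
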