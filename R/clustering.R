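# Expression-based sample clustering and Kaplan-Meier comparison between
# selected cluster branches. The interactive click-to-select workflow is
# replaced by node ids on the merge tree or a height cut.

#' Variation filter for expression rows
#'
#' Keeps rows (genes) whose coefficient of variation sd/mean across samples
#' lies in `[lower, upper]` — the classic filter used to restrict clustering
#' to genes that actually vary. Expression must be on a linear, nonnegative
#' scale.
#'
#' @param expr numeric matrix, genes x samples, with rownames.
#' @param lower,upper bounds on sd/mean (defaults 0.5 and 1000).
#' @return character vector of retained row ids.
#' @export
variationFilter <- function(expr, lower = 0.5, upper = 1000) {
    stopifnot(is.matrix(expr))
    if (any(expr < 0, na.rm = TRUE)) .stopf("expression must be nonnegative")
    mu <- rowMeans(expr, na.rm = TRUE)
    s <- apply(expr, 1, sd, na.rm = TRUE)
    ratio <- ifelse(mu > 0, s / mu, NA_real_)  # all-zero rows: undefined, drop
    keep <- !is.na(ratio) & ratio >= lower & ratio <= upper
    message(sum(!keep), " of ", nrow(expr), " rows removed by variation filter")
    if (!any(keep))
        .stopf("no rows pass the variation filter; relax the [%g, %g] bounds",
               lower, upper)
    rownames(expr)[keep]
}

#' Hierarchical clustering of samples on expression
#'
#' Agglomerative clustering of samples with distance 1 - Pearson
#' correlation computed over row-standardized genes and average linkage by
#' default. The result is a standard `hclust` tree whose internal nodes are
#' addressed by merge index (1 .. nSamples-1, root = last); use
#' [selectClusters()] to turn chosen nodes into sample labels and
#' [exportNewick()] to serialize the tree.
#'
#' @param expr numeric matrix, genes x samples (typically pre-filtered with
#'   [variationFilter()]).
#' @param linkage one of `"average"` (default), `"complete"`, `"centroid"`.
#' @return an `hclust` object with sample labels.
#' @export
clusterSamples <- function(expr, linkage = c("average", "complete", "centroid")) {
    linkage <- match.arg(linkage)
    stopifnot(is.matrix(expr))
    if (ncol(expr) < 2 || nrow(expr) < 2)
        .stopf("need at least 2 samples and 2 genes")
    sv <- apply(expr, 2, sd)
    if (any(sv == 0))
        .stopf("sample(s) with zero expression variance: %s",
               paste(colnames(expr)[sv == 0], collapse = ", "))
    s <- apply(expr, 1, sd)
    zs <- expr[s > 0, , drop = FALSE]
    zs <- (zs - rowMeans(zs)) / apply(zs, 1, sd)
    d <- as.dist(1 - cor(zs))
    hclust(d, method = linkage)
}

# member leaf indices of internal node `node` (row of hc$merge)
.nodeMembers <- function(hc, node) {
    stopifnot(node >= 1, node <= nrow(hc$merge))
    out <- integer(0)
    stack <- node
    while (length(stack)) {
        nd <- stack[length(stack)]
        stack <- stack[-length(stack)]
        for (child in hc$merge[nd, ]) {
            if (child < 0) out <- c(out, -child) else stack <- c(stack, child)
        }
    }
    sort(out)
}

#' Turn dendrogram selections into per-sample group labels
#'
#' Mirrors the interactive branch selection: each selected internal node of
#' the merge tree becomes one group; samples outside every selected node are
#' unlabeled (`NA`). Alternatively cut the tree at a height and use all
#' resulting clusters.
#'
#' @param hc an `hclust` from [clusterSamples()].
#' @param nodes integer ids of internal nodes (rows of `hc$merge`); must be
#'   pairwise disjoint in membership.
#' @param cutHeight alternative to `nodes`: cut height passed to `cutree()`.
#' @return factor of group labels along `hc$labels`, `NA` outside selections.
#' @export
selectClusters <- function(hc, nodes = NULL, cutHeight = NULL) {
    stopifnot(inherits(hc, "hclust"))
    nSamples <- length(hc$labels)
    if (!is.null(cutHeight)) {
        cl <- cutree(hc, h = cutHeight)
        return(factor(paste0("cluster", cl),
                      levels = paste0("cluster", sort(unique(cl)))))
    }
    if (is.null(nodes) || length(nodes) < 1)
        .stopf("supply internal node ids or a cut height")
    members <- lapply(nodes, function(nd) .nodeMembers(hc, nd))
    all <- unlist(members)
    if (anyDuplicated(all))
        .stopf("selected nodes overlap in membership")
    lab <- rep(NA_character_, nSamples)
    for (i in seq_along(members))
        lab[members[[i]]] <- paste0("node", nodes[i])
    factor(lab, levels = paste0("node", nodes))
}

#' Export a sample dendrogram in Newick format
#'
#' @param hc an `hclust` with sample labels.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
exportNewick <- function(hc, path) {
    ape::write.tree(ape::as.phylo(hc), file = path)
    invisible(path)
}

#' Kaplan-Meier comparison of selected sample clusters
#'
#' Applies [kmEstimate()] and [logrankTest()] (with the expected-events
#' display gate) to the group labels from a cluster selection, reporting the
#' number of samples omitted for missing survival data. Labels may come from
#' [selectClusters()] or be passed directly — the comparison only sees the
#' labels.
#'
#' @param labels per-sample group labels (`NA` = not selected), aligned with
#'   `data`.
#' @param data a [SurvivalData-class].
#' @param minExpected gating constant for the log-rank p-value display.
#' @return list with elements `km` ([KMCurve-class]) and `logrank`
#'   ([LogrankResult-class]).
#' @export
compareClustersSurvival <- function(labels, data, minExpected = 5) {
    stopifnot(is(data, "SurvivalData"))
    gc <- .groupCodes(labels)
    usable <- table(gc$codes[gc$codes > 0L & completeCases(data)])
    if (length(usable) < 2)
        .stopf("need at least 2 selected clusters with survival data")
    list(km = kmEstimate(data, labels),
         logrank = logrankTest(data, labels, minExpected = minExpected))
}
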