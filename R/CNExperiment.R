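#' Build a CNExperiment from a value matrix, annotation and sample table
#'
#' Assembles the central container: rows are reordered to genome order
#' (chromosome 1..22, X, Y, then position), markers absent from the
#' annotation are dropped with a message, and sample information is matched
#' to matrix columns by sample id. Matrix columns without a sample-table row
#' are kept with a warning; they are excluded from survival analyses because
#' their outcome is missing.
#'
#' @param values numeric matrix, markers x samples, rownames = marker ids,
#'   colnames = sample ids; linear copy scale (diploid = 2).
#' @param annotation data.frame with columns `marker_id`, `chromosome`,
#'   `position` and optionally `gene`, `cytoband`.
#' @param sampleInfo optional data.frame with a `sample_id` column (as
#'   returned by [readSampleInfo()]); stored in `colData()`.
#' @return a [CNExperiment-class] object.
#' @examples
#' ann <- data.frame(marker_id = c("m1", "m2"), chromosome = "1",
#'                   position = c(100, 200))
#' v <- matrix(2, 2, 2, dimnames = list(c("m2", "m1"), c("S1", "S2")))
#' cne <- CNExperiment(v, ann)
#' @export
CNExperiment <- function(values, annotation, sampleInfo = NULL) {
    if (!is.matrix(values) || !is.numeric(values))
        .stopf("'values' must be a numeric matrix")
    if (is.null(rownames(values)))
        .stopf("'values' must have marker ids as rownames")
    ann <- .checkAnnotation(annotation)

    keep <- rownames(values) %in% ann$marker_id
    if (!any(keep))
        .stopf("no overlap between matrix markers and annotation")
    if (any(!keep))
        message(sum(!keep), " matrix marker(s) absent from annotation dropped")
    values <- values[keep, , drop = FALSE]

    ann <- ann[match(rownames(values), ann$marker_id), , drop = FALSE]
    ord <- order(chromOrder(ann$chromosome), ann$position)
    values <- values[ord, , drop = FALSE]
    ann <- ann[ord, , drop = FALSE]

    cd <- NULL
    if (!is.null(sampleInfo)) {
        if (!"sample_id" %in% colnames(sampleInfo))
            .stopf("'sampleInfo' must have a 'sample_id' column")
        hit <- match(colnames(values), sampleInfo$sample_id)
        if (anyNA(hit))
            warning(sum(is.na(hit)), " sample column(s) not in the sample ",
                    "table; kept but excluded from survival analyses",
                    call. = FALSE)
        cd <- DataFrame(sampleInfo[hit, , drop = FALSE], check.names = FALSE)
        rownames(cd) <- colnames(values)
    }

    rd <- DataFrame(ann[, setdiff(colnames(ann), "marker_id"), drop = FALSE])
    rownames(rd) <- ann$marker_id
    se <- if (is.null(cd)) {
        SummarizedExperiment(assays = list(copynumber = values), rowData = rd)
    } else {
        SummarizedExperiment(assays = list(copynumber = values), rowData = rd,
                             colData = cd)
    }
    new("CNExperiment", se)
}

.checkAnnotation <- function(annotation) {
    need <- c("marker_id", "chromosome", "position")
    if (!all(need %in% colnames(annotation)))
        .stopf("annotation must have columns %s", paste(need, collapse = ", "))
    ann <- as.data.frame(annotation)
    ann$marker_id <- as.character(ann$marker_id)
    ann$chromosome <- as.character(ann$chromosome)
    ann$position <- as.numeric(ann$position)
    if (anyDuplicated(ann$marker_id))
        .stopf("duplicate marker ids in annotation")
    if (any(is.na(ann$position)) || any(ann$position < 0))
        .stopf("annotation positions must be nonnegative numbers")
    ann
}

#' @rdname survscan-generics
#' @export
setMethod("copyNumbers", "CNExperiment", function(x, ...) {
    assay(x, "copynumber")
})

#' @export
setMethod("show", "CNExperiment", function(object) {
    cat("CNExperiment:", nrow(object), "markers x", ncol(object), "samples\n")
    chr <- as.character(rowData(object)$chromosome)
    cat("  chromosomes:", paste(unique(chr), collapse = ", "), "\n")
    md <- metadata(object)
    if (!is.null(md$smoothing))
        cat("  smoothing: window", md$smoothing$window, "\n")
    if (!is.null(md$ploidyMode))
        cat("  ploidy-rescaled (mode -> 2 copies)\n")
    invisible(NULL)
})

#' Extract survival outcomes from a CNExperiment or sample table
#'
#' Pulls the configured survival-time and event columns out of `colData()`
#' (or a plain sample table) into a [SurvivalData-class] object aligned
#' with the object's samples. Samples with either field missing carry
#' missing survival and are omitted, with a reported count, from analyses.
#'
#' @param x a `CNExperiment` or a data.frame with a `sample_id` column.
#' @param timeCol,eventCol column names holding the survival time and the
#'   event indicator (1 = event, 0 = censored).
#' @return a `SurvivalData` object, samples in `x`'s order.
#' @export
survivalData <- function(x, timeCol = "Survival(numeric)",
                         eventCol = "Event(numeric)") {
    if (is(x, "CNExperiment")) {
        tab <- as.data.frame(colData(x), optional = TRUE)
        tab$sample_id <- colnames(x)
    } else {
        tab <- as.data.frame(x)
    }
    if (!all(c(timeCol, eventCol) %in% colnames(tab)))
        .stopf("columns '%s' and '%s' not found", timeCol, eventCol)
    SurvivalData(time = as.numeric(tab[[timeCol]]),
                 event = as.numeric(tab[[eventCol]]),
                 sampleId = as.character(tab$sample_id))
}
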