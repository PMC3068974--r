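# Tab-delimited readers/writers for the four input dialects. Strictly
# TAB-separated, "." decimal point, UTF-8; missing tokens: empty cell,
# "NA", "na", "NaN".

#' Read a tab-delimited sample-information file
#'
#' The first row is a header; one column holds the sample identifier.
#' Columns whose header ends in `"(numeric)"` are parsed as numbers, with
#' unparseable cells recorded as missing. The configured event column is
#' validated to contain only 0, 1 or missing.
#'
#' @param path file path.
#' @param idCol name or index of the sample-id column (default: first).
#' @param timeCol,eventCol names of the survival-time and event-indicator
#'   columns (the classic convention is `"Survival(numeric)"` /
#'   `"Event(numeric)"`; file conventions vary, so the names are
#'   configuration, not guessed).
#' @return data.frame with a `sample_id` column plus all remaining columns,
#'   numeric ones parsed; attributes `timeCol`/`eventCol` record the
#'   configured names.
#' @export
readSampleInfo <- function(path, idCol = 1L,
                           timeCol = "Survival(numeric)",
                           eventCol = "Event(numeric)") {
    if (!file.exists(path)) .stopf("file not found: %s", path)
    raw <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                      check.names = FALSE, stringsAsFactors = FALSE,
                      quote = "", fileEncoding = "UTF-8")
    if (nrow(raw) == 0) .stopf("sample-information file has no data rows")
    idName <- if (is.numeric(idCol)) colnames(raw)[idCol] else idCol
    if (!idName %in% colnames(raw)) .stopf("id column '%s' not found", idName)

    ids <- trimws(raw[[idName]])
    dup <- ids[duplicated(ids)]
    if (length(dup))
        .stopf("duplicate sample id(s): %s", paste(unique(dup), collapse = ", "))

    out <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
    for (cn in setdiff(colnames(raw), idName)) {
        col <- raw[[cn]]
        if (grepl("\\(numeric\\)$", cn)) {
            out[[cn]] <- .parseNumeric(col)
        } else {
            col <- trimws(col)
            col[col %in% .MISSING_TOKENS] <- NA_character_
            out[[cn]] <- col
        }
    }

    if (eventCol %in% colnames(out)) {
        ev <- out[[eventCol]]
        bad <- which(!is.na(ev) & !(ev %in% c(0, 1)))
        if (length(bad))
            .stopf("event column '%s' has value outside {0,1} for sample '%s'",
                   eventCol, out$sample_id[bad[1]])
    }
    if (timeCol %in% colnames(out)) {
        tm <- out[[timeCol]]
        bad <- which(!is.na(tm) & tm < 0)
        if (length(bad))
            .stopf("survival column '%s' is negative for sample '%s'",
                   timeCol, out$sample_id[bad[1]])
    }
    attr(out, "timeCol") <- timeCol
    attr(out, "eventCol") <- eventCol
    out
}

#' Write a sample-information table
#'
#' Inverse of [readSampleInfo()]: tab-delimited, header row, missing values
#' as empty cells. Reading the file back yields the same table.
#'
#' @param table data.frame with a `sample_id` column.
#' @param path output path.
#' @param idName header to use for the id column.
#' @return `path`, invisibly.
#' @export
writeSampleInfo <- function(table, path, idName = "Sample") {
    stopifnot("sample_id" %in% colnames(table))
    out <- table
    colnames(out)[colnames(out) == "sample_id"] <- idName
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "", fileEncoding = "UTF-8")
    invisible(path)
}

#' Read a marker-annotation table
#'
#' Expects tab-delimited columns `marker_id`, `chromosome`, `position`
#' (1-based base pairs) and optionally `gene`, `cytoband`. Rows are returned
#' sorted by chromosome then position.
#'
#' @param path file path.
#' @return data.frame in genome order.
#' @export
readAnnotation <- function(path) {
    if (!file.exists(path)) .stopf("file not found: %s", path)
    raw <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE, quote = "",
                      fileEncoding = "UTF-8")
    ann <- .checkAnnotation(raw)
    ann[order(chromOrder(ann$chromosome), ann$position), , drop = FALSE]
}

#' Read a markers x samples matrix and order it to an annotation
#'
#' First column: marker id; remaining columns: one per sample. Rows are
#' reordered to the annotation's genome order; markers absent from the
#' annotation are dropped with a message.
#'
#' @param path file path.
#' @param annotation data.frame as from [readAnnotation()].
#' @return numeric matrix in genome order (rownames = marker ids).
#' @export
readCNMatrix <- function(path, annotation) {
    if (!file.exists(path)) .stopf("file not found: %s", path)
    raw <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE, quote = "",
                      fileEncoding = "UTF-8")
    if (nrow(raw) == 0) .stopf("matrix file has no data rows")
    ids <- trimws(as.character(raw[[1]]))
    vals <- as.matrix(raw[, -1, drop = FALSE])
    suppressWarnings(storage.mode(vals) <- "double")
    rownames(vals) <- ids

    ann <- .checkAnnotation(annotation)
    ann <- ann[order(chromOrder(ann$chromosome), ann$position), , drop = FALSE]
    keep <- ids %in% ann$marker_id
    if (!any(keep)) .stopf("no overlap between matrix markers and annotation")
    if (any(!keep))
        message(sum(!keep), " matrix marker(s) absent from annotation dropped")
    vals <- vals[keep, , drop = FALSE]
    hit <- match(ann$marker_id, rownames(vals))
    vals[hit[!is.na(hit)], , drop = FALSE]
}

#' Write a markers x samples matrix
#'
#' @param values numeric matrix with marker rownames and sample colnames.
#' @param path output path.
#' @param idName header for the marker-id column.
#' @return `path`, invisibly.
#' @export
writeCNMatrix <- function(values, path, idName = "Marker") {
    df <- data.frame(id = rownames(values), values, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1] <- idName
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA", fileEncoding = "UTF-8")
    invisible(path)
}

#' Read an array-list file (ordered sample subset)
#'
#' One sample id per line; downstream analyses are restricted to and ordered
#' by this list.
#'
#' @param path file path.
#' @param table sample table (data.frame with `sample_id`) used to validate
#'   every listed id.
#' @return character vector of sample ids.
#' @export
readArrayList <- function(path, table) {
    if (!file.exists(path)) .stopf("file not found: %s", path)
    ids <- trimws(readLines(path, encoding = "UTF-8"))
    ids <- ids[ids != ""]
    if (length(ids) == 0) .stopf("array-list file is empty")
    if (anyDuplicated(ids))
        .stopf("duplicate sample id(s) in array list: %s",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
    unknown <- setdiff(ids, table$sample_id)
    if (length(unknown))
        .stopf("array-list sample id(s) not in sample table: %s",
               paste(unknown, collapse = ", "))
    ids
}
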