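#' Construct a SurvivalData object
#'
#' A sample with only one of (time, event) present is treated as missing
#' both: the half-observed outcome cannot enter a survival analysis, so the
#' pair is set missing and counted among the omitted samples.
#'
#' @param time nonnegative survival times (study time units), NA allowed.
#' @param event event indicators, 1 = event observed, 0 = censored, NA
#'   allowed.
#' @param sampleId unique sample identifiers (defaults to `S1..Sn`).
#' @return a [SurvivalData-class] object.
#' @examples
#' sd <- SurvivalData(c(1, 2, 3, 4), c(1, 1, 0, 1))
#' completeCases(sd)
#' @export
SurvivalData <- function(time, event, sampleId = NULL) {
    n <- length(time)
    if (is.null(sampleId)) sampleId <- paste0("S", seq_len(n))
    time <- as.numeric(time)
    event <- suppressWarnings(as.integer(round(as.numeric(event))))
    half <- is.na(time) != is.na(event)
    if (any(half)) {
        time[half] <- NA_real_
        event[half] <- NA_integer_
    }
    new("SurvivalData", time = time, event = event,
        sampleId = as.character(sampleId))
}

#' @rdname survscan-generics
#' @export
setMethod("survTime", "SurvivalData", function(x, ...) {
    setNames(x@time, x@sampleId)
})

#' @rdname survscan-generics
#' @export
setMethod("survEvent", "SurvivalData", function(x, ...) {
    setNames(x@event, x@sampleId)
})

#' @rdname survscan-generics
#' @export
setMethod("sampleIds", "SurvivalData", function(x, ...) x@sampleId)

#' @rdname survscan-generics
#' @export
setMethod("completeCases", "SurvivalData", function(x, ...) {
    !is.na(x@time) & !is.na(x@event)
})

#' @rdname survscan-generics
#' @export
setMethod("nOmitted", "SurvivalData", function(x, ...) {
    sum(!completeCases(x))
})

#' @export
setMethod("length", "SurvivalData", function(x) length(x@time))

setMethod("[", "SurvivalData", function(x, i, j, ..., drop = TRUE) {
    new("SurvivalData", time = x@time[i], event = x@event[i],
        sampleId = x@sampleId[i])
})

#' @export
setMethod("show", "SurvivalData", function(object) {
    cc <- completeCases(object)
    cat("SurvivalData:", length(object), "samples,",
        sum(object@event[cc] == 1L), "events,",
        sum(!cc), "with missing outcome\n")
    invisible(NULL)
})
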