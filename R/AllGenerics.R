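#' @name survscan-generics
#' @title Accessor generics
#' @description Small accessor generics shared across the result classes.
#' @param x an object.
#' @param ... passed to methods.
NULL

#' @rdname survscan-generics
#' @export
setGeneric("pValue", function(x, ...) standardGeneric("pValue"))

#' @rdname survscan-generics
#' @export
setGeneric("statistic", function(x, ...) standardGeneric("statistic"))

#' @rdname survscan-generics
#' @export
setGeneric("eligible", function(x, ...) standardGeneric("eligible"))

#' @rdname survscan-generics
#' @export
setGeneric("nOmitted", function(x, ...) standardGeneric("nOmitted"))

#' @rdname survscan-generics
#' @export
setGeneric("survTime", function(x, ...) standardGeneric("survTime"))

#' @rdname survscan-generics
#' @export
setGeneric("survEvent", function(x, ...) standardGeneric("survEvent"))

#' @rdname survscan-generics
#' @export
setGeneric("sampleIds", function(x, ...) standardGeneric("sampleIds"))

#' @rdname survscan-generics
#' @export
setGeneric("completeCases", function(x, ...) standardGeneric("completeCases"))

#' @rdname survscan-generics
#' @export
setGeneric("copyNumbers", function(x, ...) standardGeneric("copyNumbers"))

#' @rdname survscan-generics
#' @export
setGeneric("scanTable", function(x, ...) standardGeneric("scanTable"))

#' @rdname survscan-generics
#' @export
setGeneric("scanScores", function(x, ...) standardGeneric("scanScores"))

#' @rdname survscan-generics
#' @export
setGeneric("kmCurves", function(x, ...) standardGeneric("kmCurves"))

#' @rdname survscan-generics
#' @export
setGeneric("kmSummary", function(x, ...) standardGeneric("kmSummary"))

#' @rdname survscan-generics
#' @export
setGeneric("maxima", function(x, ...) standardGeneric("maxima"))

#' @rdname survscan-generics
#' @export
setGeneric("threshold", function(x, ...) standardGeneric("threshold"))

#' @rdname survscan-generics
#' @export
setGeneric("empiricalP", function(x, ...) standardGeneric("empiricalP"))
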