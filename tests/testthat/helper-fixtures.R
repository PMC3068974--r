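# shared fixture builders (all data generated in code)

# tiny annotation: nPerChrom markers on each chromosome label
makeAnnotation <- function(nPerChrom, chroms = "1") {
    m <- sum(nPerChrom)
    data.frame(
        marker_id = sprintf("m%03d", seq_len(m)),
        chromosome = rep(chroms, nPerChrom),
        position = unlist(lapply(nPerChrom, function(k) seq_len(k) * 100)),
        stringsAsFactors = FALSE)
}

# CNExperiment with given value matrix laid over makeAnnotation
makeCNE <- function(values, nPerChrom = nrow(values), chroms = "1",
                    sampleInfo = NULL) {
    ann <- makeAnnotation(nPerChrom, chroms)
    rownames(values) <- ann$marker_id
    if (is.null(colnames(values)))
        colnames(values) <- sprintf("S%02d", seq_len(ncol(values)))
    CNExperiment(values, ann, sampleInfo)
}

# random censored survival dataset
randomSurv <- function(n, eventRate = 0.7) {
    SurvivalData(round(rexp(n, 1 / 20), 3), rbinom(n, 1, eventRate))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

writeTempLines <- function(lines) {
    f <- tempfile(fileext = ".txt")
    writeLines(lines, f)
    f
}
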