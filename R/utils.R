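# shared helpers

.MISSING_TOKENS <- c("", "NA", "na", "NaN")

#' Canonical chromosome ordering
#'
#' Maps chromosome labels to an orderable rank: numeric labels ascending,
#' then X, then Y, then any other label alphabetically. An optional "chr"
#' prefix is ignored.
#'
#' @param chrom character vector of chromosome labels.
#' @return integer ranks usable in `order()`.
#' @export
chromOrder <- function(chrom) {
    lab <- sub("^chr", "", as.character(chrom))
    num <- suppressWarnings(as.numeric(lab))
    rank <- ifelse(!is.na(num), num,
                   ifelse(lab == "X", 1000,
                          ifelse(lab == "Y", 1001, NA)))
    other <- is.na(rank)
    if (any(other)) {
        rank[other] <- 1002 + match(lab[other], sort(unique(lab[other])))
    }
    rank
}

# parse a character vector as numeric, honoring the missing-value tokens;
# anything else unparseable becomes NA as well (recorded as missing)
.parseNumeric <- function(x) {
    x <- trimws(x)
    x[x %in% .MISSING_TOKENS] <- NA_character_
    suppressWarnings(as.numeric(x))
}

# chromosome run index (1, 1, ..., 2, 2, ...) for rows already in genome order
.chromRuns <- function(chrom) {
    chrom <- as.character(chrom)
    cumsum(c(TRUE, chrom[-1] != chrom[-length(chrom)]))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
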