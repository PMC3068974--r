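# Synthetic genome-ordered copy-number (and expression) datasets coupled to
# survival with planted effects. The generator is the package's study-
# condition source: its defaults define the demo conditions used throughout
# the tests and the acceptance script.

#' Specify a synthetic copy-number/survival dataset
#'
#' The generative model: each sample carries true copy 2 everywhere except
#' in planted regions, where a random carrier subset has copy 1 (deletion)
#' or 3 (gain); observed copies add Gaussian noise (sd `cnNoiseSD`)
#' truncated at 0. Event times are exponential with rate
#' `lambda0 * exp(sum of region logHR x carrier indicator)`; censoring is
#' independent uniform on (0, `censorMax`), observed time = min(event,
#' censor). Optional expression groups add a mean shift to a subset of genes
#' and (optionally) a per-group log hazard ratio.
#'
#' @param nSamples,nMarkers totals; markers are split evenly over
#'   `chromosomes`.
#' @param chromosomes character vector of chromosome labels.
#' @param regions list of planted regions; each a list with elements
#'   `chromosome`, `start`, `end` (1-based marker indices within the
#'   chromosome), `type` (`"deletion"` or `"gain"`), `carrierFraction` in
#'   (0,1), and `logHR`.
#' @param cnNoiseSD copy-scale Gaussian noise sd (default 0.35).
#' @param lambda0 baseline exponential hazard; default `log(2)/36`, i.e.
#'   median survival of 36 time units (months) for non-carriers.
#' @param censorMax upper end of the uniform censoring window (default 120).
#' @param clusterSpec optional list(`nGroups`, `nGenes`, `nInformative`,
#'   `shift`, `logHR`) describing expression groups; `logHR` is a per-group
#'   vector added to the log hazard (0 = no survival effect).
#' @return a `"simSpec"` list, ready for [simulateDataset()].
#' @export
simulationSpec <- function(nSamples = 200L, nMarkers = 2000L,
                           chromosomes = c("1", "2", "3", "4"),
                           regions = list(), cnNoiseSD = 0.35,
                           lambda0 = log(2) / 36, censorMax = 120,
                           clusterSpec = NULL) {
    stopifnot(nSamples >= 2, nMarkers >= length(chromosomes), lambda0 > 0,
              censorMax > 0, cnNoiseSD >= 0)
    perChrom <- rep(nMarkers %/% length(chromosomes), length(chromosomes))
    perChrom[seq_len(nMarkers %% length(chromosomes))] <-
        perChrom[seq_len(nMarkers %% length(chromosomes))] + 1L
    names(perChrom) <- chromosomes
    for (rg in regions) {
        if (!all(c("chromosome", "start", "end", "type", "carrierFraction",
                   "logHR") %in% names(rg)))
            .stopf("each region needs chromosome, start, end, type, carrierFraction, logHR")
        if (!rg$chromosome %in% chromosomes)
            .stopf("region chromosome '%s' not in the genome", rg$chromosome)
        if (rg$start < 1 || rg$end > perChrom[[rg$chromosome]] ||
            rg$start > rg$end)
            .stopf("region [%d, %d] outside chromosome %s (%d markers)",
                   rg$start, rg$end, rg$chromosome, perChrom[[rg$chromosome]])
        if (!rg$type %in% c("deletion", "gain"))
            .stopf("region type must be 'deletion' or 'gain'")
        if (rg$carrierFraction <= 0 || rg$carrierFraction >= 1)
            .stopf("carrierFraction must be in (0,1)")
    }
    structure(list(nSamples = as.integer(nSamples),
                   nMarkers = as.integer(nMarkers),
                   chromosomes = chromosomes, perChrom = perChrom,
                   regions = regions, cnNoiseSD = cnNoiseSD,
                   lambda0 = lambda0, censorMax = censorMax,
                   clusterSpec = clusterSpec),
              class = "simSpec")
}

#' The demo study conditions
#'
#' 200 samples, 2,000 markers over 4 chromosomes, one planted 50-marker
#' deletion (chromosome 1, markers 201-250) carried by 40% of samples with
#' hazard ratio 3, baseline median survival 36 time units, uniform(0, 120)
#' censoring. Under the exponential model carriers have median survival
#' 36/3 = 12.
#'
#' @return a `"simSpec"`.
#' @export
demoSpec <- function() {
    simulationSpec(
        nSamples = 200L, nMarkers = 2000L,
        regions = list(list(chromosome = "1", start = 201L, end = 250L,
                            type = "deletion", carrierFraction = 0.4,
                            logHR = log(3))))
}

#' Null study conditions (no copy-number/survival association)
#'
#' The null hypothesis under test is that no region's copy number is
#' associated with survival — not that the genome is free of alterations.
#' A tumor genome without alterations would leave every sample in the
#' No-change group and make copy-number grouping undefined, so the null
#' conditions plant alteration regions (two deletions, two gains, 40%
#' carriers) whose log hazard ratio is exactly 0: copy-number structure is
#' present, survival is independent of it.
#'
#' @param nSamples,nMarkers reduced sizes used in calibration simulations
#'   (defaults 100 samples, 500 markers over 2 chromosomes).
#' @return a `"simSpec"` whose planted regions all have `logHR = 0`.
#' @export
nullSpec <- function(nSamples = 100L, nMarkers = 500L) {
    nullRegion <- function(chromosome, start, end, type) {
        list(chromosome = chromosome, start = start, end = end, type = type,
             carrierFraction = 0.4, logHR = 0)
    }
    half <- nMarkers %/% 2
    q <- half %/% 5
    simulationSpec(nSamples = nSamples, nMarkers = nMarkers,
                   chromosomes = c("1", "2"),
                   regions = list(
                       nullRegion("1", q + 1L, 2L * q, "deletion"),
                       nullRegion("1", 3L * q + 1L, 4L * q, "gain"),
                       nullRegion("2", q + 1L, 2L * q, "deletion"),
                       nullRegion("2", 3L * q + 1L, 4L * q, "gain")))
}

#' Generate a synthetic dataset
#'
#' Deterministic given `seed`: the same seed yields byte-identical files
#' from [writeDataset()]. Latent truth (event/censor times, hazards,
#' carrier indicators) is returned for parameter-recovery checks.
#'
#' @param spec a `"simSpec"` from [simulationSpec()].
#' @param seed integer seed.
#' @return list with elements `cn` ([CNExperiment-class], raw copies),
#'   `annotation`, `sampleTable` (with `Survival(numeric)` /
#'   `Event(numeric)` columns), `surv` ([SurvivalData-class]),
#'   `expression` (matrix or NULL), `exprGroups` (factor or NULL),
#'   `carriers` (logical matrix samples x regions), `latent` (data.frame),
#'   `spec`.
#' @export
simulateDataset <- function(spec, seed = 1L) {
    stopifnot(inherits(spec, "simSpec"))
    set.seed(as.integer(seed))
    n <- spec$nSamples
    m <- spec$nMarkers
    sampleIds <- sprintf("S%03d", seq_len(n))
    chrom <- rep(spec$chromosomes, spec$perChrom)
    within <- unlist(lapply(spec$perChrom, seq_len), use.names = FALSE)
    ann <- data.frame(marker_id = sprintf("SNP_%05d", seq_len(m)),
                      chromosome = chrom,
                      position = within * 100000L,
                      gene = paste0("GENE", (seq_len(m) - 1L) %/% 20L + 1L),
                      stringsAsFactors = FALSE)

    truth <- matrix(2, nrow = m, ncol = n)
    nReg <- length(spec$regions)
    carriers <- matrix(FALSE, nrow = n, ncol = max(nReg, 1L))
    loghr <- rep(0, n)
    for (i in seq_len(nReg)) {
        rg <- spec$regions[[i]]
        offset <- c(0L, cumsum(spec$perChrom))[match(rg$chromosome,
                                                     spec$chromosomes)]
        rows <- offset + rg$start:rg$end
        carry <- sample.int(n, round(rg$carrierFraction * n))
        carriers[carry, i] <- TRUE
        truth[rows, carry] <- if (rg$type == "deletion") 1 else 3
        loghr[carry] <- loghr[carry] + rg$logHR
    }

    expression <- NULL
    exprGroups <- NULL
    cs <- spec$clusterSpec
    if (!is.null(cs)) {
        gix <- sort(rep_len(seq_len(cs$nGroups), n))
        exprGroups <- factor(paste0("G", gix))
        base <- matrix(2 ^ rnorm(cs$nGenes * n, mean = 7, sd = 0.5),
                       nrow = cs$nGenes, ncol = n)
        inf <- seq_len(min(cs$nInformative, cs$nGenes))
        for (g in seq_len(cs$nGroups)) {
            base[inf, gix == g] <- base[inf, gix == g] * 2 ^ (cs$shift * (g - 1))
        }
        dimnames(base) <- list(sprintf("EXPR_%04d", seq_len(cs$nGenes)),
                               sampleIds)
        expression <- base
        if (!is.null(cs$logHR)) loghr <- loghr + cs$logHR[gix]
    }

    raw <- pmax(truth + matrix(rnorm(m * n, sd = spec$cnNoiseSD), m, n), 0)
    dimnames(raw) <- list(ann$marker_id, sampleIds)

    hazard <- spec$lambda0 * exp(loghr)
    eventTime <- rexp(n, rate = hazard)
    censorTime <- runif(n, 0, spec$censorMax)
    time <- pmin(eventTime, censorTime)
    event <- as.integer(eventTime <= censorTime)

    sampleTable <- data.frame(sample_id = sampleIds, stringsAsFactors = FALSE)
    sampleTable[["Survival(numeric)"]] <- round(time, 4)
    sampleTable[["Event(numeric)"]] <- event
    surv <- SurvivalData(sampleTable[["Survival(numeric)"]], event, sampleIds)

    list(cn = CNExperiment(raw, ann, sampleTable),
         annotation = ann, sampleTable = sampleTable, surv = surv,
         expression = expression, exprGroups = exprGroups,
         carriers = carriers,
         latent = data.frame(sample_id = sampleIds, eventTime = eventTime,
                             censorTime = censorTime, hazard = hazard,
                             logHR = loghr),
         spec = spec)
}

#' Write a simulated dataset in the tab-delimited dialects
#'
#' Emits `matrix.txt`, `annotation.txt`, `sample_info.txt` and (if present)
#' `expression.txt` under `dir`. Byte-identical for identical simulations.
#'
#' @param sim result of [simulateDataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(sim, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeCNMatrix(round(copyNumbers(sim$cn), 4),
                  file.path(dir, "matrix.txt"))
    write.table(sim$annotation, file.path(dir, "annotation.txt"), sep = "\t",
                quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
    writeSampleInfo(sim$sampleTable, file.path(dir, "sample_info.txt"))
    if (!is.null(sim$expression))
        writeCNMatrix(round(sim$expression, 4),
                      file.path(dir, "expression.txt"), idName = "Gene")
    invisible(dir)
}
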