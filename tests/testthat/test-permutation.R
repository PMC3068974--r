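test_that("block permutation rearranges whole blocks and conserves values", {
    # deterministic core: (a,b,c,d), break after 2, blocks swapped
    p <- c("a", "b", "c", "d")
    expect_equal(survscan:::.applyBlocks(p, breaks = 2L, ord = c(2L, 1L)),
                 c("c", "d", "a", "b"))

    expect_error(blockPermuteProfile(1:10, K = 1), "K must be >= 2")
    expect_error(blockPermuteProfile(1:3, K = 5), "exceeds")

    set.seed(71)
    L <- 200; K <- 10
    x <- rnorm(L)
    pairs <- paste(head(x, -1), tail(x, -1))
    nPreserved <- replicate(1000, {
        y <- blockPermuteProfile(x, K)
        expect_identical(sort(y), sort(x))   # multiset conservation
        sum(paste(head(y, -1), tail(y, -1)) %in% pairs)
    })
    broken <- (L - 1) - nPreserved
    # at most K-1 adjacencies can break (only the cut junctions)
    expect_true(all(broken <= K - 1))
    # mean preserved is L-K plus the chance of rejoined junctions, < 1
    expect_gte(mean(nPreserved), L - K)
    expect_lte(mean(nPreserved), L - K + 1)
})

test_that("clinical permutation conserves (time,event) pairs and decorrelates", {
    set.seed(72)
    d <- randomSurv(40)
    pd <- permuteClinical(d)
    expect_equal(sort(paste(survTime(pd), survEvent(pd))),
                 sort(paste(survTime(d), survEvent(d))))
    expect_equal(sampleIds(pd), sampleIds(d))

    # average Kendall correlation between original and permuted times ~ 0
    taus <- replicate(200, cor(d@time, permuteClinical(d)@time,
                               method = "kendall"))
    expect_lt(abs(mean(taus)), 0.05)
})

test_that("threshold follows the order-statistic rule and alpha monotonicity", {
    set.seed(73)
    sim <- simulateDataset(nullSpec(nSamples = 60, nMarkers = 100), seed = 73)
    sm <- smoothCopyNumber(sim$cn, 10)
    sc <- scanLogrank(sm, sim$surv, stride = 10)
    nul <- maxtThreshold(sc, sm, sim$surv, scheme = "clinical", nPerm = 40,
                         alpha = 0.1, seed = 74)
    mx <- maxima(nul)
    expect_length(mx, 40L)
    expect_equal(threshold(nul),
                 sort(mx, decreasing = TRUE)[ceiling(0.1 * 40)])
    # thresholds nonincreasing in alpha, recomputed from the same maxima
    expect_gte(threshold(nul, alpha = 0.05), threshold(nul, alpha = 0.1))
    expect_gte(threshold(nul, alpha = 0.1), threshold(nul, alpha = 0.25))
    # nPerm too small for alpha is rejected
    expect_error(maxtThreshold(sc, sm, sim$surv, nPerm = 10, alpha = 0.05),
                 "too small")
})

test_that("identical seeds reproduce the permutation null exactly", {
    set.seed(75)
    sim <- simulateDataset(nullSpec(nSamples = 50, nMarkers = 80), seed = 75)
    sm <- smoothCopyNumber(sim$cn, 10)
    sc <- scanLogrank(sm, sim$surv, stride = 10)
    for (scheme in c("clinical", "blocks")) {
        a <- maxtThreshold(sc, sm, sim$surv, scheme = scheme, nPerm = 25,
                           alpha = 0.1, seed = 99)
        b <- maxtThreshold(sc, sm, sim$surv, scheme = scheme, nPerm = 25,
                           alpha = 0.1, seed = 99)
        expect_identical(maxima(a), maxima(b))
        expect_identical(threshold(a), threshold(b))
    }
})

test_that("an observed maximum above every permutation maximum hits the p floor", {
    set.seed(76)
    sim <- simulateDataset(demoSpec(), seed = 76)
    sm <- smoothCopyNumber(sim$cn, 10)
    cx <- scanCox(sm, sim$surv, stride = 10)
    nul <- maxtThreshold(cx, sm, sim$surv, scheme = "clinical", nPerm = 50,
                         alpha = 0.05, seed = 77)
    if (nul@observedMax > max(maxima(nul))) {
        expect_equal(empiricalP(nul), 1 / 51)
    }
    expect_gte(empiricalP(nul), 1 / 51)
    expect_lte(empiricalP(nul), 1)
})

test_that("significant regions are maximal supra-threshold runs with peaks", {
    tab <- data.frame(
        marker_id = paste0("m", 1:8),
        chromosome = rep(c("1", "2"), each = 4),
        position = rep(c(100, 200, 300, 400), 2),
        score = c(1, 6, 7, 2, 8, 1, 6, 6),
        statistic = 1, p_value = 0.5,
        eligible = TRUE)
    sc <- new("ScanResult", results = tab, method = "logrank", stride = 1L,
              params = list(), nOmitted = 0L)
    gr <- significantRegions(sc, 5)
    expect_equal(length(gr), 3L)
    expect_equal(as.character(GenomicRanges::seqnames(gr)), c("1", "2", "2"))
    expect_equal(GenomicRanges::start(gr), c(200, 100, 300))
    expect_equal(GenomicRanges::end(gr), c(300, 100, 400))
    expect_equal(gr$peak_marker, c("m3", "m5", "m7"))
    expect_equal(gr$peak_score, c(7, 8, 6))
    expect_equal(gr$n_markers, c(2L, 1L, 2L))

    # nothing above threshold -> empty result
    expect_length(significantRegions(sc, 100), 0L)
    # ineligible markers cannot seed a region
    tab2 <- tab; tab2$eligible <- FALSE
    sc2 <- new("ScanResult", results = tab2, method = "logrank", stride = 1L,
               params = list(), nOmitted = 0L)
    expect_length(significantRegions(sc2, 5), 0L)
})
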