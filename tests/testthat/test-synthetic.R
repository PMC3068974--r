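test_that("simulation is deterministic: same seed, byte-identical files", {
    spec <- nullSpec(nSamples = 20, nMarkers = 40)
    d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
    writeDataset(simulateDataset(spec, seed = 5), d1)
    writeDataset(simulateDataset(spec, seed = 5), d2)
    writeDataset(simulateDataset(spec, seed = 6), d3)
    for (f in c("matrix.txt", "annotation.txt", "sample_info.txt")) {
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)))
    }
    expect_false(identical(readLines(file.path(d1, "matrix.txt")),
                           readLines(file.path(d3, "matrix.txt"))))
})

test_that("the demo spec encodes the stated study conditions", {
    spec <- demoSpec()
    expect_equal(spec$nSamples, 200L)
    expect_equal(spec$nMarkers, 2000L)
    rg <- spec$regions[[1]]
    expect_equal(rg$end - rg$start + 1L, 50L)
    expect_equal(rg$carrierFraction, 0.4)
    expect_equal(exp(rg$logHR), 3)
    # baseline median survival 36 and carrier median 36/3 = 12, closed form
    expect_equal(qexp(0.5, spec$lambda0), 36)
    expect_equal(qexp(0.5, spec$lambda0 * exp(rg$logHR)), 12)

    sim <- simulateDataset(spec, seed = 10)
    carriers <- sim$carriers[, 1]
    expect_equal(sum(carriers), 80)
    # empirical carrier median event time near 12 (latent, pre-censoring)
    expect_equal(median(sim$latent$eventTime[carriers]), 12, tolerance = 0.25)
    # planted rows have ~1 copy in carriers, ~2 in non-carriers
    v <- copyNumbers(sim$cn)[201:250, ]
    expect_equal(mean(v[, carriers]), 1, tolerance = 0.05)
    expect_equal(mean(v[, !carriers]), 2, tolerance = 0.05)
})

test_that("censoring fraction matches the closed-form probability", {
    # P(censor < event) for T ~ Exp(lambda), U ~ Unif(0, C):
    # (1 - exp(-lambda C)) / (lambda C)
    spec <- nullSpec(nSamples = 4000, nMarkers = 10)
    spec$regions <- list()     # keep every sample at baseline hazard
    sim <- simulateDataset(spec, seed = 20)
    lam <- spec$lambda0; C <- spec$censorMax
    pCens <- (1 - exp(-lam * C)) / (lam * C)
    expect_equal(mean(survEvent(sim$surv) == 0), pCens, tolerance = 0.03)
})

test_that("cox_fit on the true carrier indicator recovers the planted beta", {
    set.seed(30)
    miss <- 0
    for (s in 1:5) {
        sim <- simulateDataset(demoSpec(), seed = 100 + s)
        f <- coxFit(sim$surv, as.numeric(sim$carriers[, 1]))
        beta <- unname(coef(f)[1])
        if (abs(beta - log(3)) >= 3 * f@se[1]) miss <- miss + 1
    }
    expect_lte(miss, 1)
})

test_that("expression groups are generated with the requested structure", {
    spec <- simulationSpec(nSamples = 40, nMarkers = 50,
                           chromosomes = "1",
                           clusterSpec = list(nGroups = 2, nGenes = 100,
                                              nInformative = 30, shift = 2,
                                              logHR = c(0, log(2.5))))
    sim <- simulateDataset(spec, seed = 40)
    expect_equal(dim(sim$expression), c(100, 40))
    expect_equal(nlevels(sim$exprGroups), 2L)
    expect_true(all(sim$expression >= 0))
    # informative genes really separate the groups
    inf <- 1:30
    lfc <- log2(rowMeans(sim$expression[inf, sim$exprGroups == "G2"]) /
                rowMeans(sim$expression[inf, sim$exprGroups == "G1"]))
    expect_equal(mean(lfc), 2, tolerance = 0.3)
    # group 2 carries the extra hazard
    expect_equal(unique(sim$latent$logHR[sim$exprGroups == "G2"]), log(2.5))
})

test_that("infeasible specs are rejected", {
    expect_error(simulationSpec(regions = list(list(
        chromosome = "9", start = 1, end = 10, type = "deletion",
        carrierFraction = 0.4, logHR = 0))), "not in the genome")
    expect_error(simulationSpec(regions = list(list(
        chromosome = "1", start = 400, end = 600, type = "deletion",
        carrierFraction = 0.4, logHR = 0))), "outside chromosome")
    expect_error(simulationSpec(regions = list(list(
        chromosome = "1", start = 1, end = 10, type = "duplication",
        carrierFraction = 0.4, logHR = 0))), "deletion")
    expect_error(simulationSpec(regions = list(list(
        chromosome = "1", start = 1, end = 10, type = "gain",
        carrierFraction = 1.4, logHR = 0))), "carrierFraction")
})
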