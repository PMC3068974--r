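test_that("variation filter keeps rows by coefficient of variation", {
    expr <- rbind(constant = rep(5, 6),
                  variable = c(40, 160, 100, 130, 70, 100),
                  zero = rep(0, 6))
    expect_message(keep <- variationFilter(expr, lower = 0.3), "removed")
    expect_equal(keep, "variable")
    # sd/mean ratio 0.6 for mean 100, sd 60 lies inside [0.5, 1000]
    expect_equal(sd(expr["variable", ]) / mean(expr["variable", ]), 0.42,
                 tolerance = 0.05)
    # lower = 0 keeps every nonconstant row
    suppressMessages(expect_equal(variationFilter(expr, lower = 0),
                                  c("constant", "variable")))
    expect_error(suppressMessages(variationFilter(expr, lower = 50)), "relax")
    expect_error(variationFilter(-expr), "nonnegative")
})

test_that("sample clustering merges duplicates first and ignores gene order", {
    set.seed(81)
    base <- matrix(2 ^ rnorm(200, 7, 1), nrow = 50)
    colnames(base) <- paste0("S", 1:4)
    rownames(base) <- paste0("g", 1:50)
    base[, 2] <- base[, 1]                       # duplicated sample profile
    hc <- clusterSamples(base)
    first <- hc$merge[1, ]
    expect_equal(sort(-first), c(1, 2))          # duplicates merge first
    expect_equal(hc$height[1], 0, tolerance = 1e-12)

    # permuting gene order leaves the tree unchanged
    hc2 <- clusterSamples(base[sample(50), ])
    expect_equal(hc$merge, hc2$merge)
    expect_equal(hc$height, hc2$height)

    # anti-correlated sample merges last
    m <- matrix(0, nrow = 20, ncol = 3,
                dimnames = list(paste0("g", 1:20), c("A", "B", "C")))
    sig <- seq(1, 4, length.out = 20)
    m[, "A"] <- 2 ^ (sig + rnorm(20, 0, 0.05))
    m[, "B"] <- 2 ^ (sig + rnorm(20, 0, 0.05))
    m[, "C"] <- 2 ^ (rev(sig) + rnorm(20, 0, 0.05))
    hc3 <- clusterSamples(m)
    expect_equal(sort(-hc3$merge[1, ]), c(1, 2)) # correlated pair first

    mz <- m; mz[, "B"] <- 5                      # zero-variance sample
    expect_error(clusterSamples(mz), "B")
})

test_that("node selection yields disjoint labeled groups; overlap errors", {
    set.seed(82)
    expr <- matrix(2 ^ rnorm(300, 7, 1), nrow = 30)
    colnames(expr) <- paste0("S", 1:10)
    rownames(expr) <- paste0("g", 1:30)
    hc <- clusterSamples(expr)
    root <- nrow(hc$merge)
    kids <- hc$merge[root, ]
    expect_true(all(kids > 0) || sum(kids > 0) >= 1)
    nodes <- kids[kids > 0]
    if (length(nodes) == 2) {
        lab <- selectClusters(hc, nodes)
        expect_equal(sum(!is.na(lab)), 10L)      # root children cover all
        expect_equal(nlevels(lab), 2L)
        expect_error(selectClusters(hc, c(root, nodes[1])), "overlap")
    }
    # height cut provides labels too
    lab2 <- selectClusters(hc, cutHeight = median(hc$height))
    expect_equal(length(lab2), 10L)
    # newick export round-trips through ape
    f <- tempfile(fileext = ".nwk")
    exportNewick(hc, f)
    tr <- ape::read.tree(f)
    expect_setequal(tr$tip.label, colnames(expr))
})

test_that("cluster survival comparison is pure label plumbing", {
    set.seed(83)
    n <- 60
    d <- randomSurv(n, 0.8)
    lab <- factor(rep(c("node3", "node7"), each = n / 2))
    res <- compareClustersSurvival(lab, d)
    direct <- logrankTest(d, lab)
    expect_equal(statistic(res$logrank), statistic(direct))
    expect_equal(kmSummary(res$km)$n, unname(direct@n))

    # samples outside the selection are excluded, missing survival reported
    lab2 <- lab; lab2[1:5] <- NA
    res2 <- compareClustersSurvival(lab2, d)
    expect_equal(sum(kmSummary(res2$km)$n), n - 5)

    # fewer than two usable clusters errors
    labAll <- factor(rep("node3", n))
    expect_error(compareClustersSurvival(labAll, d), "2 selected clusters")
    dMiss <- SurvivalData(ifelse(seq_len(n) <= n / 2, NA, survTime(d)),
                          ifelse(seq_len(n) <= n / 2, NA, survEvent(d)))
    expect_error(compareClustersSurvival(lab, dMiss), "2 selected clusters")
})

test_that("null clusters give calibrated p-values; planted risk groups have power", {
    # identical survival distributions in both arms: p should not be extreme
    set.seed(84)
    pvals <- replicate(40, {
        n <- 100
        tt <- rexp(n, 1 / 36)
        cen <- runif(n, 0, 120)
        d <- SurvivalData(pmin(tt, cen), as.integer(tt <= cen))
        pValue(logrankTest(d, rep(c("A", "B"), each = n / 2)))
    })
    expect_gt(min(pvals), 0.001)
    expect_gt(mean(pvals > 0.05), 0.8)   # near-uniform null p-values

    # hazard ratio 2.5 with 85 samples/arm: significant in >= 90% of runs
    set.seed(85)
    hits <- replicate(50, {
        n <- 170
        g <- rep(0:1, each = 85)
        tt <- rexp(n, (log(2) / 36) * 2.5 ^ g)
        cen <- runif(n, 0, 120)
        d <- SurvivalData(pmin(tt, cen), as.integer(tt <= cen))
        pValue(logrankTest(d, ifelse(g == 1, "hi", "lo"))) < 0.05
    })
    expect_gte(mean(hits), 0.9)
})
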