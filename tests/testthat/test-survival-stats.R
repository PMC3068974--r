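test_that("product-limit estimate matches the hand calculation", {
    km <- kmEstimate(SurvivalData(c(1, 2, 3, 4), c(1, 1, 0, 1)))
    cv <- kmCurves(km)[[1]]
    expect_equal(cv$surv, c(0.75, 0.50, 0.50, 0.00))
    expect_equal(cv$nRisk, c(4, 3, 2, 1))
    sm <- kmSummary(km)
    expect_equal(sm$observed, 3)
    expect_equal(sm$expected, 3)   # single group: Exp = total events
})

test_that("KM curves start at 1, are nonincreasing, in [0,1]; Obs sums = Exp sums", {
    set.seed(21)
    for (rep in 1:10) {
        n <- sample(10:40, 1)
        d <- randomSurv(n)
        g <- sample(c("A", "B", "C"), n, replace = TRUE)
        km <- kmEstimate(d, g)
        for (cv in kmCurves(km)) {
            expect_true(all(cv$surv >= 0 & cv$surv <= 1))
            expect_true(all(diff(c(1, cv$surv)) <= 1e-12))
        }
        sm <- kmSummary(km)
        expect_equal(sum(sm$observed), sum(sm$expected))
        expect_equal(sum(sm$observed), sum(survEvent(d) == 1))
    }
})

test_that("all-censored data gives flat curves and zero observed events", {
    km <- kmEstimate(SurvivalData(c(5, 7, 9, 11), c(0, 0, 0, 0)),
                     c("A", "A", "B", "B"))
    for (cv in kmCurves(km)) expect_true(all(cv$surv == 1))
    expect_true(all(kmSummary(km)$observed == 0))
})

test_that("two identical groups give identical curves and a zero log-rank", {
    tt <- c(1, 3, 5, 8, 12, 20)
    ev <- c(1, 1, 0, 1, 0, 1)
    d <- SurvivalData(c(tt, tt), c(ev, ev))
    g <- rep(c("A", "B"), each = 6)
    km <- kmEstimate(d, g)
    expect_equal(kmCurves(km)$A, kmCurves(km)$B)
    r <- logrankTest(d, g)
    expect_equal(statistic(r), 0, tolerance = 1e-12)
    expect_equal(pValue(r), 1)
})

test_that("log-rank matches the reference implementation on separated groups", {
    skip_if_not_installed("survival")
    tt <- c(1, 2, 3, 10, 11, 12)
    ev <- rep(1, 6)
    g <- rep(c("A", "B"), each = 3)
    r <- logrankTest(SurvivalData(tt, ev), g)
    ref <- survival::survdiff(survival::Surv(tt, ev) ~ g)
    expect_equal(statistic(r), ref$chisq, tolerance = 1e-10)
    expect_equal(unname(r@observed), unname(ref$obs))
    expect_equal(unname(r@expected), unname(ref$exp))
})

test_that("three copy-number groups give a 2-df test; gating flags low counts", {
    set.seed(3)
    n <- 60
    d <- randomSurv(n, eventRate = 0.9)
    cn <- c(rep(1, 20), rep(2, 20), rep(3, 20))
    r <- logrankTest(d, assignCNGroups(cn))
    expect_equal(r@df, 2L)
    expect_true(r@eligible)

    # a 2-sample comparison with ~1 expected event in a group is ineligible,
    # but the statistic is still computed
    d2 <- SurvivalData(c(1, 2, 3, 4, 50), c(1, 1, 1, 1, 0))
    r2 <- logrankTest(d2, c("A", "A", "A", "A", "B"))
    expect_false(r2@eligible)
    expect_true(is.finite(statistic(r2)))

    expect_error(logrankTest(d2, rep("A", 5)), "2 nonempty groups")
})

test_that("log-rank is invariant to label permutation and time rescaling", {
    set.seed(9)
    n <- 50
    d <- randomSurv(n)
    g <- sample(c("A", "B", "C"), n, replace = TRUE)
    r <- logrankTest(d, g)
    # relabel groups
    g2 <- c(A = "C", B = "A", C = "B")[g]
    expect_equal(statistic(logrankTest(d, g2)), statistic(r))
    # rescale time
    d2 <- SurvivalData(survTime(d) * 7.3, survEvent(d))
    expect_equal(statistic(logrankTest(d2, g)), statistic(r))
    # p equals the chi-square upper tail of the statistic
    expect_equal(pValue(r),
                 pchisq(statistic(r), r@df, lower.tail = FALSE))
})

test_that("Cox fit honors sign contracts and covariate negation", {
    # all events, covariate strictly increasing with time -> protective
    d <- SurvivalData(1:10, rep(1, 10))
    f <- coxFit(d, 1:10 / 10)
    expect_lt(coef(f)[1], 0)

    set.seed(13)
    n <- 80
    d2 <- randomSurv(n)
    x <- rnorm(n)
    f1 <- coxFit(d2, x)
    f2 <- coxFit(d2, -x)
    expect_equal(unname(coef(f2)[1]), -unname(coef(f1)[1]), tolerance = 1e-7)
    expect_equal(abs(f2@z[1]), abs(f1@z[1]), tolerance = 1e-7)
    expect_equal(unname(pValue(f1))[1], 2 * pnorm(-abs(f1@z[[1]])))

    expect_error(coxFit(d2, rep(1, n)), "degenerate covariate")
})

test_that("Cox under the null stays near zero", {
    set.seed(77)
    n <- 200
    tt <- rexp(n, 1 / 30)
    cen <- runif(n, 0, 90)
    d <- SurvivalData(pmin(tt, cen), as.integer(tt <= cen))
    x <- rnorm(n, 2, 0.3)
    f <- coxFit(d, x)
    expect_lt(abs(f@z[1]), 4)
    expect_lt(abs(coef(f)[1]), 3 * f@se[1])
})

test_that("Cox score and log-rank agree asymptotically for 2 groups", {
    set.seed(31)
    n <- 100
    g <- rep(0:1, each = n / 2)
    tt <- rexp(n, 1 / 20 * exp(0.6 * g))
    cen <- runif(n, 0, 60)
    d <- SurvivalData(pmin(tt, cen), as.integer(tt <= cen))
    lrX <- statistic(logrankTest(d, ifelse(g == 1, "B", "A")))
    coxX <- statistic(coxFit(d, g))[1] ^ 2   # Wald chi-square
    expect_lt(abs(coxX - lrX) / lrX, 0.15)
})

test_that("Cox matches the reference implementation, Breslow and Efron ties", {
    skip_if_not_installed("survival")
    set.seed(41)
    for (ties in c("breslow", "efron")) {
        for (rep in 1:5) {
            n <- sample(15:30, 1)
            tt <- round(rexp(n, 1 / 10), 1)    # rounding forces ties
            ev <- rbinom(n, 1, 0.8)
            if (sum(ev) < 2) ev[1:2] <- 1L
            x <- rnorm(n)
            f <- coxFit(SurvivalData(tt, ev), x, ties = ties)
            ref <- survival::coxph(survival::Surv(tt, ev) ~ x, ties = ties)
            expect_equal(unname(coef(f)[1]), unname(coef(ref)),
                         tolerance = 1e-6)
            expect_equal(unname(f@se[1]), sqrt(unname(vcov(ref)[1, 1])),
                         tolerance = 1e-6)
        }
    }
})

test_that("multivariate Cox adjusts for extra covariates", {
    skip_if_not_installed("survival")
    set.seed(55)
    n <- 120
    age <- rnorm(n, 60, 8)
    x <- rnorm(n, 2, 0.4)
    tt <- rexp(n, 0.02 * exp(0.04 * (age - 60) - 0.5 * (x - 2)))
    cen <- runif(n, 0, 80)
    d <- SurvivalData(pmin(tt, cen), as.integer(tt <= cen))
    f <- coxFit(d, x, extra = data.frame(age = age))
    ref <- survival::coxph(survival::Surv(pmin(tt, cen),
                                          as.integer(tt <= cen)) ~ x + age,
                           ties = "breslow")
    expect_equal(unname(coef(f)), unname(coef(ref)), tolerance = 1e-6)
})

test_that("monotone likelihood is flagged, not silently reported", {
    # perfect separation: the largest covariate always fails first
    d <- SurvivalData(c(1, 2, 3, 4, 5, 6), c(1, 1, 1, 0, 0, 0))
    f <- coxFit(d, c(10, 9, 8, 1, 2, 3))
    expect_false(f@converged)
})

test_that("missing survival and missing covariates are complete-case omitted", {
    d <- SurvivalData(c(1, 2, NA, 4, 5), c(1, 0, NA, 1, 1))
    g <- c("A", "B", "A", "B", NA)
    r <- logrankTest(d, g)
    expect_equal(nOmitted(r), 1L)          # the missing-survival sample
    expect_equal(sum(r@n), 3)              # S5 has no group label

    f <- coxFit(d, c(1.2, 2, 3, NA, 2.5))
    expect_equal(nOmitted(f), 2L)          # missing survival + missing covariate
})
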