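simBaf <- function(cn, pB = 0.5, seed = 1) {
    set.seed(seed)
    am <- allelicModel()
    vapply(cn, function(c) {
        if (c == 0) return(rbeta(1, 1, 1))
        g <- rbinom(1, c, pB)
        psi <- am[[as.character(c)]]
        rbeta(1, psi[g + 1, 1], psi[g + 1, 2])
    }, numeric(1))
}

# a MixtureFit stub with hard component assignments for genotyping tests
stubFit <- function(comp, k, means = NULL) {
    n <- length(comp)
    pz <- matrix(0, n, k)
    pz[cbind(seq_len(n), comp)] <- 1
    if (is.null(means)) means <- seq_len(k)
    new("MixtureFit", variant = "SB", k = as.integer(k), nBatch = 1L,
        theta = matrix(rep(means, each = 2), 2, k),
        sigma2 = matrix(0.01, 2, k), pi = matrix(1 / k, 2, k),
        mu = matrix(rep(means, each = 2), 2, k),
        tau2 = matrix(0.1, 2, k), nu0 = c(10, 10), sigma02 = c(1, 1),
        logLik = c(0, 0), probz = pz, data = means[comp],
        batch = rep(1L, n), isAugmented = rep(FALSE, n),
        hypers = new("HyperPriors"), seed = 1L)
}

test_that("mapping likelihood matches direct evaluation", {
    model <- allelicModel()
    # one sample, one SNP, b = 0.5, copy 2, pB = 0.5
    b <- matrix(0.5, 1, 1)
    expected <- log(0.25 * dbeta(0.5, 1, 99) + 0.5 * dbeta(0.5, 20, 20) +
                    0.25 * dbeta(0.5, 99, 1))
    got <- mappingLogLik(b, 1L, mapping = 2L, model, popFreq = 0.5)
    expect_equal(got, expected, tolerance = 1e-6)
    # the balanced heterozygote term dominates at b = 0.5
    expect_gt(0.5 * dbeta(0.5, 20, 20),
              0.25 * (dbeta(0.5, 1, 99) + dbeta(0.5, 99, 1)))

    # b = 0, copy 1, pB = 0.3: A-allele term dominates
    bb <- 1e-6
    b0 <- matrix(bb, 1, 1)
    expected0 <- log(0.7 * dbeta(bb, 1, 99) + 0.3 * dbeta(bb, 99, 1))
    got0 <- mappingLogLik(b0, 1L, mapping = 1L, model, popFreq = 0.3)
    expect_equal(got0, expected0, tolerance = 1e-6)
    expect_gt(0.7 * dbeta(bb, 1, 99), 0.3 * dbeta(bb, 99, 1))

    # pB = 0: binomial degenerates to the all-A genotype
    got00 <- mappingLogLik(b0, 1L, mapping = 2L, model, popFreq = 0)
    expect_equal(got00, log(dbeta(bb, 1, 99)), tolerance = 1e-6)
})

test_that("mapping likelihood is invariant to sample and SNP order", {
    set.seed(80)
    cn <- sample(0:2, 40, TRUE)
    baf <- cbind(simBaf(cn, seed = 81), simBaf(cn, pB = 0.3, seed = 82))
    comp <- cn + 1L
    ll <- mappingLogLik(baf, comp, 0:2, popFreq = c(0.5, 0.3))
    perm <- sample(40)
    ll2 <- mappingLogLik(baf[perm, ], comp[perm], 0:2,
                         popFreq = c(0.5, 0.3))
    ll3 <- mappingLogLik(baf[, 2:1], comp, 0:2, popFreq = c(0.3, 0.5))
    expect_equal(ll, ll2, tolerance = 1e-10)
    expect_equal(ll, ll3, tolerance = 1e-10)
})

test_that("deletion polymorphism maps components to copies 0,1,2", {
    set.seed(83)
    n <- 300
    cn <- sample(0:2, n, TRUE, c(0.05, 0.3, 0.65))
    baf <- matrix(simBaf(cn, seed = 84), ncol = 1)
    fit <- stubFit(cn + 1L, 3, means = c(-3, -0.5, 0))
    calls <- genotypeComponents(fit, baf, regionId = "del")
    expect_identical(cnMapping(calls), c(0L, 1L, 2L))
    expect_true(all(abs(rowSums(cnProb(calls)) - 1) < 1e-12))
    expect_equal(hardCalls(calls), cn)
})

test_that("identical trimodal BAF in all components collapses to diploid", {
    set.seed(85)
    n <- 300
    comp <- sample(1:3, n, TRUE)
    baf <- matrix(simBaf(rep(2, n), seed = 86), ncol = 1)
    fit <- stubFit(comp, 3, means = c(-0.2, 0, 0.2))
    calls <- suppressMessages(
        genotypeComponents(fit, baf, regionId = "null", popFreq = 0.5))
    expect_identical(cnMapping(calls), c(2L, 2L, 2L))
})

test_that("tetramodal BAF in the top component maps it to three copies", {
    set.seed(87)
    n <- 400
    cn <- sample(2:3, n, TRUE, c(0.8, 0.2))
    baf <- matrix(simBaf(cn, seed = 88), ncol = 1)
    fit <- stubFit(cn - 1L, 2, means = c(0, 0.4))
    calls <- genotypeComponents(fit, baf, regionId = "dup")
    expect_identical(cnMapping(calls), c(2L, 3L))
})

test_that("copy number aggregation is a linear projection of probz", {
    pz <- matrix(c(0.7, 0.2, 0.1,
                   0.1, 0.6, 0.3), 2, 3, byrow = TRUE)
    n <- 2
    fit <- stubFit(c(1L, 2L), 3, means = c(-3, -0.5, 0))
    fit@probz <- pz
    fit@data <- c(-3, -0.5)
    set.seed(89)
    baf <- matrix(simBaf(c(0, 1), seed = 90), ncol = 1)
    calls <- genotypeComponents(fit, baf, popFreq = 0.5, probCut = 0.5)
    f <- cnMapping(calls)
    manual <- matrix(0, 2, 5)
    for (h in 1:3) manual[, f[h] + 1] <- manual[, f[h] + 1] + pz[, h]
    expect_equal(unname(cnProb(calls)), manual)
})

test_that("population allele frequency estimation uses diploid thresholds", {
    baf <- matrix(c(0.02, 0.05, 0.48, 0.52, 0.97, 0.99), ncol = 1)
    pf <- estimatePopFreq(baf, rep(TRUE, 6))
    # 2 AA, 2 AB, 2 BB -> pB = (2 + 4) / 12
    expect_equal(unname(pf), 0.5)
    pf2 <- estimatePopFreq(baf, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
    expect_equal(unname(pf2), (0 + 1) / 6)
})

test_that("Hardy-Weinberg chi-square reproduces hand-checked values", {
    # constructed exact equilibrium: q = 1/3
    res <- hweChisq(c(25, 100, 100))
    expect_equal(res$q, 1 / 3, tolerance = 1e-12)
    expect_equal(res$chi2, 0, tolerance = 1e-12)
    # matches a generic Pearson oracle on arbitrary triples
    set.seed(91)
    for (i in 1:20) {
        counts <- rmultinom(1, 500, c(0.04, 0.32, 0.64))[, 1]
        res <- hweChisq(counts)
        n <- sum(counts)
        q <- (2 * counts[1] + counts[2]) / (2 * n)
        expected <- n * c(q^2, 2 * q * (1 - q), (1 - q)^2)
        expect_equal(res$chi2, pearsonChisq(counts, expected),
                     tolerance = 1e-12)
    }
    # degenerate cases
    expect_equal(hweChisq(c(0, 0, 100))$chi2, 0)
    expect_error(hweChisq(c(0, 0, 0)), "no genotyped")
})
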