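# hyperparameters for the fixed-hyperparameter conjugate checks
fixedHp <- list(mu = 0.2, tau2 = 0.25, nu0 = 8, sigma02 = 0.5)

test_that("one-component posterior moments match the quadrature oracle", {
    set.seed(30)
    r <- rnorm(200, 0.3, 0.12)
    fit <- gibbsFit(r, variant = "SB", k = 1, fixU = TRUE,
                    fixedHypers = fixedHp, nStarts = 2, startBurnin = 20,
                    nBurnin = 100, nIter = 1500, seed = 31)
    oracle <- conjugateOracle(r, fixedHp$mu, fixedHp$tau2, fixedHp$nu0,
                              fixedHp$sigma02)
    thetaChain <- fit@theta[, 1]
    sigmaChain <- fit@sigma2[, 1]
    expect_lt(abs(mean(thetaChain) - oracle$eTheta),
              3 * batchMeansSe(thetaChain))
    expect_lt(abs(mean(sigmaChain) - oracle$eSigma2),
              max(3 * batchMeansSe(sigmaChain), 0.02 * oracle$eSigma2))
    expect_lt(abs(var(thetaChain) - oracle$vTheta), 0.5 * oracle$vTheta)
})

test_that("full hierarchy recovers mean and scale of one component", {
    set.seed(32)
    r <- rnorm(500, 0.3, 0.1)
    fit <- gibbsFit(r, variant = "SB", k = 1, nStarts = 2,
                    startBurnin = 50, nBurnin = 200, nIter = 600, seed = 33)
    expect_lt(abs(mean(fit@theta) - 0.3), 0.02)
    expect_lt(abs(mean(sqrt(fit@sigma2)) - 0.1), 0.02)
})

test_that("near-Gaussian sampling model at d = 100", {
    # marginal of r given (theta, sigma) is t_100, indistinguishable from
    # normal: Kolmogorov distance below 0.02
    x <- seq(-5, 5, length.out = 2001)
    kd <- max(abs(pt(x, df = 100) - pnorm(x)))
    expect_lt(kd, 0.02)
    # and the sampler's posterior predictive matches a normal fit
    set.seed(34)
    r <- rnorm(400, 0, 0.2)
    fit <- gibbsFit(r, variant = "SB", k = 1, nStarts = 2,
                    startBurnin = 50, nBurnin = 100, nIter = 300, seed = 35)
    pp <- posteriorPredictive(fit, nDraws = 50, seed = 36)
    expect_gt(pp$p.value, 0.01)
})

test_that("multi-batch model recovers batch-shifted component means", {
    set.seed(36)
    n <- 600
    batch <- rep(1:2, each = n / 2)
    cn <- sample(1:3, n, TRUE, c(0.1, 0.35, 0.55))
    means <- c(-2, -0.5, 0)
    shift <- c(0, 0.3)
    r <- rnorm(n, means[cn] + shift[batch], 0.1)
    fit <- gibbsFit(r, batch, variant = "MB", k = 3, nStarts = 5,
                    startBurnin = 100, nBurnin = 200, nIter = 500,
                    seed = 37)
    theta <- matrix(colMeans(fit@theta), 3, 2)
    theta <- apply(theta, 2, sort)
    for (h in 1:3)
        expect_lt(abs((theta[h, 2] - theta[h, 1]) - 0.3), 0.05)
    for (h in 1:3)
        expect_lt(abs(theta[h, 1] - means[h]), 0.05)
})

test_that("component probabilities are a proper per-sample distribution", {
    set.seed(38)
    r <- c(rnorm(150, -1), rnorm(150, 1))
    fit <- gibbsFit(r, variant = "SB", k = 2, nStarts = 3,
                    startBurnin = 50, nBurnin = 100, nIter = 300, seed = 39)
    expect_true(all(abs(rowSums(probz(fit)) - 1) < 1e-12))
    expect_true(all(probz(fit) >= 0))
})

test_that("SB and MB chains are identical when only one batch exists", {
    set.seed(40)
    r <- c(rnorm(100, -0.5), rnorm(100, 0.3))
    args <- list(r = r, batch = rep(1L, 200), k = 2, nStarts = 2,
                 startBurnin = 30, nBurnin = 50, nIter = 100, seed = 41)
    fitSB <- do.call(gibbsFit, c(args, variant = "SB"))
    fitMB <- do.call(gibbsFit, c(args, variant = "MB"))
    expect_identical(fitSB@theta, fitMB@theta)
    expect_identical(fitSB@sigma2, fitMB@sigma2)
    expect_identical(fitSB@logLik, fitMB@logLik)
})

test_that("pooling the variance cannot beat the richer model's likelihood", {
    set.seed(42)
    r <- c(rnorm(200, -0.5, 0.05), rnorm(200, 0.3, 0.3))
    argsCommon <- list(r = r, k = 2, nStarts = 3, startBurnin = 50,
                       nBurnin = 100, nIter = 300, seed = 43)
    fitMB <- do.call(gibbsFit, c(argsCommon, variant = "SB"))
    fitMBP <- do.call(gibbsFit, c(argsCommon, variant = "SBP"))
    expect_lte(max(fitMBP@logLik), max(fitMB@logLik) + 1)
})

test_that("homozygous deletion augmentation follows its contract", {
    r <- c(rnorm(50, 0, 0.1), -3.1, -2.9, -3.0)
    batch <- c(rep(1L, 30), rep(2L, 23))
    # batch 2 holds the deletions; batch 1 lacks them
    r <- c(rnorm(30, 0, 0.1), rnorm(20, 0, 0.1), -3.1, -2.9, -3.0)
    aug <- augmentHomozygous(r, batch, seed = 44)
    expect_equal(sum(aug$isAugmented), 10)
    expect_true(all(aug$batch[aug$isAugmented] == 1L))
    expect_true(all(aug$r[aug$isAugmented] < -1))
    # all batches already covered: no-op
    r2 <- c(-3, rnorm(20), -3, rnorm(20))
    b2 <- rep(1:2, each = 21)
    aug2 <- augmentHomozygous(r2, b2)
    expect_identical(aug2$r, r2)
    # no deletions anywhere: no-op
    aug3 <- augmentHomozygous(rnorm(30), rep(1:2, 15))
    expect_false(any(aug3$isAugmented))
})

test_that("augmentation leaves non-augmented posterior probabilities intact", {
    set.seed(45)
    n <- 400
    batch <- rep(1:2, each = n / 2)
    cn <- sample(0:2, n, TRUE, c(0.004, 0.25, 0.746))
    r <- rnorm(n, c(-3, -0.5, 0)[cn + 1], 0.1)
    # force all homozygous deletions into batch 1
    del <- which(cn == 0)
    batch[del] <- 1L
    aug <- augmentHomozygous(r, batch, seed = 46)
    fitAug <- gibbsFit(aug$r, aug$batch, variant = "MB", k = 3,
                       isAugmented = aug$isAugmented, nStarts = 3,
                       startBurnin = 50, nBurnin = 150, nIter = 400,
                       seed = 47)
    # the comparison model drops the rare deletions and the component
    # dedicated to them
    keepIdx <- setdiff(seq_along(r), del)
    fitNo <- gibbsFit(r[keepIdx], batch[keepIdx], variant = "MB", k = 2,
                      nStarts = 3, startBurnin = 50, nBurnin = 150,
                      nIter = 400, seed = 47)
    pA <- alignedProbz(fitAug)[!fitAug@isAugmented, ][keepIdx, 2:3]
    pN <- alignedProbz(fitNo)
    conc <- cor(as.vector(pA), as.vector(pN))
    expect_gt(conc, 0.99)
})

test_that("label switching diagnostics flag constructed switches", {
    set.seed(48)
    r <- c(rnorm(150, -1, 0.15), rnorm(150, 1, 0.15))
    fit <- gibbsFit(r, variant = "SB", k = 2, nStarts = 2,
                    startBurnin = 50, nBurnin = 100, nIter = 400, seed = 49)
    expect_false(detectLabelSwitching(fit, window = 100)$flagged)
    # synthetically permute the components at the midpoint
    swapped <- fit
    half <- 201:400
    swapped@theta[half, ] <- fit@theta[half, c(2, 1)]
    swapped@mu[half, ] <- fit@mu[half, c(2, 1)]
    expect_true(detectLabelSwitching(swapped, window = 100)$flagged)
    expect_error(detectLabelSwitching(fit, window = 500), "two windows")
})

test_that("overfitted models are flagged in most replicates", {
    flagged <- vapply(1:6, function(s) {
        set.seed(500 + s)
        r <- c(rnorm(100, -1, 0.15), rnorm(100, 1, 0.15))
        fit <- gibbsFit(r, variant = "SB", k = 4, nStarts = 2,
                        startBurnin = 50, nBurnin = 100, nIter = 300,
                        seed = 600 + s)
        detectLabelSwitching(fit, window = 75)$flagged
    }, logical(1))
    expect_gte(mean(flagged), 0.5)
})

test_that("stationarity: restart from a posterior draw stays stationary", {
    set.seed(50)
    r <- rnorm(300, 0.1, 0.15)
    fit <- gibbsFit(r, variant = "SB", k = 1, nStarts = 2,
                    startBurnin = 50, nBurnin = 300, nIter = 800, seed = 51)
    th <- fit@theta[, 1]
    # Geweke-style z-score between the first and last thirds
    n3 <- length(th) %/% 3
    a <- th[seq_len(n3)]; b <- th[(length(th) - n3 + 1):length(th)]
    z <- (mean(a) - mean(b)) /
        sqrt(batchMeansSe(a)^2 + batchMeansSe(b)^2)
    expect_lt(abs(z), 3)
})
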