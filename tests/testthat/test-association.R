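simAssocData <- function(n, orPerCopy, seed, q = 0.3) {
    set.seed(seed)
    cn <- sample(0:2, n, TRUE, c(q^2, 2 * q * (1 - q), (1 - q)^2))
    age <- rnorm(n)
    male <- rbinom(n, 1, 0.5)
    eta <- -0.2 + 0.1 * age + 0.05 * male + log(orPerCopy) * cn
    y <- rbinom(n, 1, plogis(eta))
    prob <- matrix(0, n, 5)
    prob[cbind(seq_len(n), cn + 1)] <- 1
    list(y = y, cov = data.frame(age = age, male = male), cn = cn,
         prob = prob)
}

test_that("posterior mode agrees with the maximum likelihood oracle", {
    d <- simAssocData(2000, orPerCopy = 1.4, seed = 100)
    fit <- fitAssociation(d$y, d$cov, cnProb = d$prob, stratified = FALSE,
                          nIter = 2500, nBurnin = 800, thin = 5,
                          seed = 101, fixZ = 1)
    ml <- glm(d$y ~ d$cov$age + d$cov$male + d$cn, family = binomial)
    mlCoef <- coef(ml)[["d$cn"]]
    mlSe <- summary(ml)$coefficients["d$cn", 2]
    postMean <- mean(fit@beta[, "cn"])
    postSd <- sd(fit@beta[, "cn"])
    expect_lt(abs(postMean - mlCoef), 2 * max(postSd, mlSe))
    # other coefficients too
    for (nm in c("age", "male")) {
        expect_lt(abs(mean(fit@beta[, nm]) - coef(ml)[[paste0("d$cov$", nm)]]),
                  3 * max(sd(fit@beta[, nm]), 0.05))
    }
})

test_that("true odds ratio is covered by the 90 percent credible interval", {
    hits <- vapply(1:8, function(s) {
        d <- simAssocData(2500, orPerCopy = 1.2, seed = 200 + s)
        fit <- fitAssociation(d$y, d$cov, cnProb = d$prob,
                              stratified = FALSE, nIter = 2000,
                              nBurnin = 600, thin = 4, seed = 300 + s,
                              fixZ = 1)
        ci <- quantile(fit@beta[, "cn"], c(0.05, 0.95))
        ci[1] <= log(1.2) && log(1.2) <= ci[2]
    }, logical(1))
    expect_gte(mean(hits), 0.85 - 1e-9)
})

test_that("null simulations keep the spike indicator at or below its prior", {
    zbar <- vapply(1:5, function(s) {
        d <- simAssocData(1500, orPerCopy = 1.0, seed = 400 + s)
        fit <- fitAssociation(d$y, d$cov, cnProb = d$prob,
                              stratified = FALSE, nIter = 1500,
                              nBurnin = 500, thin = 3, seed = 500 + s)
        mean(fit@z)
    }, numeric(1))
    expect_lte(mean(zbar), 0.5)
})

test_that("a strong effect drives the spike posterior towards one", {
    d <- simAssocData(2500, orPerCopy = 1.5, seed = 110)
    fit <- fitAssociation(d$y, d$cov, cnProb = d$prob, stratified = FALSE,
                          nIter = 2000, nBurnin = 600, thin = 4,
                          seed = 111)
    expect_gt(mean(fit@z), 0.8)
})

test_that("with the spike off, slab coefficients are prior draws", {
    d <- simAssocData(800, orPerCopy = 1.6, seed = 120)
    fit <- fitAssociation(d$y, d$cov, cnProb = d$prob, stratified = FALSE,
                          nIter = 4000, nBurnin = 200, thin = 2,
                          seed = 121, fixZ = 0)
    draws <- fit@beta[, "cn"]
    # Cauchy(0, 2.5): compare quartiles (moments do not exist)
    expect_lt(abs(median(draws)), 0.5)
    iqr <- diff(quantile(draws, c(0.25, 0.75)))
    expect_gt(iqr, 2.5)   # Cauchy IQR = 2 * scale = 5, allow sampling slack
    expect_lt(iqr, 12)
})

test_that("copy number uncertainty widens the credible interval", {
    d <- simAssocData(2000, orPerCopy = 1.3, seed = 130)
    fitExact <- fitAssociation(d$y, d$cov, cnProb = d$prob,
                               stratified = FALSE, nIter = 1500,
                               nBurnin = 500, thin = 3, seed = 131,
                               fixZ = 1)
    noisy <- 0.6 * d$prob + 0.4 * matrix(rep(colMeans(d$prob), each = 2000),
                                         2000, 5)
    fitNoisy <- fitAssociation(d$y, d$cov, cnProb = noisy,
                               stratified = FALSE, nIter = 1500,
                               nBurnin = 500, thin = 3, seed = 131,
                               fixZ = 1)
    wExact <- diff(quantile(fitExact@beta[, "cn"], c(0.05, 0.95)))
    wNoisy <- diff(quantile(fitNoisy@beta[, "cn"], c(0.05, 0.95)))
    expect_gt(wNoisy, wExact)
})

test_that("association fits are reproducible under a fixed seed", {
    d <- simAssocData(500, orPerCopy = 1.2, seed = 140)
    f1 <- fitAssociation(d$y, d$cov, cnProb = d$prob, stratified = FALSE,
                         nIter = 500, nBurnin = 100, thin = 2, seed = 141)
    f2 <- fitAssociation(d$y, d$cov, cnProb = d$prob, stratified = FALSE,
                         nIter = 500, nBurnin = 100, thin = 2, seed = 141)
    expect_identical(f1@beta, f2@beta)
    expect_identical(f1@z, f2@z)
})

test_that("summaries report odds ratios, intervals and the spike mean", {
    fit <- new("AssociationFit",
               beta = matrix(log(1.2), 4, 1,
                             dimnames = list(NULL, "cn")),
               z = c(1, 0, 1, 1), copyDraws = matrix(0, 0, 0),
               stratified = FALSE, accept = c(cn = 0.4))
    s <- summarizeAssociation(fit, slabOnly = FALSE)
    expect_equal(s$postZ, 0.75)
    row <- s$table[s$table$coefficient == "cn", ]
    expect_equal(row$or, 1.2, tolerance = 1e-12)
    expect_equal(row$ci_lo, 1.2, tolerance = 1e-12)
    expect_equal(row$ci_hi, 1.2, tolerance = 1e-12)
})

test_that("shared effects across strata give high sign concordance", {
    set.seed(150)
    n <- 2000
    cn <- sample(0:2, n, TRUE, c(0.09, 0.42, 0.49))
    hq <- rbinom(n, 1, 0.5)
    eta <- -0.1 + 0.4 * cn           # same direction in both strata
    y <- rbinom(n, 1, plogis(eta))
    prob <- matrix(0, n, 5); prob[cbind(seq_len(n), cn + 1)] <- 1
    fit <- fitAssociation(y, NULL, highQuality = hq == 1, cnProb = prob,
                          stratified = TRUE, nIter = 2000, nBurnin = 600,
                          thin = 4, seed = 151, fixZ = 1)
    s <- summarizeAssociation(fit)
    expect_gt(s$signConcordance, 0.9)
})
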