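# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: quadrature and closed forms here, samplers there.

# Exact posterior moments and evidence for the one-component model
#   r_i ~ N(theta, 1/lambda),  theta ~ N(m0, t20),
#   lambda ~ Gamma(nu0/2, rate = nu0*s02/2)
# theta is integrated analytically (compound-symmetric Gaussian marginal);
# lambda by deterministic quadrature on a fine grid.
conjugateOracle <- function(r, m0, t20, nu0, s02, nGrid = 20000) {
    n <- length(r)
    e <- r - m0
    sse <- sum(e^2); se <- sum(e)
    logMarg <- function(lam) {
        # log N(r | m0*1, (1/lam) I + t20 J) via Woodbury
        logdet <- (n - 1) * log(1 / lam) + log(1 / lam + n * t20)
        Q <- lam * sse - lam^2 * t20 * se^2 / (1 + n * t20 * lam)
        -n / 2 * log(2 * pi) - 0.5 * logdet - 0.5 * Q
    }
    logf <- function(lam) {
        stats::dgamma(lam, nu0 / 2, rate = nu0 * s02 / 2, log = TRUE) +
            logMarg(lam)
    }
    # locate the mode, then integrate on a generous grid around it
    opt <- stats::optimize(logf, c(1e-6, 1e6), maximum = TRUE)
    lamMode <- opt$maximum
    lams <- exp(seq(log(lamMode) - 12, log(lamMode) + 12,
                    length.out = nGrid))
    lf <- vapply(lams, logf, numeric(1))
    m <- max(lf)
    w <- exp(lf - m)
    dlam <- diff(lams)
    trap <- sum((w[-1] + w[-nGrid]) / 2 * dlam)
    logEvidence <- m + log(trap)
    # posterior over lambda on the grid (trapezoid weights)
    wt <- w * c(dlam[1] / 2, (dlam[-1] + dlam[-(nGrid - 1)]) / 2,
                dlam[nGrid - 1] / 2)
    wt <- wt / sum(wt)
    condPrec <- lams * n + 1 / t20
    condMean <- (lams * sum(r) + m0 / t20) / condPrec
    eTheta <- sum(wt * condMean)
    vTheta <- sum(wt * (1 / condPrec + condMean^2)) - eTheta^2
    eSigma2 <- sum(wt * (1 / lams))
    list(logEvidence = logEvidence, eTheta = eTheta, vTheta = vTheta,
         eSigma2 = eSigma2)
}

# generic Pearson chi-square on observed vs expected counts
pearsonChisq <- function(obs, expected) sum((obs - expected)^2 / expected)

# rank-based AUC (equivalent to trapezoidal ROC integration)
rankAuc <- function(score, positive) {
    rk <- rank(score)
    n1 <- sum(positive); n0 <- sum(!positive)
    (sum(rk[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# two-sample eCDF supremum distance by direct enumeration
ecdfSup <- function(a, b) {
    xs <- sort(unique(c(a, b)))
    Fa <- vapply(xs, function(x) mean(a <= x), numeric(1))
    Fb <- vapply(xs, function(x) mean(b <= x), numeric(1))
    max(abs(Fa - Fb))
}

# Monte-Carlo standard error of a chain mean via the package-independent
# batch-means estimator
batchMeansSe <- function(x, nb = 20) {
    n <- length(x)
    m <- n %/% nb
    bm <- vapply(seq_len(nb), function(i) mean(x[((i - 1) * m + 1):(i * m)]),
                 numeric(1))
    stats::sd(bm) / sqrt(nb)
}

# small simulated region experiment shared by io/preprocess tests
makeToyExperiment <- function(nProbes = 60, nSamples = 20, seed = 1) {
    set.seed(seed)
    probes <- data.frame(
        probe_id = sprintf("p%03d", seq_len(nProbes)),
        chrom = "chr1",
        pos = sort(sample.int(1e6, nProbes)),
        gc = runif(nProbes, 0.3, 0.7),
        is_snp = rep(c(TRUE, FALSE), length.out = nProbes))
    samples <- data.frame(
        sample_id = sprintf("s%02d", seq_len(nSamples)),
        plate = rep(c("pA", "pB"), length.out = nSamples),
        site = "site1", high_quality = TRUE,
        stringsAsFactors = FALSE)
    lrr <- matrix(rnorm(nProbes * nSamples, 0, 0.2), nProbes, nSamples)
    baf <- matrix(NA_real_, nProbes, nSamples)
    baf[probes$is_snp, ] <- sample(c(0.01, 0.5, 0.99),
                                   sum(probes$is_snp) * nSamples, TRUE)
    CNPExperiment(lrr, baf, probes, samples)
}
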