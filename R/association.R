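#' @include AllClasses.R
NULL

#' Bayesian logistic regression of disease on latent copy number
#'
#' Fits, by Markov chain Monte Carlo, the case-control model
#' \deqn{logit P(y_i = 1) = \beta_0 + \beta_1 age_i + \beta_2 male_i +
#'   \beta_3 PC1_i + \beta_4 PC2_i + \beta_5 PC3_i + \beta_6 I_{hq,i} +
#'   z (\beta_7 C_i + \beta_8 C_i I_{hq,i})}
#' where the integer copy number \eqn{C_i} is latent, sampled each scan from
#' a multinomial with weights given by the per-sample copy number posterior
#' probabilities times the Bernoulli likelihood; \eqn{z} is a spike indicator
#' with a Bernoulli(0.5) prior whose posterior mean estimates the probability
#' of association; and each coefficient has a Cauchy(0, 2.5) prior.
#' Coefficients are updated one at a time by random-walk Metropolis with step
#' sizes adapted during burn-in (frozen afterwards); when \eqn{z = 0} the
#' slab coefficients are refreshed from their priors, which is their exact
#' conditional. The unstratified variant drops the quality main effect and
#' interaction. Continuous covariates should be supplied mean-centred.
#'
#' @param y logical/0-1 case status.
#' @param covariates data.frame (or NULL) of covariate columns such as
#'   \code{age}, \code{male}, \code{pc1}, \code{pc2}, \code{pc3}; used as
#'   given.
#' @param highQuality logical quality stratum per sample (required when
#'   \code{stratified}).
#' @param cnProb matrix (n x 5) of copy number probabilities \code{cn0..cn4}
#'   per sample.
#' @param stratified include quality main effect and copy-quality
#'   interaction (default TRUE).
#' @param nIter total MCMC iterations after burn-in (default 5000).
#' @param nBurnin burn-in iterations (default 1000).
#' @param thin thinning interval (default 25).
#' @param seed integer seed.
#' @param priorScale Cauchy prior scale (default 2.5).
#' @param fixZ optionally fix the spike indicator at 0 or 1 (NULL samples
#'   it).
#' @return An \linkS4class{AssociationFit}.
#' @export
fitAssociation <- function(y, covariates = NULL, highQuality = NULL,
                           cnProb, nIter = 5000L, nBurnin = 1000L,
                           thin = 25L, seed = 1L, stratified = TRUE,
                           priorScale = 2.5, fixZ = NULL) {
    y <- as.numeric(y)
    n <- length(y)
    cnProb <- as.matrix(cnProb)
    stopifnot(nrow(cnProb) == n, ncol(cnProb) == 5L)
    if (stratified && is.null(highQuality))
        stop("highQuality required for the stratified model")
    X <- cbind(intercept = rep(1, n))
    if (!is.null(covariates))
        X <- cbind(X, as.matrix(covariates))
    if (stratified)
        X <- cbind(X, hq = as.numeric(highQuality))
    p <- ncol(X)
    slabNames <- if (stratified) c("cn", "cn_hq") else "cn"
    nSlab <- length(slabNames)
    hq <- if (stratified) as.numeric(highQuality) else numeric(n)

    maxp <- apply(cnProb, 1, max)
    noVar <- all(max.col(cnProb) == max.col(cnProb)[1]) &&
        all(maxp > 1 - 1e-12)
    if (noVar)
        warning("no copy number variation in cnProb; the spike posterior ",
                "will track its prior")
    # with degenerate probabilities the latent copy number is a point mass
    # and its update can be skipped entirely
    degenerate <- all(maxp > 1 - 1e-12)

    set.seed(seed)
    beta <- rep(0, p)
    slab <- rep(0, nSlab)
    z <- if (is.null(fixZ)) 1 else fixZ
    C <- max.col(cnProb, ties.method = "first") - 1
    cnVals <- 0:4
    active <- which(colSums(cnProb) > 0)
    logPi <- log(pmax(cnProb[, active, drop = FALSE], 1e-300))
    sgn <- 2 * y - 1

    etaBase <- as.vector(X %*% beta)
    slabTerm <- function(Cv, slab) {
        if (nSlab == 2) slab[1] * Cv + slab[2] * Cv * hq else slab[1] * Cv
    }
    # Bernoulli log likelihood, stable for large |eta|
    logLikEta <- function(eta) sum(stats::plogis(sgn * eta, log.p = TRUE))

    step <- rep(0.1, p + nSlab)
    acc <- rep(0, p + nSlab)
    tries <- rep(0, p + nSlab)

    nKeep <- as.integer(nIter / thin)
    betaC <- matrix(NA_real_, nKeep, p + nSlab,
                    dimnames = list(NULL, c(colnames(X), slabNames)))
    zC <- numeric(nKeep)
    cDrawC <- matrix(NA_integer_, 0, 0)
    kept <- 0L

    total <- nBurnin + nIter
    for (it in seq_len(total)) {
        # C_i | rest: multinomial over copy numbers
        if (!degenerate) {
            nA <- length(active)
            etaC <- matrix(etaBase, n, nA)
            if (z == 1)
                for (j in seq_len(nA))
                    etaC[, j] <- etaBase + slabTerm(cnVals[active[j]], slab)
            w <- logPi +
                if (z == 1) stats::plogis(sgn * etaC, log.p = TRUE) else 0
            gum <- -log(-log(matrix(stats::runif(n * nA), n)))
            C <- cnVals[active][max.col(w + gum, ties.method = "first")]
        }

        etaSlab <- slabTerm(C, slab)

        # z | rest: Bernoulli from the likelihood ratio slab vs null
        if (is.null(fixZ)) {
            ll1 <- logLikEta(etaBase + etaSlab)
            ll0 <- logLikEta(etaBase)
            pz1 <- 1 / (1 + exp(ll0 - ll1))
            z <- as.numeric(stats::runif(1) < pz1)
        }

        # beta | rest: one-at-a-time random-walk Metropolis
        etaAdd <- if (z == 1) etaSlab else numeric(n)
        curLL <- logLikEta(etaBase + etaAdd)
        for (j in seq_len(p)) {
            tries[j] <- tries[j] + 1
            prop <- beta[j] + stats::rnorm(1, 0, step[j])
            etaProp <- etaBase + X[, j] * (prop - beta[j])
            propLL <- logLikEta(etaProp + etaAdd)
            lr <- propLL - curLL +
                stats::dcauchy(prop, 0, priorScale, log = TRUE) -
                stats::dcauchy(beta[j], 0, priorScale, log = TRUE)
            if (log(stats::runif(1)) < lr) {
                beta[j] <- prop
                etaBase <- etaProp
                curLL <- propLL
                acc[j] <- acc[j] + 1
            }
        }
        # slab coefficients
        for (s in seq_len(nSlab)) {
            jj <- p + s
            if (z == 0) {
                # conditional is the prior when the spike is off
                slab[s] <- stats::rcauchy(1, 0, priorScale)
                next
            }
            tries[jj] <- tries[jj] + 1
            prop <- slab
            prop[s] <- slab[s] + stats::rnorm(1, 0, step[jj])
            etaPropAdd <- slabTerm(C, prop)
            propLL <- logLikEta(etaBase + etaPropAdd)
            lr <- propLL - curLL +
                stats::dcauchy(prop[s], 0, priorScale, log = TRUE) -
                stats::dcauchy(slab[s], 0, priorScale, log = TRUE)
            if (log(stats::runif(1)) < lr) {
                slab <- prop
                etaSlab <- etaPropAdd
                curLL <- propLL
                acc[jj] <- acc[jj] + 1
            }
        }

        # adapt proposal steps during burn-in only
        if (it <= nBurnin && it %% 50 == 0) {
            rate <- ifelse(tries > 0, acc / tries, 0.44)
            step <- step * exp(rate - 0.44)
            acc[] <- 0; tries[] <- 0
        }
        if (it > nBurnin && (it - nBurnin) %% thin == 0L) {
            kept <- kept + 1L
            betaC[kept, ] <- c(beta, slab)
            zC[kept] <- z
        }
    }
    rate <- ifelse(tries > 0, acc / tries, NA_real_)
    names(rate) <- colnames(betaC)
    new("AssociationFit", beta = betaC[seq_len(kept), , drop = FALSE],
        z = zC[seq_len(kept)], copyDraws = cDrawC,
        stratified = stratified, accept = rate)
}

#' Summarise an association fit
#'
#' Posterior means and equal-tailed credible intervals on the odds-ratio
#' scale for each coefficient, the posterior mean of the spike indicator,
#' and (for stratified fits) the sign concordance of the low- and
#' high-quality copy number slopes across draws.
#'
#' @param fit an \linkS4class{AssociationFit}.
#' @param level credible level (default 0.90).
#' @param slabOnly restrict the odds-ratio table to draws with z = 1
#'   (default TRUE; with no such draws, all draws are used).
#' @return list with \code{table} (data.frame: coefficient, estimate, or,
#'   ci_lo, ci_hi), \code{postZ}, and \code{signConcordance} (NA when
#'   unstratified).
#' @export
summarizeAssociation <- function(fit, level = 0.90, slabOnly = TRUE) {
    draws <- fit@beta
    use <- if (slabOnly && any(fit@z == 1) && length(fit@z) == nrow(draws))
        fit@z == 1 else rep(TRUE, nrow(draws))
    a <- (1 - level) / 2
    est <- colMeans(draws[use, , drop = FALSE])
    qs <- apply(draws[use, , drop = FALSE], 2, stats::quantile,
                probs = c(a, 1 - a), names = FALSE)
    tab <- data.frame(coefficient = colnames(draws),
                      estimate = unname(est),
                      or = exp(unname(est)),
                      ci_lo = exp(qs[1, ]),
                      ci_hi = exp(qs[2, ]),
                      row.names = NULL)
    sc <- NA_real_
    if (fit@stratified && all(c("cn", "cn_hq") %in% colnames(draws))) {
        lo <- draws[use, "cn"]
        hi <- draws[use, "cn"] + draws[use, "cn_hq"]
        sc <- mean(sign(lo) == sign(hi))
    }
    list(table = tab, postZ = mean(fit@z), signConcordance = sc)
}
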