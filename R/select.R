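#' @include AllClasses.R mixture.R
NULL

#' Comparison of mixture model variants at one region
#'
#' @slot table data.frame with one row per fitted model (variant, K, final
#'   log likelihood, marginal likelihood when computed, selection flag).
#' @slot selectedVariant,selectedK the chosen model.
#' @slot escalated logical: whether multi-batch models were evaluated.
#' @export
setClass("ModelComparison",
    representation(table = "data.frame", selectedVariant = "character",
                   selectedK = "integer", escalated = "logical"))

setMethod("show", "ModelComparison", function(object) {
    cat("ModelComparison:", nrow(object@table), "model(s); selected",
        object@selectedVariant, "K =", object@selectedK,
        if (object@escalated) "(escalated to multi-batch)" else "", "\n")
    print(object@table, row.names = FALSE)
})

#' Escalation rule for multi-batch models
#'
#' Multi-batch models are only evaluated when more than \code{fracCut} of
#' the samples have a maximum component probability below \code{probCut}
#' in the better single-batch model. Augmented pseudo-observations are
#' excluded from the fraction.
#'
#' @param fit a single-batch \linkS4class{MixtureFit}.
#' @param probCut posterior probability cut (default 0.99).
#' @param fracCut fraction cut (default 0.02).
#' @return logical(1).
#' @export
shouldEscalate <- function(fit, probCut = 0.99, fracCut = 0.02) {
    maxp <- apply(probz(fit), 1, max)[!fit@isAugmented]
    mean(maxp < probCut) > fracCut
}

#' Candidate component numbers for a region
#'
#' When apparent homozygous deletions are present (any summary below
#' \code{detectionThreshold}) only 3- and 4-component models are considered;
#' otherwise 1-4 components.
#'
#' @param r numeric summaries.
#' @param detectionThreshold default -1.
#' @return integer vector of K values.
#' @export
candidateK <- function(r, detectionThreshold = -1) {
    r <- r[is.finite(r)]
    if (!length(r)) stop("no data values supplied")
    if (min(r) < detectionThreshold) c(3L, 4L) else 1:4
}

#' Gate for computing marginal likelihoods
#'
#' Marginal likelihoods are only computed when the difference of simple
#' post-hoc summaries -- the log likelihood at the last iteration -- is
#' small.
#'
#' @param loglikA,loglikB final log likelihoods of the two fits.
#' @param gate threshold (default 10).
#' @return logical(1): TRUE when \code{abs(loglikA - loglikB) < gate}.
#' @export
gateMarginalLikelihood <- function(loglikA, loglikB, gate = 10) {
    abs(loglikA - loglikB) < gate
}

# relabel retained draws by ascending component location (batch-averaged
# theta); returns list of relabeled chains
relabelChains <- function(fit) {
    K <- fit@k; B <- fit@nBatch
    theta <- fit@theta; sigma2 <- fit@sigma2; pimat <- fit@pi
    mu <- fit@mu; tau2 <- fit@tau2
    for (t in seq_len(nrow(mu))) {
        ord <- order(rowMeans(matrix(theta[t, ], K, B)))
        if (identical(ord, seq_len(K))) next
        mu[t, ] <- mu[t, ord]
        tau2[t, ] <- tau2[t, ord]
        for (b in seq_len(B)) {
            cols <- (b - 1L) * K + seq_len(K)
            theta[t, cols] <- theta[t, cols][ord]
            pimat[t, cols] <- pimat[t, cols][ord]
            if (!fit@variant %in% c("SBP", "MBP"))
                sigma2[t, cols] <- sigma2[t, cols][ord]
        }
    }
    list(theta = theta, sigma2 = sigma2, pi = pimat, mu = mu, tau2 = tau2)
}

logMeanExp <- function(x) {
    m <- max(x)
    m + log(mean(exp(x - m)))
}

ldirichlet <- function(x, alpha) {
    a <- rep_len(alpha, length(x))
    lgamma(sum(a)) - sum(lgamma(a)) + sum((a - 1) * log(pmax(x, 1e-300)))
}

# conditional log density of theta* given the current state (z, U, sigma2,
# mu, tau2); mirrors the theta update in gibbsScan
condLogDensTheta <- function(st, r, batch, K, B, thetaStar) {
    KB <- K * B
    idx <- groupIndex(st$z, batch, K)
    sU <- groupSums(st$U, idx, KB)
    sUr <- groupSums(st$U * r, idx, KB)
    tau2v <- rep(st$tau2, times = B)
    muv <- rep(st$mu, times = B)
    prec <- sU / as.vector(st$sigma2) + 1 / tau2v
    mean_ <- (sUr / as.vector(st$sigma2) + muv / tau2v) / prec
    sum(stats::dnorm(as.vector(thetaStar), mean_, sqrt(1 / prec), log = TRUE))
}

# conditional log density of the precisions sigma2tilde* given theta*, z, U,
# nu0, sigma02
condLogDensPrec <- function(st, r, batch, K, B, pooled, thetaStar, precStar) {
    KB <- K * B
    idx <- groupIndex(st$z, batch, K)
    ss <- groupSums(st$U * (r - thetaStar[cbind(st$z, batch)])^2, idx, KB)
    cnt <- groupSums(rep(1, length(r)), idx, KB)
    if (pooled) {
        ss <- colSums(matrix(ss, K, B))
        cnt <- colSums(matrix(cnt, K, B))
    }
    sum(stats::dgamma(precStar, (st$nu0 + cnt) / 2,
                      rate = (st$nu0 * st$sigma02 + ss) / 2, log = TRUE))
}

condLogDensPi <- function(st, batch, K, B, alpha, piStar) {
    idx <- groupIndex(st$z, batch, K)
    cnt <- matrix(groupSums(rep(1, length(st$z)), idx, K * B), K, B)
    sum(vapply(seq_len(B), function(b)
        ldirichlet(piStar[b, ], alpha + cnt[, b]), numeric(1)))
}

condLogDensMu <- function(st, hp, K, B, thetaStar, muStar) {
    precMu <- B / st$tau2 + 1 / hp@tau20
    meanMu <- (rowSums(thetaStar) / st$tau2 + hp@mu0 / hp@tau20) / precMu
    sum(stats::dnorm(muStar, meanMu, sqrt(1 / precMu), log = TRUE))
}

# conditional log pmf of nu0* given the precisions and sigma02
condLogDensNu0 <- function(precStar, sigma02, nu0Star, beta, nuMax) {
    grid <- seq_len(nuMax)
    nPrec <- length(precStar)
    lp <- (grid - 1) * log(1 - beta) +
        nPrec * ((grid / 2) * log(grid * sigma02 / 2) - lgamma(grid / 2)) +
        (grid / 2 - 1) * sum(log(precStar)) -
        (grid * sigma02 / 2) * sum(precStar)
    lp <- lp - max(lp)
    log(exp(lp[nu0Star]) / sum(exp(lp)))
}

#' Chib's marginal likelihood for a mixture fit
#'
#' Estimates the log marginal likelihood via the identity
#' log m(r) = log p(r | psi*) + log p(psi*) - log p(psi* | r), evaluated at a
#' high-density point psi* (the posterior mean after relabeling every
#' retained draw by ascending mu_h). The posterior ordinate is decomposed
#' into block ordinates (theta, precisions, pi, mu, tau2, sigma02, nu0) in a
#' fixed order, each estimated by Rao-Blackwellised averaging over a reduced
#' Gibbs run in which the preceding blocks are held at their starred values;
#' ordinates whose full conditionals are free of latent data (tau2, nu0) are
#' evaluated exactly. Fits flagged for label switching are refused, as the
#' ordinate is then undefined.
#'
#' @param fit a converged \linkS4class{MixtureFit}.
#' @param nReducedIter,nReducedBurnin reduced-run schedule (defaults 200,
#'   50).
#' @param seed integer seed (results are deterministic given the seed).
#' @param fixU,fixedHypers must match the options used in \code{gibbsFit}.
#' @return log marginal likelihood (numeric scalar) with attribute
#'   \code{"ordinates"}.
#' @export
chibMarginalLikelihood <- function(fit, nReducedIter = 200L,
                                   nReducedBurnin = 50L, seed = 1L,
                                   fixU = FALSE, fixedHypers = list()) {
    ls <- detectLabelSwitching(fit)
    if (ls$flagged)
        stop("label switching detected; marginal likelihood ordinate is ",
             "undefined for this fit")
    hp <- fit@hypers
    K <- fit@k; B <- fit@nBatch
    pooled <- fit@variant %in% c("SBP", "MBP")
    r <- fit@data; batch <- fit@batch
    dEff <- if (fixU) Inf else hp@d

    rl <- relabelChains(fit)
    thetaStar <- matrix(colMeans(rl$theta), K, B)
    precDraws <- 1 / rl$sigma2
    precStar <- if (pooled) colMeans(precDraws)[seq(1, K * B, by = K)]
        else colMeans(precDraws)
    sigma2Star <- if (pooled) matrix(1 / precStar, K, B, byrow = TRUE)
        else matrix(1 / precStar, K, B)
    piStar <- matrix(colMeans(rl$pi), K, B)
    piStar <- t(piStar / rep(colSums(piStar), each = K))  # B x K
    muStar <- colMeans(rl$mu)
    tau2Star <- 1 / colMeans(1 / rl$tau2)
    sigma02Star <- mean(fit@sigma02)
    nu0Star <- as.integer(names(which.max(table(fit@nu0))))

    # likelihood and prior at psi*
    logLikStar <- mixLogLik(r, batch, thetaStar, sigma2Star, piStar, dEff)
    logPrior <- sum(stats::dnorm(as.vector(thetaStar),
                                 rep(muStar, times = B),
                                 rep(sqrt(tau2Star), times = B),
                                 log = TRUE)) +
        sum(stats::dgamma(precStar, nu0Star / 2,
                          rate = nu0Star * sigma02Star / 2, log = TRUE))
    if (K > 1)
        logPrior <- logPrior + sum(vapply(seq_len(B), function(b)
            ldirichlet(piStar[b, ], rep(hp@alpha, K)), numeric(1)))
    if (is.null(fixedHypers$mu))
        logPrior <- logPrior +
            sum(stats::dnorm(muStar, hp@mu0, sqrt(hp@tau20), log = TRUE))
    if (is.null(fixedHypers$tau2))
        logPrior <- logPrior +
            sum(stats::dgamma(1 / tau2Star, hp@eta0 / 2,
                              rate = hp@eta0 * hp@m20 / 2, log = TRUE))
    if (is.null(fixedHypers$sigma02))
        logPrior <- logPrior +
            stats::dgamma(sigma02Star, hp@a0, rate = hp@b0, log = TRUE)
    if (is.null(fixedHypers$nu0)) {
        # geometric prior truncated to 1..nuMax
        lp <- (seq_len(hp@nuMax) - 1) * log(1 - hp@beta) + log(hp@beta)
        logPrior <- logPrior + lp[nu0Star] - log(sum(exp(lp)))
    }

    set.seed(seed)
    starState <- function() {
        list(theta = thetaStar, sigma2 = sigma2Star, pi = piStar,
             mu = muStar, tau2 = tau2Star, nu0 = nu0Star,
             sigma02 = sigma02Star, prec = precStar,
             U = rep(1, length(r)),
             z = sample.int(K, length(r), replace = TRUE))
    }
    runReduced <- function(freeze, collect) {
        st <- starState()
        for (it in seq_len(nReducedBurnin))
            st <- gibbsScan(st, r, batch, K, B, hp, pooled, fixedHypers,
                            fixU, freeze)
        vals <- numeric(nReducedIter)
        for (it in seq_len(nReducedIter)) {
            st <- gibbsScan(st, r, batch, K, B, hp, pooled, fixedHypers,
                            fixU, freeze)
            vals[it] <- collect(st)
        }
        logMeanExp(vals)
    }

    ordinates <- c(theta = runReduced(character(0), function(st)
        condLogDensTheta(st, r, batch, K, B, thetaStar)))
    ordinates["prec"] <- runReduced("theta", function(st)
        condLogDensPrec(st, r, batch, K, B, pooled, thetaStar, precStar))
    if (K > 1)
        ordinates["pi"] <- runReduced(c("theta", "sigma2"), function(st)
            condLogDensPi(st, batch, K, B, hp@alpha, piStar))
    if (is.null(fixedHypers$mu))
        ordinates["mu"] <- runReduced(c("theta", "sigma2", "pi"),
            function(st) condLogDensMu(st, hp, K, B, thetaStar, muStar))
    if (is.null(fixedHypers$tau2)) {
        devs <- rowSums((thetaStar - muStar)^2)
        ordinates["tau2"] <- sum(stats::dgamma(1 / tau2Star,
            (hp@eta0 + B) / 2, rate = (hp@eta0 * hp@m20 + devs) / 2,
            log = TRUE))
    }
    if (is.null(fixedHypers$sigma02))
        ordinates["sigma02"] <- runReduced(
            c("theta", "sigma2", "pi", "mu", "tau2"),
            function(st) stats::dgamma(sigma02Star,
                hp@a0 + length(precStar) * st$nu0 / 2,
                rate = hp@b0 + st$nu0 * sum(precStar) / 2, log = TRUE))
    if (is.null(fixedHypers$nu0))
        ordinates["nu0"] <- condLogDensNu0(precStar, sigma02Star, nu0Star,
                                           hp@beta, hp@nuMax)

    out <- logLikStar + logPrior - sum(ordinates)
    attr(out, "ordinates") <- ordinates
    attr(out, "logLikStar") <- logLikStar
    attr(out, "logPriorStar") <- logPrior
    out
}

#' Posterior predictive replicates of the region summaries
#'
#' For each of \code{nDraws} retained posterior draws, simulates a replicate
#' dataset of the same size and batch structure from the fitted mixture and
#' compares the observed summaries with the pooled replicates by a two-sample
#' Kolmogorov-Smirnov statistic.
#'
#' @param fit a \linkS4class{MixtureFit}.
#' @param nDraws number of replicate datasets (default: all retained draws;
#'   0 returns an empty matrix).
#' @param seed integer seed.
#' @return list with \code{replicates} (nDraws x n matrix), \code{D} and
#'   \code{p.value}.
#' @export
posteriorPredictive <- function(fit, nDraws = NULL, seed = 1L) {
    nKeep <- nrow(fit@theta)
    if (is.null(nDraws)) nDraws <- nKeep
    if (nDraws == 0L)
        return(list(replicates = matrix(numeric(0), 0, length(fit@data)),
                    D = NA_real_, p.value = NA_real_))
    set.seed(seed)
    take <- if (nDraws >= nKeep) seq_len(nKeep)
        else sort(sample.int(nKeep, nDraws))
    n <- length(fit@data)
    K <- fit@k; B <- fit@nBatch
    d <- fit@hypers@d
    reps <- matrix(NA_real_, length(take), n)
    for (i in seq_along(take)) {
        t <- take[i]
        theta <- matrix(fit@theta[t, ], K, B)
        sigma2 <- matrix(fit@sigma2[t, ], K, B)
        pimat <- matrix(fit@pi[t, ], K, B)
        z <- vapply(fit@batch, function(b)
            sample.int(K, 1, prob = pimat[, b]), integer(1))
        U <- if (is.finite(d)) stats::rgamma(n, d / 2, rate = d / 2)
            else rep(1, n)
        reps[i, ] <- stats::rnorm(n, theta[cbind(z, fit@batch)],
                                  sqrt(sigma2[cbind(z, fit@batch)] / U))
    }
    ks <- ksStatistic(fit@data, as.vector(reps))
    list(replicates = reps, D = ks$D, p.value = ks$p.value)
}

# parsimony order: pooled variants and smaller K are simpler
parsimonyRank <- function(variant, k) {
    2L * k + ifelse(variant %in% c("SBP", "MBP"), 0L, 1L)
}

#' Fit and select among mixture model variants at one region
#'
#' Runs the model cascade: single-batch models (SB, SBP) for each candidate
#' K; if more than 2\% of samples are uncertainly assigned in the best
#' single-batch model and more than one batch is present, multi-batch models
#' (MB, MBP) are evaluated too. Among fitted models the one with the highest
#' final log likelihood wins, with the more parsimonious model (pooled
#' variance, then smaller K) preferred on ties within 2 log units; when the
#' top two models are within the marginal-likelihood gate, Chib's estimates
#' decide.
#'
#' @param r numeric summaries (after augmentation if any).
#' @param batch integer batch per observation.
#' @param kSet candidate component counts (default from
#'   \code{\link{candidateK}}).
#' @param variants \code{"auto"} for the cascade, or a subset of
#'   \code{c("SB","SBP","MB","MBP")} to force.
#' @param hypers a \linkS4class{HyperPriors}.
#' @param isAugmented logical flags per observation.
#' @param nStarts,startBurnin,nBurnin,nIter,thin sampler schedule, passed to
#'   \code{\link{gibbsFit}}.
#' @param computeChib whether to compute Chib marginal likelihoods for gated
#'   comparisons (default TRUE).
#' @param gate marginal-likelihood gate on final log likelihoods (default
#'   10).
#' @param seed integer seed.
#' @return list with \code{fit} (selected \linkS4class{MixtureFit}) and
#'   \code{comparison} (a \linkS4class{ModelComparison}).
#' @export
selectMixtureModel <- function(r, batch, kSet = NULL, variants = "auto",
                               hypers = new("HyperPriors"),
                               isAugmented = NULL, nStarts = 10L,
                               startBurnin = 200L, nBurnin = 500L,
                               nIter = 1000L, thin = 1L, computeChib = TRUE,
                               gate = 10, seed = 1L) {
    if (is.null(kSet)) kSet <- candidateK(r)
    batch <- as.integer(factor(batch))
    B <- max(batch)
    auto <- identical(variants, "auto")
    singles <- if (auto) c("SB", "SBP") else
        intersect(variants, c("SB", "SBP"))
    multis <- if (auto) c("MB", "MBP") else
        intersect(variants, c("MB", "MBP"))
    if (!auto && !length(singles) && !length(multis))
        stop("no valid variants requested")

    fits <- list()
    fitOne <- function(variant, k, s) {
        gibbsFit(r, batch, variant = variant, k = k, hypers = hypers,
                 nBurnin = nBurnin, nIter = nIter, thin = thin,
                 nStarts = nStarts, startBurnin = startBurnin,
                 seed = seed + s, isAugmented = isAugmented)
    }
    s <- 0L
    for (k in kSet) for (v in singles) {
        s <- s + 1L
        fits[[paste(v, k, sep = "_")]] <- fitOne(v, k, s)
    }

    escalated <- FALSE
    if (length(fits)) {
        lastLL <- vapply(fits, function(f) f@logLik[length(f@logLik)],
                         numeric(1))
        bestSingle <- fits[[which.max(lastLL)]]
        if ((auto && B > 1L && shouldEscalate(bestSingle)) ||
            (!auto && length(multis))) {
            escalated <- auto
            for (k in kSet) for (v in multis) {
                s <- s + 1L
                fits[[paste(v, k, sep = "_")]] <- fitOne(v, k, s)
            }
        }
    } else {
        for (k in kSet) for (v in multis) {
            s <- s + 1L
            fits[[paste(v, k, sep = "_")]] <- fitOne(v, k, s)
        }
    }

    lastLL <- vapply(fits, function(f) f@logLik[length(f@logLik)],
                     numeric(1))
    flagged <- vapply(fits, function(f)
        tryCatch(detectLabelSwitching(f)$flagged, error = function(e) TRUE),
        logical(1))
    usable <- if (all(flagged)) seq_along(fits) else which(!flagged)
    ll <- lastLL[usable]
    eligible <- usable[ll >= max(ll) - 2]
    ranks <- vapply(fits[eligible], function(f)
        parsimonyRank(f@variant, f@k), integer(1))
    selIdx <- eligible[which.min(ranks)]

    chibVals <- rep(NA_real_, length(fits))
    if (computeChib && length(usable) > 1) {
        ord <- usable[order(lastLL[usable], decreasing = TRUE)]
        top2 <- ord[1:2]
        if (gateMarginalLikelihood(lastLL[top2[1]], lastLL[top2[2]], gate)) {
            ml <- vapply(top2, function(i)
                tryCatch(as.numeric(chibMarginalLikelihood(fits[[i]],
                    seed = seed)), error = function(e) NA_real_),
                numeric(1))
            chibVals[top2] <- ml
            if (all(is.finite(ml)))
                selIdx <- top2[which.max(ml)]
        }
    }

    sel <- fits[[selIdx]]
    tab <- data.frame(variant = vapply(fits, function(f) f@variant, ""),
                      k = vapply(fits, function(f) f@k, integer(1)),
                      logLik = lastLL,
                      marginalLik = chibVals,
                      labelSwitching = flagged,
                      selected = seq_along(fits) == selIdx,
                      row.names = NULL)
    cmp <- new("ModelComparison", table = tab,
               selectedVariant = sel@variant, selectedK = sel@k,
               escalated = escalated)
    list(fit = sel, comparison = cmp)
}
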