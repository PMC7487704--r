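#' @include AllClasses.R
NULL

# --- internal helpers -------------------------------------------------------

# group index: component h fastest, batch b slowest -> (b-1)*K + h
groupIndex <- function(z, batch, K) (batch - 1L) * K + z

# grouped sums with zeros for empty groups
groupSums <- function(x, idx, nGroups) {
    out <- numeric(nGroups)
    s <- rowsum(x, idx)
    out[as.integer(rownames(s))] <- s
    out
}

rdirichlet1 <- function(alpha) {
    g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
    if (all(g == 0)) g <- rep(1, length(alpha))
    g / sum(g)
}

# categorical sampling by the Gumbel-max trick on a matrix of log weights
sampleRows <- function(logw) {
    gum <- -log(-log(matrix(stats::runif(length(logw)), nrow(logw))))
    max.col(logw + gum, ties.method = "first")
}

softmaxRows <- function(logw) {
    m <- apply(logw, 1, max)
    w <- exp(logw - m)
    w / rowSums(w)
}

# start-selection score: observed-data log likelihood plus the hierarchical
# prior on (theta, mu). The likelihood alone is invariant to per-batch label
# permutations, so it cannot distinguish chains whose components track
# different copy number states in different batches; the theta | mu, tau2
# term heavily penalises such misaligned modes.
startScore <- function(st, r, batch, hp, d) {
    mixLogLik(r, batch, st$theta, st$sigma2, st$pi, d) +
        sum(stats::dnorm(st$theta, st$mu, sqrt(st$tau2), log = TRUE)) +
        sum(stats::dnorm(st$mu, hp@mu0, sqrt(hp@tau20), log = TRUE))
}

# observed-data log likelihood: t (or normal) mixture marginal over z and U
mixLogLik <- function(r, batch, theta, sigma2, pimat, d) {
    K <- nrow(theta)
    n <- length(r)
    ll <- matrix(NA_real_, n, K)
    for (h in seq_len(K)) {
        th <- theta[h, batch]
        sg <- sqrt(sigma2[h, batch])
        dens <- if (is.finite(d))
            stats::dt((r - th) / sg, df = d, log = TRUE) - log(sg)
        else stats::dnorm(r, th, sg, log = TRUE)
        ll[, h] <- dens + log(pimat[cbind(batch, h)])
    }
    m <- apply(ll, 1, max)
    sum(m + log(rowSums(exp(ll - m))))
}

# batch-specific component-mean anchors: k-means centres per batch, sorted
# ascending so component labels are rank-aligned across batches. Sorting is
# essential: if labels start attached to different copy number states in
# different batches the chain cannot recover, because per-batch label
# permutations leave the likelihood (and, when the batch shift is comparable
# to the cluster gap, nearly the posterior) unchanged.
initAnchors <- function(r, batch, K, B) {
    centers <- vars <- props <- matrix(NA_real_, K, B)
    for (b in seq_len(B)) {
        rb <- r[batch == b]
        km <- if (length(unique(rb)) >= K)
            tryCatch(stats::kmeans(rb, centers = K, nstart = 3),
                     error = function(e) NULL)
        else NULL
        if (is.null(km)) {
            centers[, b] <- stats::quantile(rb, names = FALSE,
                                            probs = (seq_len(K) - 0.5) / K)
            vars[, b] <- max(stats::var(rb), 1e-4)
            props[, b] <- 1 / K
        } else {
            ord <- order(km$centers)
            centers[, b] <- km$centers[ord]
            vars[, b] <- pmax(km$withinss[ord] / pmax(km$size[ord], 1),
                              1e-4)
            props[, b] <- pmax(km$size[ord], 0.5) / length(rb)
        }
    }
    list(centers = centers, vars = vars, props = props / rep(colSums(props),
                                                             each = K))
}

# draw an initial state: batch means anchored at rank-aligned k-means
# centres with jitter; all other parameters drawn from their priors
drawInitialState <- function(r, batch, K, B, hp, pooled, fixed,
                             anchors = NULL) {
    nu0 <- if (!is.null(fixed$nu0)) fixed$nu0 else
        min(stats::rgeom(1, hp@beta) + 1L, hp@nuMax)
    sigma02 <- if (!is.null(fixed$sigma02)) fixed$sigma02 else
        stats::rgamma(1, hp@a0, rate = hp@b0)
    tau2 <- if (!is.null(fixed$tau2)) rep_len(fixed$tau2, K) else
        1 / stats::rgamma(K, hp@eta0 / 2, rate = hp@eta0 * hp@m20 / 2)
    if (is.null(anchors)) {
        mu <- if (!is.null(fixed$mu)) rep_len(fixed$mu, K) else
            sort(stats::rnorm(K, hp@mu0, sqrt(hp@tau20)))
        theta <- matrix(stats::rnorm(K * B, mu, sqrt(tau2)), K, B)
        theta <- apply(theta, 2, sort)
        dim(theta) <- c(K, B)
        nPrec <- if (pooled) B else K * B
        prec <- stats::rgamma(nPrec, nu0 / 2, rate = nu0 * sigma02 / 2)
        prec <- pmax(prec, 1e-8)
        sigma2 <- if (pooled) matrix(1 / prec, K, B, byrow = TRUE)
            else matrix(1 / prec, K, B)
        pimat <- t(vapply(seq_len(B),
                          function(b) rdirichlet1(rep(hp@alpha, K)),
                          numeric(K)))
        dim(pimat) <- c(B, K)
    } else {
        # anchor the full initial state at the per-batch k-means solution
        # (jittered) so every start opens inside a well-separated basin
        # with labels rank-aligned across batches
        jitter <- 0.1 * max(stats::sd(r), 1e-3)
        theta <- anchors$centers + stats::rnorm(K * B, 0, jitter)
        theta <- apply(theta, 2, sort)
        dim(theta) <- c(K, B)
        mu <- if (!is.null(fixed$mu)) rep_len(fixed$mu, K) else
            rowMeans(theta)
        sigma2 <- anchors$vars *
            exp(stats::rnorm(K * B, 0, 0.2))
        dim(sigma2) <- c(K, B)
        if (pooled)
            sigma2 <- matrix(colMeans(sigma2), K, B, byrow = TRUE)
        pimat <- t(anchors$props *
                   matrix(stats::rgamma(K * B, 20, 20), K, B))
        pimat <- pimat / rowSums(pimat)
        dim(pimat) <- c(B, K)
    }
    list(theta = theta, sigma2 = sigma2, pi = pimat, mu = mu, tau2 = tau2,
         nu0 = nu0, sigma02 = sigma02,
         U = rep(1, length(r)), z = sample.int(K, length(r), replace = TRUE))
}

# one full Gibbs scan in fixed order:
# z, U, theta, sigma2, pi, mu, tau2, sigma02, nu0
# `freeze` names parameter blocks held fixed (used by Chib reduced runs)
gibbsScan <- function(st, r, batch, K, B, hp, pooled, fixed, fixU,
                      freeze = character(0)) {
    n <- length(r)
    KB <- K * B

    # z | . : multinomial over components
    logw <- matrix(NA_real_, n, K)
    for (h in seq_len(K)) {
        sd_h <- sqrt(st$sigma2[h, batch] / st$U)
        logw[, h] <- stats::dnorm(r, st$theta[h, batch], sd_h, log = TRUE) +
            log(pmax(st$pi[cbind(batch, h)], 1e-300))
    }
    st$z <- sampleRows(logw)
    st$logw <- logw

    # U | . : gamma scale weights of the t mixture
    if (!fixU && is.finite(hp@d)) {
        dev2 <- (r - st$theta[cbind(st$z, batch)])^2 /
            st$sigma2[cbind(st$z, batch)]
        st$U <- stats::rgamma(n, (hp@d + 1) / 2, rate = (hp@d + dev2) / 2)
        st$U <- pmax(st$U, 1e-10)
    } else st$U <- rep(1, n)

    idx <- groupIndex(st$z, batch, K)
    sU <- groupSums(st$U, idx, KB)
    sUr <- groupSums(st$U * r, idx, KB)

    # theta | . : precision-weighted normal, prior N(mu_h, tau2_h)
    if (!"theta" %in% freeze) {
        tau2v <- rep(st$tau2, times = B)
        muv <- rep(st$mu, times = B)
        prec <- sU / as.vector(st$sigma2) + 1 / tau2v
        mean_ <- (sUr / as.vector(st$sigma2) + muv / tau2v) / prec
        st$theta <- matrix(stats::rnorm(KB, mean_, sqrt(1 / prec)), K, B)
    }

    # sigma2 | . : conjugate gamma on the precisions
    ss <- groupSums(st$U * (r - st$theta[cbind(st$z, batch)])^2, idx, KB)
    cnt <- groupSums(rep(1, n), idx, KB)
    if (!"sigma2" %in% freeze) {
        if (pooled) {
            ssB <- colSums(matrix(ss, K, B))
            cntB <- colSums(matrix(cnt, K, B))
            precs <- stats::rgamma(B, (st$nu0 + cntB) / 2,
                                   rate = (st$nu0 * st$sigma02 + ssB) / 2)
            precs <- pmax(precs, 1e-8)
            st$sigma2 <- matrix(1 / precs, K, B, byrow = TRUE)
            st$prec <- precs
        } else {
            precs <- stats::rgamma(KB, (st$nu0 + cnt) / 2,
                                   rate = (st$nu0 * st$sigma02 + ss) / 2)
            precs <- pmax(precs, 1e-8)
            st$sigma2 <- matrix(1 / precs, K, B)
            st$prec <- precs
        }
    } else if (is.null(st$prec)) {
        st$prec <- if (pooled) 1 / st$sigma2[1, ] else 1 / as.vector(st$sigma2)
    }

    # pi | . : Dirichlet with batch counts
    cntKB <- matrix(cnt, K, B)
    if (!"pi" %in% freeze) {
        for (b in seq_len(B))
            st$pi[b, ] <- rdirichlet1(hp@alpha + cntKB[, b])
    }

    # mu | . : normal conjugate over batches
    if (is.null(fixed$mu) && !"mu" %in% freeze) {
        precMu <- B / st$tau2 + 1 / hp@tau20
        meanMu <- (rowSums(st$theta) / st$tau2 + hp@mu0 / hp@tau20) / precMu
        st$mu <- stats::rnorm(K, meanMu, sqrt(1 / precMu))
    }

    # tau2 | . : gamma conjugate on between-batch precisions
    if (is.null(fixed$tau2) && !"tau2" %in% freeze) {
        devs <- rowSums((st$theta - st$mu)^2)
        tprec <- stats::rgamma(K, (hp@eta0 + B) / 2,
                               rate = (hp@eta0 * hp@m20 + devs) / 2)
        st$tau2 <- pmax(1 / tprec, 1e-10)
    }

    # sigma02 | . : gamma conjugate over the precisions given nu0
    if (is.null(fixed$sigma02) && !"sigma02" %in% freeze) {
        nPrec <- length(st$prec)
        st$sigma02 <- stats::rgamma(1, hp@a0 + nPrec * st$nu0 / 2,
                                    rate = hp@b0 + st$nu0 * sum(st$prec) / 2)
    }

    # nu0 | . : discrete conditional on 1..nuMax under Geometric(beta)
    if (is.null(fixed$nu0) && !"nu0" %in% freeze) {
        grid <- seq_len(hp@nuMax)
        nPrec <- length(st$prec)
        slog <- sum(log(st$prec))
        ssum <- sum(st$prec)
        lp <- (grid - 1) * log(1 - hp@beta) +
            nPrec * ((grid / 2) * log(grid * st$sigma02 / 2) -
                     lgamma(grid / 2)) +
            (grid / 2 - 1) * slog - (grid * st$sigma02 / 2) * ssum
        lp <- lp - max(lp)
        st$nu0 <- sample(grid, 1, prob = exp(lp))
    }
    st
}

#' Fit a hierarchical Bayesian mixture of t distributions by Gibbs sampling
#'
#' Clusters one-dimensional CNV region summaries with a K-component mixture
#' of t distributions whose component means and variances vary by batch (MB),
#' share a variance within batch (MBP), or collapse all batches into one (SB,
#' SBP). All priors are conjugate; the sampler scans the full conditionals in
#' a fixed order (z, U, theta, sigma2, pi, mu, tau2, sigma02, nu0).
#' \code{nStarts} chains are run for \code{startBurnin} iterations each,
#' with component means, variances and weights anchored (jittered) at a
#' rank-aligned per-batch k-means solution and hyperparameters drawn from
#' their priors; the state with the highest penalised log likelihood
#' (observed-data likelihood plus the hierarchical prior on the batch
#' means, which distinguishes chains whose labels track different copy
#' number states in different batches) is kept, and a final run of
#' \code{nBurnin} burn-in plus \code{nIter} retained iterations follows.
#'
#' @param r numeric vector of per-sample region summaries (finite).
#' @param batch integer/character batch per observation (collapsed to one
#'   batch under SB/SBP).
#' @param variant \code{"MB"}, \code{"MBP"}, \code{"SB"} or \code{"SBP"}.
#' @param k number of mixture components.
#' @param hypers a \linkS4class{HyperPriors}.
#' @param nBurnin,nIter,thin final-run schedule (defaults 500, 1000, 1).
#' @param nStarts,startBurnin random-start schedule (defaults 10, 200).
#' @param seed integer seed.
#' @param isAugmented logical flag per observation (from
#'   \code{\link{augmentHomozygous}}); augmented points are fitted but
#'   excluded from downstream summaries.
#' @param fixU fix the latent t scale weights at 1 (Gaussian sampling model);
#'   also implied by \code{d = Inf} in the hyperparameters.
#' @param fixedHypers optional named list freezing \code{mu}, \code{tau2},
#'   \code{nu0} and/or \code{sigma02} at given values (their update steps are
#'   skipped), used for conjugate checks and reduced Chib runs.
#' @param startState optional full initial state (as produced internally);
#'   when supplied the random-start phase is skipped.
#' @return A \linkS4class{MixtureFit}.
#' @export
gibbsFit <- function(r, batch = NULL, variant = c("MB", "MBP", "SB", "SBP"),
                     k = 3L, hypers = new("HyperPriors"), nBurnin = 500L,
                     nIter = 1000L, thin = 1L, nStarts = 10L,
                     startBurnin = 200L, seed = 1L, isAugmented = NULL,
                     fixU = FALSE, fixedHypers = list(), startState = NULL) {
    variant <- match.arg(variant)
    stopifnot(all(is.finite(r)), k >= 1)
    n <- length(r)
    if (is.null(isAugmented)) isAugmented <- rep(FALSE, n)
    if (is.null(batch) || variant %in% c("SB", "SBP"))
        batch <- rep(1L, n)
    batch <- as.integer(factor(batch))
    B <- max(batch)
    K <- as.integer(k)
    pooled <- variant %in% c("SBP", "MBP")
    hp <- hypers
    set.seed(seed)

    st <- startState
    if (is.null(st)) {
        anchors <- initAnchors(r, batch, K, B)
        bestLL <- -Inf
        for (s in seq_len(nStarts)) {
            cand <- drawInitialState(r, batch, K, B, hp, pooled,
                                     fixedHypers, anchors)
            for (it in seq_len(startBurnin))
                cand <- gibbsScan(cand, r, batch, K, B, hp, pooled,
                                  fixedHypers, fixU)
            ll <- startScore(cand, r, batch, hp, hp@d)
            if (ll > bestLL) { bestLL <- ll; st <- cand }
        }
    }
    for (it in seq_len(nBurnin))
        st <- gibbsScan(st, r, batch, K, B, hp, pooled, fixedHypers, fixU)

    nKeep <- as.integer(nIter / thin)
    KB <- K * B
    thetaC <- matrix(NA_real_, nKeep, KB)
    sigmaC <- matrix(NA_real_, nKeep, KB)
    piC <- matrix(NA_real_, nKeep, KB)
    muC <- matrix(NA_real_, nKeep, K)
    tauC <- matrix(NA_real_, nKeep, K)
    nu0C <- numeric(nKeep)
    s02C <- numeric(nKeep)
    llC <- numeric(nKeep)
    pz <- matrix(0, n, K)
    kept <- 0L
    for (it in seq_len(nIter)) {
        st <- gibbsScan(st, r, batch, K, B, hp, pooled, fixedHypers, fixU)
        if (it %% thin == 0L) {
            kept <- kept + 1L
            thetaC[kept, ] <- as.vector(st$theta)
            sigmaC[kept, ] <- as.vector(st$sigma2)
            piC[kept, ] <- as.vector(t(st$pi))
            muC[kept, ] <- st$mu
            tauC[kept, ] <- st$tau2
            nu0C[kept] <- st$nu0
            s02C[kept] <- st$sigma02
            llC[kept] <- mixLogLik(r, batch, st$theta, st$sigma2, st$pi,
                                   hp@d)
            pz <- pz + softmaxRows(st$logw)
        }
    }
    pz <- pz / kept
    pz <- pz / rowSums(pz)
    cn <- paste0("h", rep(seq_len(K), times = B), ".b",
                 rep(seq_len(B), each = K))
    colnames(thetaC) <- colnames(sigmaC) <- colnames(piC) <- cn
    colnames(muC) <- colnames(tauC) <- paste0("h", seq_len(K))
    new("MixtureFit", variant = variant, k = K, nBatch = B,
        theta = thetaC[seq_len(kept), , drop = FALSE],
        sigma2 = sigmaC[seq_len(kept), , drop = FALSE],
        pi = piC[seq_len(kept), , drop = FALSE],
        mu = muC[seq_len(kept), , drop = FALSE],
        tau2 = tauC[seq_len(kept), , drop = FALSE],
        nu0 = nu0C[seq_len(kept)], sigma02 = s02C[seq_len(kept)],
        logLik = llC[seq_len(kept)], probz = pz, data = r,
        batch = batch, isAugmented = isAugmented, hypers = hp,
        seed = as.integer(seed))
}

#' Augment rare homozygous deletions across batches
#'
#' When observations below \code{detectionThreshold} (apparent homozygous
#' deletions) occur in some but not all batches, every batch lacking them
#' gains \code{nFakePerBatch} flagged pseudo-observations drawn from
#' Normal(m, s^2), where m and s are the mean and SD of the observed
#' sub-threshold values (s floored at 0.1). The flags ensure augmented points
#' are excluded from posterior summaries, genotype frequencies and the
#' association model; their only role is to pin the lowest mixture component
#' to the homozygous-deletion state in every batch.
#'
#' @param r numeric summaries.
#' @param batch integer batch per observation.
#' @param detectionThreshold default -1.
#' @param nFakePerBatch default 10.
#' @param seed integer seed.
#' @return list with elements \code{r}, \code{batch}, \code{isAugmented}.
#' @export
augmentHomozygous <- function(r, batch, detectionThreshold = -1,
                              nFakePerBatch = 10L, seed = 1L) {
    batch <- as.integer(factor(batch))
    sub <- r < detectionThreshold
    out <- list(r = r, batch = batch, isAugmented = rep(FALSE, length(r)))
    if (!any(sub)) return(out)
    lacking <- setdiff(seq_len(max(batch)), unique(batch[sub]))
    if (!length(lacking)) return(out)
    m <- mean(r[sub])
    s <- max(stats::sd(r[sub]), 0.1, na.rm = TRUE)
    if (is.na(s)) s <- 0.1
    set.seed(seed)
    fake <- stats::rnorm(nFakePerBatch * length(lacking), m, s)
    list(r = c(r, fake),
         batch = c(batch, rep(lacking, each = nFakePerBatch)),
         isAugmented = c(rep(FALSE, length(r)),
                         rep(TRUE, nFakePerBatch * length(lacking))))
}

#' Diagnose label switching in a mixture fit
#'
#' Splits the retained component-mean chains into consecutive windows and
#' compares, per batch, the rank order of the within-window averages of
#' theta_hb. A fit is flagged when any two windows disagree on the order,
#' which typically indicates that too many components were specified.
#'
#' @param fit a \linkS4class{MixtureFit}.
#' @param window window length in retained draws (default: a fifth of the
#'   chain, at least 2).
#' @return list with \code{flagged} (logical) and \code{orders} (window-by-
#'   batch matrix of order strings).
#' @export
detectLabelSwitching <- function(fit, window = NULL) {
    nDraw <- nrow(fit@theta)
    if (is.null(window)) window <- max(2L, nDraw %/% 5L)
    if (nDraw < 2L * window)
        stop("need at least two windows of retained draws")
    nw <- nDraw %/% window
    K <- fit@k; B <- fit@nBatch
    orders <- matrix("", nw, B)
    for (w in seq_len(nw)) {
        rows <- ((w - 1L) * window + 1L):(w * window)
        for (b in seq_len(B)) {
            cols <- (b - 1L) * K + seq_len(K)
            m <- colMeans(fit@theta[rows, cols, drop = FALSE])
            orders[w, b] <- paste(order(m), collapse = ",")
        }
    }
    flagged <- any(apply(orders, 2, function(o) length(unique(o)) > 1L))
    list(flagged = flagged, orders = orders)
}

#' Effective sample size of a chain
#'
#' Initial positive sequence estimator from the autocorrelation function.
#'
#' @param x numeric chain.
#' @return Estimated effective sample size.
#' @export
effectiveSize <- function(x) {
    n <- length(x)
    if (stats::sd(x) == 0) return(n)
    rho <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
    s <- 0
    for (k in seq_along(rho)) {
        if (rho[k] < 0) break
        s <- s + rho[k]
    }
    max(1, n / (1 + 2 * s))
}
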