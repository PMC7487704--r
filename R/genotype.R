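#' @include AllClasses.R
NULL

#' Beta shape parameters of the allelic B-allele-frequency model
#'
#' For each total copy number c in 0..4, the possible allelic genotypes
#' ordered by B-allele count (e.g. AA, AB, BB for c = 2) each get a beta
#' distribution for the observed BAF. Homozygous genotypes are sharply
#' concentrated near 0 or 1, heterozygous genotypes near their allelic dose
#' (1/2 for one of two copies, 1/3 and 2/3 for three copies, quarters for
#' four). Copy number zero has no alleles; its single "null" genotype gets a
#' diffuse uniform beta, as BAF is then noise. Values are package defaults
#' and fully configurable.
#'
#' @return Named list indexed by copy number \code{"0".."4"}; each element a
#'   (c+1) x 2 matrix of beta shape1/shape2 rows ordered by B-allele count.
#' @export
allelicModel <- function() {
    list(`0` = matrix(c(1, 1), 1, 2, byrow = TRUE),
         `1` = matrix(c(1, 99, 99, 1), 2, 2, byrow = TRUE),
         `2` = matrix(c(1, 99, 20, 20, 99, 1), 3, 2, byrow = TRUE),
         `3` = matrix(c(1, 99, 13.3, 26.7, 26.7, 13.3, 99, 1), 4, 2,
                      byrow = TRUE),
         `4` = matrix(c(1, 99, 10, 30, 20, 20, 30, 10, 99, 1), 5, 2,
                      byrow = TRUE))
}

#' Estimate population B allele frequencies from diploid samples
#'
#' Hard genotypes are derived from BAF by thresholds (< 0.25 AA, 0.25-0.75
#' AB, > 0.75 BB) among samples called diploid, and the B allele frequency is
#' the allele proportion.
#'
#' @param baf numeric matrix, samples x SNPs (vector allowed for one SNP).
#' @param diploid logical vector selecting the diploid-called samples.
#' @return numeric vector of per-SNP B allele frequencies.
#' @export
estimatePopFreq <- function(baf, diploid) {
    baf <- as.matrix(baf)
    apply(baf[diploid, , drop = FALSE], 2, function(b) {
        b <- b[is.finite(b)]
        if (!length(b)) return(NA_real_)
        nB <- sum(b > 0.75) * 2 + sum(b >= 0.25 & b <= 0.75)
        nB / (2 * length(b))
    })
}

#' Log likelihood of a component-to-copy-number mapping
#'
#' For samples confidently assigned to a single mixture component, evaluates
#' the BAF likelihood of the candidate mapping f: component -> copy number.
#' For sample i at SNP j with copy number c = f(h_i), the likelihood averages
#' over the allelic genotypes g in G(c): beta(b_ij; psi_cg) weighted by the
#' binomial probability of g B alleles out of c at population frequency
#' p_jB. Copy number zero reduces to the single diffuse beta.
#'
#' @param baf samples x SNPs matrix of B allele frequencies (confident
#'   samples only).
#' @param component integer mixture component per sample (ascending-mean
#'   order).
#' @param mapping integer vector: copy number for each component.
#' @param model allelic model as from \code{\link{allelicModel}}.
#' @param popFreq numeric per-SNP B allele frequencies.
#' @return log likelihood (numeric scalar).
#' @export
mappingLogLik <- function(baf, component, mapping, model = allelicModel(),
                          popFreq) {
    baf <- as.matrix(baf)
    stopifnot(nrow(baf) == length(component),
              ncol(baf) == length(popFreq))
    total <- 0
    for (j in seq_len(ncol(baf))) {
        pB <- popFreq[j]
        b <- pmin(pmax(baf[, j], 1e-6), 1 - 1e-6)
        for (h in unique(component)) {
            c <- mapping[h]
            rows <- which(component == h & is.finite(baf[, j]))
            if (!length(rows)) next
            psi <- model[[as.character(c)]]
            g <- seq_len(nrow(psi)) - 1L
            w <- stats::dbinom(g, size = c, prob = pB)
            dens <- vapply(seq_along(g), function(k)
                w[k] * stats::dbeta(b[rows], psi[k, 1], psi[k, 2]),
                numeric(length(rows)))
            dens <- matrix(dens, nrow = length(rows))
            total <- total + sum(log(pmax(rowSums(dens), 1e-300)))
        }
    }
    total
}

# admissible mappings: non-decreasing over components ordered by mean,
# consecutive steps of 0 or 1 copy, range within 0..4, and the modal
# component anchored at 2 (unless duplicationOnly, which anchors the lowest
# component at 2)
enumerateMappings <- function(k, modal, duplicationOnly = FALSE) {
    grid <- as.matrix(expand.grid(rep(list(0:1), k - 1)))
    maps <- list()
    for (start in 0:4) {
        if (k == 1) {
            maps[[length(maps) + 1L]] <- start
            next
        }
        for (i in seq_len(nrow(grid))) {
            f <- start + cumsum(c(0L, grid[i, ]))
            if (max(f) <= 4L) maps[[length(maps) + 1L]] <- f
        }
    }
    anchor <- if (duplicationOnly) 1L else modal
    keep <- vapply(maps, function(f) f[anchor] == 2L, logical(1))
    unique(maps[keep])
}

#' Batch-rank-aligned component probabilities
#'
#' Returns the per-sample component probability matrix with columns
#' reordered, within each sample's batch, by the rank of the batch-specific
#' posterior component means. Location/scale batch distortions preserve the
#' rank order of the copy number clusters, so ranks give the canonical
#' component correspondence across batches even if the sampler settled in a
#' mode where raw labels track different states in different batches (the
#' homozygous-deletion augmentation keeps the extreme component populated in
#' every batch, making the ranks well defined).
#'
#' @param fit a \linkS4class{MixtureFit}.
#' @return matrix (n x K); column k is the k-th smallest component of each
#'   sample's batch.
#' @export
alignedProbz <- function(fit) {
    K <- fit@k; B <- fit@nBatch
    thbar <- matrix(colMeans(fit@theta), K, B)
    pz <- probz(fit)
    out <- pz
    for (b in seq_len(B)) {
        ord <- order(thbar[, b])
        rows <- fit@batch == b
        out[rows, ] <- pz[rows, ord, drop = FALSE]
    }
    out
}

#' Genotype mixture components to integer copy numbers
#'
#' Orders the mixture components by posterior mean, enumerates the
#' admissible one-to-one and many-to-one mappings into copy numbers 0..4
#' (non-decreasing, contiguous, with the modal component mapped to two
#' copies unless a duplication-only region is declared), scores each mapping
#' by the BAF likelihood of \code{\link{mappingLogLik}} on confidently
#' assigned samples, and aggregates the component probabilities into copy
#' number probabilities under the winning mapping. Augmented
#' pseudo-observations are dropped from the output; samples excluded from
#' the fit can be appended as no-calls via \code{sampleId}.
#'
#' @param fit a \linkS4class{MixtureFit}.
#' @param baf samples x SNPs matrix of BAFs for the fitted (non-augmented)
#'   observations, rows in data order.
#' @param popFreq optional per-SNP B allele frequencies; estimated from the
#'   modal (diploid) component when missing.
#' @param model allelic model (default \code{\link{allelicModel}}).
#' @param regionId region identifier for the output.
#' @param sampleId sample identifiers (default seq along the data).
#' @param probCut confident-assignment threshold (default 0.99).
#' @param duplicationOnly declare a duplication-only region (lowest
#'   component diploid).
#' @return A \linkS4class{CopyNumberCalls}.
#' @export
genotypeComponents <- function(fit, baf, popFreq = NULL,
                               model = allelicModel(), regionId = "region",
                               sampleId = NULL, probCut = 0.99,
                               duplicationOnly = FALSE) {
    keep <- !fit@isAugmented
    pz <- alignedProbz(fit)[keep, , drop = FALSE]
    baf <- as.matrix(baf)
    if (nrow(baf) != nrow(pz))
        stop("baf must have one row per non-augmented observation")
    K <- fit@k
    if (is.null(sampleId)) sampleId <- as.character(seq_len(nrow(pz)))

    maxp <- apply(pz, 1, max)
    comp <- max.col(pz, ties.method = "first")
    confident <- maxp >= probCut
    if (!any(confident))
        stop("no samples confidently assigned to a single component")
    modal <- as.integer(names(which.max(table(comp[confident]))))

    hasSnp <- ncol(baf) > 0 && any(is.finite(baf[confident, , drop = FALSE]))
    if (hasSnp) {
        if (is.null(popFreq))
            popFreq <- estimatePopFreq(baf, confident & comp == modal)
        cands <- enumerateMappings(K, modal, duplicationOnly)
        ll <- vapply(cands, function(f)
            mappingLogLik(baf[confident, , drop = FALSE], comp[confident],
                          f, model, popFreq), numeric(1))
        best <- max(ll)
        tied <- which(ll >= best - 1e-8)
        if (length(tied) > 1) {
            nStates <- vapply(cands[tied], function(f)
                length(unique(f)), integer(1))
            tied <- tied[order(-nStates)]
            message("mapping likelihood tie; preferring the mapping with ",
                    "more distinct copy number states")
        }
        mapping <- cands[[tied[1]]]
    } else {
        warning("no SNP BAFs available in region ", regionId,
                "; falling back to the log2R-mean heuristic mapping")
        thbar <- matrix(colMeans(fit@theta), K, fit@nBatch)
        means <- rowMeans(apply(thbar, 2, sort))
        mapping <- pmin(pmax(round(2 + (means - means[modal]) / 0.5), 0L),
                        4L)
        mapping <- as.integer(cummax(mapping))
    }

    prob <- matrix(0, nrow(pz), 5L,
                   dimnames = list(NULL, paste0("cn", 0:4)))
    for (h in seq_len(K))
        prob[, mapping[h] + 1L] <- prob[, mapping[h] + 1L] + pz[, h]
    hard <- max.col(prob, ties.method = "first") - 1L
    new("CopyNumberCalls", regionId = regionId,
        mapping = as.integer(mapping), prob = prob,
        hardCall = as.integer(hard), sampleId = as.character(sampleId))
}

#' Hardy-Weinberg chi-square test for a deletion polymorphism
#'
#' Given genotyped counts for copy numbers 0, 1 and 2 (duplications are
#' excluded from the test), estimates the deletion allele frequency
#' q = (2 n0 + n1) / (2N) and compares observed counts with the expected
#' (N q^2, 2 N q (1-q), N (1-q)^2) by a 1-df Pearson chi-square.
#'
#' @param counts numeric length-3 vector \code{c(n0, n1, n2)}.
#' @return list with \code{chi2}, \code{p.value}, \code{q}.
#' @export
hweChisq <- function(counts) {
    stopifnot(length(counts) == 3)
    n <- sum(counts)
    if (n == 0) stop("no genotyped samples")
    q <- (2 * counts[1] + counts[2]) / (2 * n)
    if (q == 0) return(list(chi2 = 0, p.value = 1, q = 0))
    expected <- n * c(q^2, 2 * q * (1 - q), (1 - q)^2)
    chi2 <- sum((counts - expected)^2 / expected)
    list(chi2 = unname(chi2),
         p.value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
         q = unname(q))
}
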