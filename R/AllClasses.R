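#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assays<- rowRanges colData
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#' @importFrom IRanges IRanges subsetByOverlaps disjoin
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
NULL

#' Container for SNP-array intensities at probe resolution
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding the two
#' assays used throughout the workflow: \code{lrr} (log2 R ratios) and
#' \code{baf} (B allele frequencies, defined only at SNP probes). Rows are
#' probes (with \code{rowRanges} carrying position, GC content and the SNP
#' flag), columns are samples (with \code{colData} carrying plate, study
#' site, case status, covariates and the data-quality stratum).
#'
#' @slot .Data inherited \code{RangedSummarizedExperiment} structure.
#' @export
setClass("CNPExperiment", contains = "RangedSummarizedExperiment")

setValidity("CNPExperiment", function(object) {
    msg <- NULL
    an <- names(assays(object))
    if (!all(c("lrr", "baf") %in% an))
        msg <- c(msg, "assays must include 'lrr' and 'baf'")
    if (is.null(msg)) {
        baf <- assay(object, "baf")
        rng <- suppressWarnings(range(baf, na.rm = TRUE))
        if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1))
            msg <- c(msg, "BAF values must lie in [0, 1]")
        rd <- rowRanges(object)
        if (!is.null(rd) && "is_snp" %in% names(S4Vectors::mcols(rd))) {
            nonsnp <- !S4Vectors::mcols(rd)$is_snp
            if (any(nonsnp) && any(!is.na(baf[nonsnp, , drop = FALSE])))
                msg <- c(msg, "BAF must be missing at nonpolymorphic probes")
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' One-dimensional summary of a CNV region
#'
#' Per-sample scalar summaries (median log2 R ratio across the probes in the
#' region, or the first principal component of the probe submatrix) together
#' with the plate and quality annotation needed downstream.
#'
#' @slot regionId character(1) region identifier.
#' @slot summary named numeric vector, one value per sample (NA allowed when
#'   all probes for that sample are missing).
#' @slot method \code{"median"} or \code{"pc1"}.
#' @slot plate character vector parallel to \code{summary}.
#' @slot highQuality logical vector parallel to \code{summary}.
#' @export
setClass("RegionSummary",
    representation(regionId = "character", summary = "numeric",
                   method = "character", plate = "character",
                   highQuality = "logical"))

setValidity("RegionSummary", function(object) {
    n <- length(object@summary)
    if (length(object@plate) != n || length(object@highQuality) != n)
        return("plate and highQuality must be parallel to summary")
    if (!object@method %in% c("median", "pc1"))
        return("method must be 'median' or 'pc1'")
    TRUE
})

#' Mapping from chemistry plates to latent batches at one CNV region
#'
#' @slot regionId character(1).
#' @slot plateBatch named character vector: names are plates, values the
#'   merged batch labels (consecutive letters in a deterministic order).
#' @slot nBatches integer(1).
#' @slot mergeLog data.frame logging each agglomeration step (pair merged,
#'   K-S statistic and p-value) and any pre-merges of small plates.
#' @export
setClass("BatchAssignment",
    representation(regionId = "character", plateBatch = "character",
                   nBatches = "integer", mergeLog = "data.frame"))

setValidity("BatchAssignment", function(object) {
    if (is.null(names(object@plateBatch)))
        return("plateBatch must be named by plate")
    if (object@nBatches != length(unique(object@plateBatch)))
        return("nBatches must equal the number of distinct batch labels")
    TRUE
})

#' Hyperparameters of the hierarchical mixture model
#'
#' Fixed quantities of the hierarchy: the Normal(mu0, tau20) prior on the
#' overall component means mu_h, the Gamma(eta0/2, eta0*m20/2) prior on the
#' between-batch precisions 1/tau2_h, the Gamma(a0, b0) prior on sigma02, the
#' Geometric(beta) prior on nu0, the Dirichlet(alpha) prior on the component
#' weights, and the t degrees of freedom d. The informative tau2 prior keeps
#' batch-level component means close to their overall mean, which discourages
#' label switching at genuine copy number polymorphisms.
#'
#' @slot mu0,tau20 prior mean and variance for the overall component means.
#' @slot eta0,m20 shape-type and scale-type parameters of the tau2 prior.
#' @slot a0,b0 Gamma prior on sigma02.
#' @slot beta success probability of the geometric prior on nu0.
#' @slot alpha Dirichlet concentration (recycled across components).
#' @slot d t-distribution degrees of freedom; \code{Inf} gives the Gaussian
#'   limit with the latent scale weights fixed at 1.
#' @slot nuMax upper truncation of the discrete nu0 support.
#' @export
setClass("HyperPriors",
    representation(mu0 = "numeric", tau20 = "numeric", eta0 = "numeric",
                   m20 = "numeric", a0 = "numeric", b0 = "numeric",
                   beta = "numeric", alpha = "numeric", d = "numeric",
                   nuMax = "integer"),
    prototype(mu0 = 0, tau20 = 0.4, eta0 = 32, m20 = 0.5, a0 = 1.8, b0 = 6,
              beta = 0.1, alpha = 1, d = 100, nuMax = 100L))

setValidity("HyperPriors", function(object) {
    pos <- c(tau20 = object@tau20, eta0 = object@eta0, m20 = object@m20,
             a0 = object@a0, b0 = object@b0, alpha = object@alpha,
             d = object@d)
    if (any(pos <= 0)) return("scale hyperparameters must be positive")
    if (object@beta <= 0 || object@beta >= 1)
        return("beta must lie in (0, 1)")
    TRUE
})

#' Posterior draws for one mixture model variant
#'
#' Chains of all sampled parameters of the hierarchical t mixture, the
#' Rao-Blackwellised per-sample component probabilities, and the observed-data
#' log-likelihood trace. Component columns are stored in the sampler's label
#' order; use \code{\link{componentOrder}} for the ascending-mean relabeling.
#'
#' @slot variant one of \code{"SB"}, \code{"SBP"}, \code{"MB"}, \code{"MBP"}.
#' @slot k integer number of components.
#' @slot nBatch integer number of batches (1 for SB/SBP).
#' @slot theta,sigma2 matrices (iterations x K*B), columns ordered h fastest.
#' @slot pi matrix (iterations x K*B) of batch-specific weights.
#' @slot mu,tau2 matrices (iterations x K) of hyper-means and variances.
#' @slot nu0,sigma02 numeric vectors of hyperparameter draws.
#' @slot logLik observed-data log-likelihood per retained iteration.
#' @slot probz matrix (n x K) of posterior component probabilities.
#' @slot data numeric vector of the (possibly augmented) summaries fitted.
#' @slot batch integer batch index per observation.
#' @slot isAugmented logical flag per observation.
#' @slot hypers the \linkS4class{HyperPriors} used.
#' @slot seed integer seed of the run.
#' @export
setClass("MixtureFit",
    representation(variant = "character", k = "integer", nBatch = "integer",
                   theta = "matrix", sigma2 = "matrix", pi = "matrix",
                   mu = "matrix", tau2 = "matrix", nu0 = "numeric",
                   sigma02 = "numeric", logLik = "numeric", probz = "matrix",
                   data = "numeric", batch = "integer",
                   isAugmented = "logical", hypers = "HyperPriors",
                   seed = "integer"))

setValidity("MixtureFit", function(object) {
    if (!object@variant %in% c("SB", "SBP", "MB", "MBP"))
        return("variant must be SB, SBP, MB or MBP")
    if (nrow(object@probz) != length(object@data))
        return("probz must have one row per observation")
    sums <- rowSums(object@probz)
    if (any(abs(sums - 1) > 1e-8))
        return("per-sample component probabilities must sum to 1")
    TRUE
})

#' Integer copy number calls for one region
#'
#' @slot regionId character(1).
#' @slot mapping integer vector: copy number assigned to each mixture
#'   component (components in ascending order of posterior mean).
#' @slot prob matrix (n x 5) of posterior probabilities over copy numbers
#'   0..4, columns \code{cn0..cn4}; rows sum to 1.
#' @slot hardCall integer vector of maximum a posteriori copy numbers (NA for
#'   samples excluded from the fit).
#' @slot sampleId character vector of sample identifiers.
#' @export
setClass("CopyNumberCalls",
    representation(regionId = "character", mapping = "integer",
                   prob = "matrix", hardCall = "integer",
                   sampleId = "character"))

setValidity("CopyNumberCalls", function(object) {
    if (ncol(object@prob) != 5L)
        return("prob must have 5 columns (cn0..cn4)")
    if (any(abs(rowSums(object@prob) - 1) > 1e-8))
        return("copy number probabilities must sum to 1 per sample")
    if (length(object@hardCall) != nrow(object@prob))
        return("hardCall must be parallel to prob")
    TRUE
})

#' Posterior draws of the case-control regression
#'
#' @slot beta matrix of retained coefficient draws, one named column per
#'   coefficient (the copy number slope is \code{cn}, its quality interaction
#'   \code{cn_hq}).
#' @slot z numeric vector of spike-indicator draws (0/1).
#' @slot copyDraws matrix of sampled integer copy numbers (optional; may have
#'   zero rows).
#' @slot stratified logical(1): whether quality terms were included.
#' @slot accept named numeric vector of Metropolis acceptance rates.
#' @export
setClass("AssociationFit",
    representation(beta = "matrix", z = "numeric", copyDraws = "matrix",
                   stratified = "logical", accept = "numeric"))

setValidity("AssociationFit", function(object) {
    if (length(object@z) && !all(object@z %in% c(0, 1)))
        return("z draws must be 0/1")
    TRUE
})

#' Design of a synthetic SNP-array cohort
#'
#' Defaults emulate the study conditions of the simulation benchmark: 990
#' samples on 16 chemistry plates, one CNV region of 54 markers (1 SNP + 53
#' nonpolymorphic), a deletion allele segregating at frequency 0.22 under
#' Hardy-Weinberg equilibrium, copy-number cluster means (-3, -0.5, 0, 0.4)
#' for 0-3 copies, and plate-level distortions r* = (r - rbar_c) * xi + rbar_c
#' + eps with eps ~ N(delta, 0.02^2) applied to plates drawn affected with
#' probability 0.5.
#'
#' @slot nSamples,nPlates,nMarkers cohort dimensions.
#' @slot q deletion allele frequency.
#' @slot delta location shift mean of the batch distortion.
#' @slot xi scale factor of the batch distortion (>= 1).
#' @slot epsSd standard deviation of the distortion noise.
#' @slot plateProb probability a plate is affected.
#' @slot clusterMeans named numeric, log2 R cluster mean per copy number.
#' @slot probeSd probe-level measurement noise SD.
#' @slot sampleSd per-sample baseline random-effect SD.
#' @slot pB population B allele frequency of the region's SNP.
#' @export
setClass("SimulationDesign",
    representation(nSamples = "integer", nPlates = "integer",
                   nMarkers = "integer", q = "numeric", delta = "numeric",
                   xi = "numeric", epsSd = "numeric", plateProb = "numeric",
                   clusterMeans = "numeric", probeSd = "numeric",
                   sampleSd = "numeric", pB = "numeric"),
    prototype(nSamples = 990L, nPlates = 16L, nMarkers = 54L, q = 0.22,
              delta = 0, xi = 1, epsSd = 0.02, plateProb = 0.5,
              clusterMeans = c(`0` = -3, `1` = -0.5, `2` = 0, `3` = 0.4),
              probeSd = 0.15, sampleSd = 0.1, pB = 0.5))

setValidity("SimulationDesign", function(object) {
    if (object@q <= 0 || object@q >= 1)
        return("allele frequency must lie in (0, 1)")
    if (object@xi < 1) return("xi must be >= 1")
    if (object@epsSd <= 0 || object@probeSd <= 0 || object@sampleSd < 0)
        return("noise SDs must be positive")
    TRUE
})
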