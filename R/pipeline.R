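#' @include AllClasses.R select.R genotype.R batch.R
NULL

#' Batch discovery, mixture fitting and genotyping for one CNV region
#'
#' Chains the region workflow: summarise the region to one value per sample
#' (median log2 R ratio by default), estimate latent batches from the
#' chemistry plates, augment rare homozygous deletions where needed, fit and
#' select the mixture model (the SB/SBP to MB/MBP cascade, or a forced
#' variant), and genotype the mixture components from the region's SNP
#' B allele frequencies. Samples with a missing summary are excluded from
#' the fit and carried as no-calls.
#'
#' @param x a \linkS4class{CNPExperiment}.
#' @param region a length-1 \code{GRanges}; NULL uses the whole probe set as
#'   one region.
#' @param method region summary method (\code{"median"} or \code{"pc1"}).
#' @param variants \code{"auto"} (cascade) or forced variant subset.
#' @param hypers a \linkS4class{HyperPriors}.
#' @param alpha,exclusionFloor batch-estimation settings (see
#'   \code{\link{estimateBatches}}).
#' @param nStarts,startBurnin,nBurnin,nIter,thin sampler schedule.
#' @param computeChib compute gated Chib marginal likelihoods during model
#'   selection.
#' @param seed integer seed covering every stochastic stage.
#' @return list with \code{summary}, \code{batches}, \code{comparison},
#'   \code{fit}, \code{calls}, \code{excluded} (sample ids with missing
#'   summaries).
#' @export
cnpPipeline <- function(x, region = NULL, method = "median",
                        variants = "auto", hypers = new("HyperPriors"),
                        alpha = 0.01, exclusionFloor = -1, nStarts = 10L,
                        startBurnin = 200L, nBurnin = 500L, nIter = 1000L,
                        thin = 1L, computeChib = FALSE, seed = 1L) {
    if (is.null(region)) {
        rr <- rowRanges(x)
        region <- GRanges(as.character(seqnames(rr))[1],
                          IRanges(min(start(rr)), max(end(rr))),
                          region_id = "region_all")
    }
    rs <- summarizeRegion(x, region, method)
    keep <- is.finite(rs@summary)
    excluded <- names(rs@summary)[!keep]
    r <- rs@summary[keep]
    plates <- rs@plate[keep]

    ba <- estimateBatches(rs, alpha = alpha,
                          exclusionFloor = exclusionFloor)
    bi <- batchIndex(ba, plates)

    aug <- augmentHomozygous(r, bi, detectionThreshold = exclusionFloor,
                             seed = seed)
    kSet <- candidateK(r, detectionThreshold = exclusionFloor)
    sel <- selectMixtureModel(aug$r, aug$batch, kSet = kSet,
                              variants = variants, hypers = hypers,
                              isAugmented = aug$isAugmented,
                              nStarts = nStarts, startBurnin = startBurnin,
                              nBurnin = nBurnin, nIter = nIter, thin = thin,
                              computeChib = computeChib, seed = seed)

    sub <- subsetByOverlaps(x, region)
    snp <- rowRanges(sub)$is_snp
    baf <- t(assay(sub, "baf")[snp, keep, drop = FALSE])
    calls <- genotypeComponents(sel$fit, baf,
                                regionId = region$region_id[1],
                                sampleId = names(r))
    list(summary = rs, batches = ba, comparison = sel$comparison,
         fit = sel$fit, calls = calls, excluded = excluded)
}
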