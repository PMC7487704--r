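#' @include AllClasses.R
NULL

# Local-linear LOESS smooth with tricube weights; predicts at `xout`,
# clamping to the fitted range so extrapolation reuses the boundary fit.
loessPredict <- function(x, y, xout, span) {
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(unique(x)) < 5) return(rep(mean(y), length(xout)))
    fit <- stats::loess(y ~ x, span = span, degree = 1,
                        control = stats::loess.control(surface = "interpolate"))
    xc <- pmin(pmax(xout, min(x)), max(x))
    stats::predict(fit, data.frame(x = xc))
}

#' GC correction of log2 R ratios
#'
#' Per sample, fits a LOESS (local linear, span \code{span}) of the log2 R
#' ratios against probe GC content over a random subsample of probes, predicts
#' the GC trend for the full probe set, and returns the residuals
#' (observed - predicted). When all probes share the same GC value the
#' correction degenerates to mean subtraction.
#'
#' @param x a \linkS4class{CNPExperiment}.
#' @param nSubsample number of probes used to fit the trend (default 30000,
#'   capped at the probe count).
#' @param span LOESS span (default 1/3).
#' @param seed integer seed for the probe subsample.
#' @return A \linkS4class{CNPExperiment} with the \code{lrr} assay replaced by
#'   residuals.
#' @export
gcCorrect <- function(x, nSubsample = 30000, span = 1/3, seed = 1L) {
    gc <- rowRanges(x)$gc
    lrr <- assay(x, "lrr")
    n <- nrow(lrr)
    set.seed(seed)
    idx <- sort(sample.int(n, min(nSubsample, n)))
    res <- lrr
    for (j in seq_len(ncol(lrr))) {
        y <- lrr[, j]
        if (all(is.na(y))) {
            warning("sample ", colnames(lrr)[j],
                    " has no finite log2 R ratios; left unchanged")
            next
        }
        if (length(unique(gc)) == 1L) {
            res[, j] <- y - mean(y, na.rm = TRUE)
            next
        }
        pred <- loessPredict(gc[idx], y[idx], gc, span)
        res[, j] <- y - pred
    }
    out <- x
    assays(out)$lrr <- res
    out
}

# Split probes into chromosome arms given an optional centromere table
# (data.frame chrom/start/end). Returns a factor over probes.
armFactor <- function(rr, centromeres = NULL) {
    chrom <- as.character(seqnames(rr))
    pos <- start(rr)
    if (is.null(centromeres)) {
        warning("no chromosome-arm annotation supplied; ",
                "treating each chromosome as a single arm")
        return(factor(chrom))
    }
    arm <- chrom
    for (i in seq_len(nrow(centromeres))) {
        sel <- chrom == centromeres$chrom[i]
        arm[sel] <- paste0(chrom[sel],
                           ifelse(pos[sel] < centromeres$start[i], "p", "q"))
    }
    factor(arm)
}

#' Spatial correction of GC-corrected log2 R ratios
#'
#' Per sample and chromosome arm, takes the SNPs with balanced allele
#' fractions (0.4 < BAF < 0.6) as anchors, smooths their GC-corrected log2 R
#' ratios against probe order within the arm by LOESS, predicts the spatial
#' trend for every probe on the arm (including imbalanced SNPs and
#' nonpolymorphic probes), and returns residuals. Arms with fewer than
#' \code{minAnchors} anchors are left uncorrected with a warning.
#'
#' @param x a \linkS4class{CNPExperiment} (typically after
#'   \code{\link{gcCorrect}}).
#' @param span LOESS span (default 1/3).
#' @param centromeres optional data.frame (\code{chrom}, \code{start},
#'   \code{end}) of centromere spans defining arm boundaries; absent, whole
#'   chromosomes are used with a warning.
#' @param minAnchors minimum balanced-SNP anchors per arm (default 10).
#' @return A \linkS4class{CNPExperiment} with detrended \code{lrr}.
#' @export
spatialCorrect <- function(x, span = 1/3, centromeres = NULL,
                           minAnchors = 10L) {
    rr <- rowRanges(x)
    lrr <- assay(x, "lrr")
    baf <- assay(x, "baf")
    isSnp <- rr$is_snp
    arms <- armFactor(rr, centromeres)
    res <- lrr
    warned <- FALSE
    for (j in seq_len(ncol(lrr))) {
        for (a in levels(arms)) {
            sel <- which(arms == a)
            sel <- sel[order(start(rr)[sel])]
            idxArm <- seq_along(sel)
            b <- baf[sel, j]
            anchors <- which(isSnp[sel] & !is.na(b) & b > 0.4 & b < 0.6 &
                             is.finite(lrr[sel, j]))
            if (length(anchors) < minAnchors) {
                if (!warned) {
                    warning("arm(s) with fewer than ", minAnchors,
                            " balanced-SNP anchors left uncorrected")
                    warned <- TRUE
                }
                next
            }
            pred <- loessPredict(idxArm[anchors], lrr[sel, j][anchors],
                                 idxArm, span)
            res[sel, j] <- lrr[sel, j] - pred
        }
    }
    out <- x
    assays(out)$lrr <- res
    out
}

#' Per-sample data-quality metrics
#'
#' Computes, per sample, the median absolute deviation and lag-10
#' autocorrelation of autosomal log2 R ratios ordered by genomic position.
#' Samples with fewer than 11 finite values get a missing autocorrelation.
#'
#' @param x a \linkS4class{CNPExperiment}.
#' @return data.frame with columns \code{sample_id}, \code{mad},
#'   \code{acf10}.
#' @export
qualityMetrics <- function(x) {
    rr <- rowRanges(x)
    auto <- !grepl("^(chr)?[XYM]", as.character(seqnames(rr)))
    ord <- order(as.character(seqnames(rr))[auto], start(rr)[auto])
    lrr <- assay(x, "lrr")[which(auto)[ord], , drop = FALSE]
    acf10 <- apply(lrr, 2, function(v) {
        v <- v[is.finite(v)]
        if (length(v) < 11) return(NA_real_)
        stats::acf(v, lag.max = 10, plot = FALSE)$acf[11]
    })
    mads <- apply(lrr, 2, function(v) stats::mad(v, na.rm = TRUE))
    data.frame(sample_id = colnames(lrr), mad = mads, acf10 = acf10,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Stratify samples into high/low quality by autocorrelation
#'
#' @param metrics output of \code{\link{qualityMetrics}}.
#' @param acfCut fixed autocorrelation cutoff (default 0.06); samples with
#'   \code{acf10 < acfCut} are high quality.
#' @param decile if \code{TRUE}, use the empirical 90th percentile of
#'   \code{acf10} as the cutoff instead (top decile flagged low quality).
#' @return logical vector \code{high_quality}, named by sample.
#' @export
stratifyQuality <- function(metrics, acfCut = 0.06, decile = FALSE) {
    if (decile)
        acfCut <- stats::quantile(metrics$acf10, 0.9, na.rm = TRUE,
                                  names = FALSE)
    hq <- metrics$acf10 < acfCut
    hq[is.na(hq)] <- FALSE
    names(hq) <- metrics$sample_id
    hq
}

#' Reciprocal overlap of two intervals
#'
#' TRUE when the overlap covers at least \code{fraction} of both intervals
#' (1-based inclusive coordinates, same chromosome assumed).
#'
#' @param a,b numeric length-2 vectors \code{c(start, end)}.
#' @param fraction required fraction (default 0.5).
#' @return logical(1).
#' @export
reciprocalOverlap <- function(a, b, fraction = 0.5) {
    ov <- min(a[2], b[2]) - max(a[1], b[1]) + 1
    if (ov <= 0) return(FALSE)
    lenA <- a[2] - a[1] + 1
    lenB <- b[2] - b[1] + 1
    ov >= fraction * lenA && ov >= fraction * lenB
}

#' Consolidate per-sample CNV calls into analysis regions
#'
#' The pooled call boundaries are broken into disjoint intervals; intervals
#' carried by at least \code{minCarriers} distinct samples are kept; runs of
#' kept intervals separated by no gap form a candidate region, whose final
#' span is the minimum start to maximum end over member intervals carried by
#' at least \code{coreFraction} of the region's carrier set.
#'
#' @param calls data.frame with columns \code{sample_id}, \code{chrom},
#'   \code{start}, \code{end} (1-based inclusive).
#' @param minCarriers minimum distinct carriers per interval (default 150).
#' @param coreFraction fraction of the region's carriers required for an
#'   interval to extend the region span (default 0.5).
#' @return \code{GRanges} of pairwise non-overlapping regions with
#'   \code{region_id} and \code{n_carriers} columns.
#' @export
consolidateRegions <- function(calls, minCarriers = 150,
                               coreFraction = 0.5) {
    if (is.null(calls) || nrow(calls) == 0L) return(GRanges())
    gr <- GRanges(calls$chrom, IRanges(calls$start, calls$end),
                  sample_id = calls$sample_id)
    dj <- disjoin(gr)
    hits <- findOverlaps(dj, gr)
    carriers <- split(gr$sample_id[S4Vectors::subjectHits(hits)],
                      factor(S4Vectors::queryHits(hits),
                             levels = seq_along(dj)))
    carriers <- lapply(carriers, unique)
    nCar <- lengths(carriers)
    keep <- which(nCar >= minCarriers)
    if (!length(keep)) return(GRanges())
    dj <- dj[keep]
    carriers <- carriers[keep]
    # group kept intervals that touch (gap of 0 bp) on the same chromosome
    ord <- order(as.character(seqnames(dj)), start(dj))
    dj <- dj[ord]; carriers <- carriers[ord]
    grp <- cumsum(c(TRUE, !(as.character(seqnames(dj))[-1] ==
                            as.character(seqnames(dj))[-length(dj)] &
                            start(dj)[-1] <= end(dj)[-length(dj)] + 1)))
    out <- lapply(split(seq_along(dj), grp), function(ii) {
        regionCarriers <- unique(unlist(carriers[ii]))
        frac <- vapply(carriers[ii],
                       function(s) length(s) / length(regionCarriers),
                       numeric(1))
        core <- ii[frac >= coreFraction]
        if (!length(core)) core <- ii[which.max(frac)]
        GRanges(seqnames(dj)[ii[1]],
                IRanges(min(start(dj)[core]), max(end(dj)[core])),
                n_carriers = length(regionCarriers))
    })
    out <- suppressWarnings(do.call(c, unname(out)))
    out$region_id <- sprintf("CNP_%03d", seq_along(out))
    out
}

#' Filter an external HMM call table to the high-confidence set
#'
#' Keeps autosomal calls with at least \code{minProbes} probes and posterior
#' probability at least \code{minPosterior}.
#'
#' @param calls data.frame with columns \code{sample_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{state}, \code{n_probes},
#'   \code{posterior_prob}.
#' @param minProbes,minPosterior filters (defaults 10 and 0.9).
#' @return Filtered data.frame.
#' @export
filterCnvCalls <- function(calls, minProbes = 10, minPosterior = 0.9) {
    keep <- calls$n_probes >= minProbes &
        calls$posterior_prob >= minPosterior &
        !grepl("^(chr)?[XYM]", calls$chrom)
    calls[keep, , drop = FALSE]
}
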