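makeGcExperiment <- function(nProbes = 2000, nSamples = 3, slope = 0.8,
                             seed = 3) {
    set.seed(seed)
    probes <- data.frame(probe_id = sprintf("p%05d", seq_len(nProbes)),
                         chrom = "chr1", pos = seq_len(nProbes) * 500,
                         gc = runif(nProbes, 0.25, 0.75),
                         is_snp = FALSE)
    samples <- data.frame(sample_id = sprintf("s%d", seq_len(nSamples)),
                          plate = "pA")
    lrr <- matrix(slope * probes$gc + rnorm(nProbes * nSamples, 0, 0.1),
                  nProbes, nSamples)
    baf <- matrix(NA_real_, nProbes, nSamples)
    CNPExperiment(lrr, baf, probes, samples)
}

test_that("GC correction removes a linear GC trend", {
    x <- makeGcExperiment()
    xc <- gcCorrect(x, nSubsample = 1500, seed = 9)
    gc <- SummarizedExperiment::rowRanges(xc)$gc
    res <- SummarizedExperiment::assay(xc, "lrr")
    for (j in 1:3)
        expect_lt(abs(cor(res[, j], gc)), 0.05)
    # residuals agree in spirit with an ordinary least squares detrend
    olsRes <- residuals(lm(SummarizedExperiment::assay(x, "lrr")[, 1] ~ gc))
    expect_gt(cor(res[, 1], olsRes), 0.98)
})

test_that("GC correction degenerate cases: constant signal, constant GC", {
    x <- makeGcExperiment(nProbes = 500, slope = 0)
    lrr <- SummarizedExperiment::assay(x, "lrr")
    lrr[, 1] <- 0.42
    SummarizedExperiment::assays(x)$lrr <- lrr
    xc <- gcCorrect(x, seed = 2)
    expect_lt(max(abs(SummarizedExperiment::assay(xc, "lrr")[, 1])), 1e-8)

    # constant GC: correction is mean subtraction
    x2 <- makeGcExperiment(nProbes = 300, slope = 0)
    rr <- SummarizedExperiment::rowRanges(x2)
    rr$gc <- 0.5
    SummarizedExperiment::rowRanges(x2) <- rr
    y <- SummarizedExperiment::assay(x2, "lrr")[, 1]
    xc2 <- gcCorrect(x2, seed = 2)
    expect_equal(SummarizedExperiment::assay(xc2, "lrr")[, 1],
                 y - mean(y), tolerance = 1e-12)
})

makeWaveExperiment <- function(nProbes = 4000, wave = TRUE, seed = 5) {
    set.seed(seed)
    probes <- data.frame(probe_id = sprintf("p%05d", seq_len(nProbes)),
                         chrom = "chr1", pos = seq_len(nProbes) * 1000,
                         gc = 0.5, is_snp = rep(c(TRUE, FALSE),
                                                length.out = nProbes))
    samples <- data.frame(sample_id = "s1", plate = "pA")
    trend <- if (wave) 0.3 * sin(seq_len(nProbes) / 600) else 0
    lrr <- matrix(trend + rnorm(nProbes, 0, 0.15), ncol = 1)
    baf <- matrix(NA_real_, nProbes, 1)
    baf[probes$is_snp, 1] <- runif(sum(probes$is_snp), 0.42, 0.58)
    CNPExperiment(lrr, baf, probes, samples)
}

acf10 <- function(v) stats::acf(v, lag.max = 10, plot = FALSE)$acf[11]

test_that("spatial correction removes slow genomic waves", {
    x <- makeWaveExperiment()
    before <- acf10(SummarizedExperiment::assay(x, "lrr")[, 1])
    expect_gt(before, 0.3)
    expect_warning(xc <- spatialCorrect(x), "arm")
    after <- acf10(SummarizedExperiment::assay(xc, "lrr")[, 1])
    expect_lt(after, 0.06)
})

test_that("spatial correction leaves white noise essentially unchanged", {
    x <- makeWaveExperiment(wave = FALSE, seed = 6)
    before <- acf10(SummarizedExperiment::assay(x, "lrr")[, 1])
    xc <- suppressWarnings(spatialCorrect(x))
    after <- acf10(SummarizedExperiment::assay(xc, "lrr")[, 1])
    expect_lt(abs(after - before), 0.02)
})

test_that("arms without balanced-SNP anchors are left untouched", {
    x <- makeWaveExperiment(nProbes = 500, seed = 7)
    baf <- SummarizedExperiment::assay(x, "baf")
    baf[!is.na(baf)] <- 0.95          # no balanced SNPs anywhere
    SummarizedExperiment::assays(x)$baf <- baf
    before <- SummarizedExperiment::assay(x, "lrr")
    xc <- suppressWarnings(spatialCorrect(x))
    expect_identical(SummarizedExperiment::assay(xc, "lrr"), before)
})

test_that("corrections are idempotent to within smoother tolerance", {
    x <- makeGcExperiment(nProbes = 4000)
    x1 <- gcCorrect(x, nSubsample = 4000, seed = 4)
    x2 <- gcCorrect(x1, nSubsample = 4000, seed = 4)
    d <- SummarizedExperiment::assay(x2, "lrr") -
        SummarizedExperiment::assay(x1, "lrr")
    expect_lt(sd(d), 0.01 * sd(SummarizedExperiment::assay(x1, "lrr")))
})

test_that("lag-10 autocorrelation matches its sampling distribution", {
    set.seed(10)
    nP <- 10000
    probes <- data.frame(probe_id = sprintf("p%05d", seq_len(nP)),
                         chrom = "chr2", pos = seq_len(nP) * 100,
                         gc = 0.5, is_snp = FALSE)
    samples <- data.frame(sample_id = c("iid", "ar1"), plate = "pA")
    phi <- 0.5
    ar <- as.numeric(arima.sim(list(ar = phi), nP))
    lrr <- cbind(rnorm(nP), ar)
    x <- CNPExperiment(lrr, lrr * NA, probes, samples)
    qm <- qualityMetrics(x)
    expect_lt(abs(qm$acf10[1]), 0.03)          # iid: near zero
    expect_lt(abs(qm$acf10[2] - phi^10), 0.05) # AR(1): closed form phi^10
    expect_true(all(qm$mad >= 0))
})

test_that("quality stratification applies the fixed autocorrelation cut", {
    metrics <- data.frame(sample_id = c("a", "b"), mad = c(0.1, 0.1),
                          acf10 = c(0.05, 0.07))
    flags <- stratifyQuality(metrics, acfCut = 0.06)
    expect_identical(unname(flags), c(TRUE, FALSE))
    # fewer than 11 probes: acf undefined, flagged low quality
    metrics$acf10[1] <- NA
    expect_false(stratifyQuality(metrics)[["a"]])
})

test_that("reciprocal overlap implements the 50 percent rule symmetrically", {
    expect_true(reciprocalOverlap(c(100, 200), c(150, 250)))
    expect_false(reciprocalOverlap(c(100, 200), c(190, 400)))
    expect_true(reciprocalOverlap(c(5, 50), c(5, 50)))
    # symmetry on random interval pairs
    set.seed(11)
    for (i in 1:50) {
        a <- sort(sample.int(1000, 2)); b <- sort(sample.int(1000, 2))
        expect_identical(reciprocalOverlap(a, b), reciprocalOverlap(b, a))
    }
})

test_that("region consolidation follows the carrier and core rules", {
    # 200 identical calls -> single region
    calls <- data.frame(sample_id = sprintf("s%03d", 1:200),
                        chrom = "chr1", start = 1000, end = 2000)
    gr <- consolidateRegions(calls)
    expect_length(gr, 1)
    expect_equal(GenomicRanges::start(gr), 1000)
    expect_equal(GenomicRanges::end(gr), 2000)

    # 160 short + 20 long: the long tail has too few carriers
    calls2 <- rbind(
        data.frame(sample_id = sprintf("a%03d", 1:160), chrom = "chr1",
                   start = 1000, end = 2000),
        data.frame(sample_id = sprintf("b%03d", 1:20), chrom = "chr1",
                   start = 1000, end = 5000))
    gr2 <- consolidateRegions(calls2)
    expect_length(gr2, 1)
    expect_equal(GenomicRanges::end(gr2), 2000)

    # below the carrier threshold everywhere -> nothing
    calls3 <- data.frame(sample_id = sprintf("c%03d", 1:100),
                         chrom = "chr1", start = 1, end = 10)
    expect_length(consolidateRegions(calls3), 0)
    expect_length(consolidateRegions(calls3[0, ]), 0)
})

test_that("consolidated regions are pairwise non-overlapping", {
    set.seed(12)
    calls <- do.call(rbind, lapply(1:400, function(i) {
        s <- sample.int(5000, 1)
        data.frame(sample_id = sprintf("s%03d", i), chrom = "chr3",
                   start = s, end = s + sample.int(2000, 1))
    }))
    gr <- consolidateRegions(calls, minCarriers = 50)
    if (length(gr) > 1) {
        hits <- GenomicRanges::findOverlaps(gr, gr)
        expect_true(all(S4Vectors::queryHits(hits) ==
                        S4Vectors::subjectHits(hits)))
    }
    succeed()
})

test_that("HMM call filtering keeps the high-confidence autosomal set", {
    calls <- data.frame(sample_id = "s", chrom = c("chr1", "chr1", "chrX"),
                        start = 1, end = 10, state = "deletion",
                        n_probes = c(12, 9, 15),
                        posterior_prob = c(0.95, 0.95, 0.95))
    out <- filterCnvCalls(calls)
    expect_equal(nrow(out), 1)
    expect_equal(out$n_probes, 12)
})
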