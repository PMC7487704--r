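#' @include AllClasses.R genotype.R
NULL

#' Construct a simulation design
#'
#' See \linkS4class{SimulationDesign} for the meaning and defaults of all
#' parameters; any can be overridden by name.
#'
#' @param ... slots to override, e.g. \code{delta = 0.5}, \code{xi = 2}.
#' @return A \linkS4class{SimulationDesign}.
#' @export
simulationDesign <- function(...) {
    args <- list(...)
    for (nm in c("nSamples", "nPlates", "nMarkers"))
        if (!is.null(args[[nm]])) args[[nm]] <- as.integer(args[[nm]])
    do.call(new, c(list("SimulationDesign"), args))
}

#' Simulate a SNP-array cohort with a copy number polymorphism
#'
#' Generates probe-level log2 R ratios and B allele frequencies for one CNV
#' region. Integer copy numbers are drawn from Hardy-Weinberg proportions of
#' the deletion allele frequency \code{q}; probe values are
#' Normal(rbar_c, probeSd^2) around the copy-number cluster mean plus a
#' per-sample baseline random effect Normal(0, sampleSd^2) emulating
#' sample-to-sample quality variation. The first marker is a SNP: its BAF is
#' drawn from the allelic beta model given the copy number and the
#' population B allele frequency (uniform noise for zero copies); remaining
#' markers are nonpolymorphic with missing BAF. Samples are randomised to
#' chemistry plates.
#'
#' @param design a \linkS4class{SimulationDesign}.
#' @param seed integer seed (fixed seed gives bitwise-identical output).
#' @return list with \code{experiment} (a \linkS4class{CNPExperiment}),
#'   \code{truth} (data.frame sample_id, plate, cn) and \code{design}.
#' @export
simulateCohort <- function(design = simulationDesign(), seed = 1L) {
    set.seed(seed)
    n <- design@nSamples
    q <- design@q
    cn <- sample(0:2, n, replace = TRUE,
                 prob = c(q^2, 2 * q * (1 - q), (1 - q)^2))
    plate <- sample(rep(sprintf("plate%02d", seq_len(design@nPlates)),
                        length.out = n))
    sampleEff <- stats::rnorm(n, 0, design@sampleSd)
    m <- design@nMarkers
    rbar <- design@clusterMeans[as.character(cn)]
    lrr <- matrix(stats::rnorm(m * n, rep(rbar + sampleEff, each = m),
                               design@probeSd), m, n)
    baf <- matrix(NA_real_, m, n)
    am <- allelicModel()
    for (i in seq_len(n)) {
        if (cn[i] == 0) {
            baf[1, i] <- stats::rbeta(1, 1, 1)
        } else {
            g <- stats::rbinom(1, cn[i], design@pB)
            psi <- am[[as.character(cn[i])]]
            baf[1, i] <- stats::rbeta(1, psi[g + 1, 1], psi[g + 1, 2])
        }
    }
    pos <- seq(70122981, by = 2000, length.out = m)
    probes <- data.frame(probe_id = sprintf("probe%03d", seq_len(m)),
                         chrom = "chr4", pos = pos,
                         gc = round(stats::runif(m, 0.3, 0.7), 3),
                         is_snp = c(TRUE, rep(FALSE, m - 1)))
    samples <- data.frame(sample_id = sprintf("sample%04d", seq_len(n)),
                          plate = plate, site = "site1",
                          high_quality = TRUE,
                          stringsAsFactors = FALSE)
    x <- CNPExperiment(lrr, baf, probes, samples)
    truth <- data.frame(sample_id = samples$sample_id, plate = plate,
                        cn = cn, stringsAsFactors = FALSE)
    list(experiment = x, truth = truth, design = design)
}

#' Apply plate-level batch distortions
#'
#' Each chemistry plate is drawn affected with probability
#' \code{design@plateProb}; on affected plates every probe value is
#' transformed as r* = (r - rbar_c) * xi + rbar_c + eps with eps ~
#' N(delta, epsSd^2), where rbar_c is the true cluster mean of the sample's
#' copy number. Unaffected plates pass through untouched.
#'
#' @param cohort output of \code{\link{simulateCohort}}.
#' @param seed integer seed.
#' @param forceAffected optional character vector of plate names to treat as
#'   affected (bypasses the Bernoulli draw).
#' @return The cohort list with a distorted \code{experiment} and an added
#'   \code{affectedPlates} element.
#' @export
applyBatchEffects <- function(cohort, seed = 1L, forceAffected = NULL) {
    design <- cohort$design
    truth <- cohort$truth
    x <- cohort$experiment
    set.seed(seed)
    plates <- sort(unique(truth$plate))
    affected <- if (is.null(forceAffected))
        plates[stats::runif(length(plates)) < design@plateProb]
    else forceAffected
    lrr <- assay(x, "lrr")
    rbar <- design@clusterMeans[as.character(truth$cn)]
    sel <- truth$plate %in% affected
    if (any(sel)) {
        m <- nrow(lrr)
        centred <- sweep(lrr[, sel, drop = FALSE], 2, rbar[sel])
        eps <- matrix(stats::rnorm(m * sum(sel), design@delta, design@epsSd),
                      m, sum(sel))
        lrr[, sel] <- sweep(centred * design@xi, 2, rbar[sel], "+") + eps
    }
    assays(x)$lrr <- lrr
    cohort$experiment <- x
    cohort$affectedPlates <- affected
    cohort
}

#' Evaluate copy number calls against simulation truth
#'
#' The carrier-versus-noncarrier AUC uses 1 minus the posterior probability
#' of two copies as the score for true copy number different from two,
#' computed by the trapezoidal rule over all thresholds. Hard-call accuracy
#' is reported overall and per true copy number, along with carrier
#' sensitivity and specificity of the hard calls.
#'
#' @param calls a \linkS4class{CopyNumberCalls} (samples in truth order).
#' @param truth data.frame with column \code{cn} of true copy numbers.
#' @return list with \code{auc}, \code{accuracy}, \code{perCopyAccuracy},
#'   \code{sensitivity}, \code{specificity}.
#' @export
evaluateCalls <- function(calls, truth) {
    stopifnot(nrow(cnProb(calls)) == nrow(truth))
    carrier <- truth$cn != 2
    score <- 1 - cnProb(calls)[, "cn2"]
    auc <- if (length(unique(carrier)) < 2) NA_real_ else
        as.numeric(pROC::auc(pROC::roc(response = carrier,
                                       predictor = score,
                                       levels = c(FALSE, TRUE),
                                       direction = "<", quiet = TRUE)))
    hard <- hardCalls(calls)
    acc <- mean(hard == truth$cn, na.rm = TRUE)
    per <- tapply(hard == truth$cn, truth$cn, mean, na.rm = TRUE)
    sens <- mean(hard[carrier] != 2, na.rm = TRUE)
    spec <- mean(hard[!carrier] == 2, na.rm = TRUE)
    list(auc = auc, accuracy = acc, perCopyAccuracy = per,
         sensitivity = sens, specificity = spec)
}
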