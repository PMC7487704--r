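#' @include AllClasses.R
NULL

#' Two-sample Kolmogorov-Smirnov comparison of eCDFs
#'
#' Returns the supremum distance between the two empirical cumulative
#' distribution functions and the asymptotic p-value. Each group must
#' contribute at least two finite values.
#'
#' @param a,b numeric vectors.
#' @return list with elements \code{D} and \code{p.value}.
#' @export
ksStatistic <- function(a, b) {
    a <- a[is.finite(a)]
    b <- b[is.finite(b)]
    if (length(a) < 2 || length(b) < 2)
        stop("each group needs at least 2 finite values")
    kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
    list(D = unname(kt$statistic), p.value = unname(kt$p.value))
}

#' Estimate latent batches by recursive plate merging
#'
#' Chemistry plates provisionally define batches; samples with summaries
#' below \code{exclusionFloor} (likely homozygous deletions) are excluded
#' from the eCDF comparisons. The pair of current batches with the largest
#' Kolmogorov-Smirnov p-value is merged while that p-value exceeds
#' \code{alpha}, recomputing eCDFs on the merged groups, until no pair is
#' indistinguishable. Ties are broken on the lexicographically smallest pair
#' so the result does not depend on plate input order. Plates contributing
#' fewer than \code{minPlateSize} test values are pre-merged with the plate
#' of closest mean (logged). Excluded samples inherit their plate's batch.
#' Final batch labels are consecutive letters ordered by batch mean summary.
#'
#' @param object a \linkS4class{RegionSummary}, or a numeric vector of
#'   per-sample summaries.
#' @param plates character vector of plate labels (ignored when
#'   \code{object} is a \code{RegionSummary}).
#' @param alpha type 1 error for declaring two eCDFs different (default
#'   0.01).
#' @param exclusionFloor summaries below this value are excluded from
#'   testing (default -1).
#' @param minPlateSize minimum test values per plate before pre-merging
#'   (default 5).
#' @return A \linkS4class{BatchAssignment}.
#' @export
estimateBatches <- function(object, plates = NULL, alpha = 0.01,
                            exclusionFloor = -1, minPlateSize = 5L) {
    if (is(object, "RegionSummary")) {
        values <- object@summary
        plates <- object@plate
        rid <- object@regionId
    } else {
        values <- object
        rid <- "region"
        if (is.null(plates)) stop("plates must be supplied")
    }
    stopifnot(length(values) == length(plates))
    plates <- as.character(plates)
    use <- is.finite(values) & values >= exclusionFloor
    log <- data.frame(step = character(), left = character(),
                      right = character(), D = numeric(), p = numeric(),
                      stringsAsFactors = FALSE)

    # group = current batch membership, keyed by plate
    membership <- stats::setNames(sort(unique(plates)), sort(unique(plates)))
    groupValues <- function() {
        g <- membership[plates[use]]
        split(values[use], g)
    }

    # pre-merge plates with too few usable values into the plate of
    # closest mean
    gv <- groupValues()
    small <- names(gv)[lengths(gv) < minPlateSize]
    small <- union(small, setdiff(membership, names(gv)))  # empty plates
    if (length(small) && length(small) < length(unique(membership))) {
        big <- setdiff(unique(membership), small)
        bigMeans <- vapply(big, function(g)
            mean(values[use & membership[plates] == g]), numeric(1))
        for (s in sort(small)) {
            sm <- mean(values[use & membership[plates] == s])
            target <- if (is.finite(sm)) big[which.min(abs(bigMeans - sm))]
                else big[1]
            membership[membership == s] <- target
            log <- rbind(log, data.frame(step = "premerge", left = s,
                                         right = target, D = NA_real_,
                                         p = NA_real_))
        }
    }

    repeat {
        gv <- groupValues()
        groups <- sort(names(gv))
        if (length(groups) < 2) break
        best <- NULL
        for (i in seq_along(groups)[-length(groups)]) {
            for (j in seq((i + 1), length(groups))) {
                ks <- ksStatistic(gv[[groups[i]]], gv[[groups[j]]])
                cand <- list(i = groups[i], j = groups[j], D = ks$D,
                             p = ks$p.value)
                if (is.null(best) || cand$p > best$p) best <- cand
            }
        }
        if (best$p <= alpha) break
        membership[membership == best$j] <- best$i
        log <- rbind(log, data.frame(step = "merge", left = best$i,
                                     right = best$j, D = best$D, p = best$p))
    }

    # deterministic labels: consecutive letters ordered by batch mean
    finalGroups <- unique(membership)
    gm <- vapply(finalGroups, function(g)
        mean(values[use & membership[plates] == g], na.rm = TRUE), numeric(1))
    gm[!is.finite(gm)] <- Inf
    lab <- stats::setNames(LETTERS[rank(gm, ties.method = "first")],
                           finalGroups)
    plateBatch <- stats::setNames(unname(lab[membership]), names(membership))
    new("BatchAssignment", regionId = rid, plateBatch = plateBatch,
        nBatches = length(finalGroups), mergeLog = log)
}

#' Integer batch index per sample from a batch assignment
#'
#' @param assignment a \linkS4class{BatchAssignment}.
#' @param plates character vector of per-sample plates.
#' @return integer vector of contiguous batch indices 1..B, ordered by batch
#'   label.
#' @export
batchIndex <- function(assignment, plates) {
    lab <- assignment@plateBatch[as.character(plates)]
    as.integer(factor(lab, levels = sort(unique(assignment@plateBatch))))
}
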