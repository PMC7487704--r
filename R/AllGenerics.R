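#' @include AllClasses.R
NULL

#' Accessors for CNPmix objects
#'
#' Small accessor generics: \code{probz} returns the per-sample component
#' probability matrix of a \linkS4class{MixtureFit}; \code{componentOrder}
#' the permutation sorting components by posterior mean; \code{batchLabels}
#' the plate-to-batch map of a \linkS4class{BatchAssignment}; \code{nBatches}
#' its batch count; \code{cnProb}, \code{hardCalls} and \code{cnMapping} the
#' probability matrix, MAP calls and component-to-copy-number map of a
#' \linkS4class{CopyNumberCalls}.
#'
#' @param object a CNPmix object.
#' @return See details per method.
#' @name accessors
#' @aliases probz componentOrder batchLabels nBatches cnProb hardCalls
#'   cnMapping
NULL

#' @rdname accessors
#' @export
setGeneric("probz", function(object) standardGeneric("probz"))

#' @rdname accessors
#' @export
setGeneric("componentOrder", function(object) standardGeneric("componentOrder"))

#' @rdname accessors
#' @export
setGeneric("batchLabels", function(object) standardGeneric("batchLabels"))

#' @rdname accessors
#' @export
setGeneric("nBatches", function(object) standardGeneric("nBatches"))

#' @rdname accessors
#' @export
setGeneric("cnProb", function(object) standardGeneric("cnProb"))

#' @rdname accessors
#' @export
setGeneric("hardCalls", function(object) standardGeneric("hardCalls"))

#' @rdname accessors
#' @export
setGeneric("cnMapping", function(object) standardGeneric("cnMapping"))

#' @rdname accessors
setMethod("probz", "MixtureFit", function(object) object@probz)

#' @rdname accessors
setMethod("componentOrder", "MixtureFit", function(object) {
    # order by the batch-averaged posterior mean of theta: the actual
    # component locations (mu is shrunk towards its prior mean)
    K <- object@k
    m <- rowMeans(matrix(colMeans(object@theta), K, object@nBatch))
    order(m)
})

#' @rdname accessors
setMethod("batchLabels", "BatchAssignment", function(object) object@plateBatch)

#' @rdname accessors
setMethod("nBatches", "BatchAssignment", function(object) object@nBatches)

#' @rdname accessors
setMethod("cnProb", "CopyNumberCalls", function(object) object@prob)

#' @rdname accessors
setMethod("hardCalls", "CopyNumberCalls", function(object) object@hardCall)

#' @rdname accessors
setMethod("cnMapping", "CopyNumberCalls", function(object) object@mapping)

setMethod("show", "RegionSummary", function(object) {
    cat("RegionSummary for", object@regionId, "(", object@method, ")\n")
    cat(" ", length(object@summary), "samples;",
        sum(is.na(object@summary)), "missing;",
        length(unique(object@plate)), "plates\n")
})

setMethod("show", "BatchAssignment", function(object) {
    cat("BatchAssignment for", object@regionId, "\n")
    cat(" ", length(object@plateBatch), "plates merged into",
        object@nBatches, "batch(es)\n")
    tab <- table(object@plateBatch)
    cat("  plates per batch:", paste(names(tab), tab, sep = "=",
                                     collapse = ", "), "\n")
})

setMethod("show", "MixtureFit", function(object) {
    cat(sprintf("MixtureFit: %s model, K=%d, B=%d\n", object@variant,
                object@k, object@nBatch))
    cat(sprintf("  %d observations (%d augmented), %d retained draws\n",
                length(object@data), sum(object@isAugmented),
                nrow(object@theta)))
    ord <- componentOrder(object)
    m <- rowMeans(matrix(colMeans(object@theta), object@k, object@nBatch))
    cat("  component means:",
        paste(sprintf("%.3f", m[ord]), collapse = ", "), "\n")
    cat(sprintf("  final log-likelihood: %.2f\n",
                object@logLik[length(object@logLik)]))
})

setMethod("show", "CopyNumberCalls", function(object) {
    cat("CopyNumberCalls for", object@regionId, "\n")
    cat("  component -> copy number:",
        paste(seq_along(object@mapping), object@mapping, sep = "->",
              collapse = ", "), "\n")
    tab <- table(factor(object@hardCall, levels = 0:4))
    cat("  hard calls:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
})

setMethod("show", "AssociationFit", function(object) {
    cat("AssociationFit:", nrow(object@beta), "retained draws",
        if (object@stratified) "(stratified)" else "(unstratified)", "\n")
    cat(sprintf("  posterior mean z: %.3f\n", mean(object@z)))
    if ("cn" %in% colnames(object@beta))
        cat(sprintf("  copy number odds ratio: %.3f\n",
                    exp(mean(object@beta[, "cn"]))))
})

setMethod("show", "SimulationDesign", function(object) {
    cat(sprintf("SimulationDesign: %d samples, %d plates, %d markers\n",
                object@nSamples, object@nPlates, object@nMarkers))
    cat(sprintf("  q=%.2f, delta=%.2f, xi=%.2f\n", object@q, object@delta,
                object@xi))
})
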