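#' @include AllClasses.R
NULL

#' Construct a CNPExperiment from matrices and manifests
#'
#' @param lrr numeric matrix of log2 R ratios, probes x samples.
#' @param baf numeric matrix of B allele frequencies, probes x samples; NA at
#'   nonpolymorphic probes.
#' @param probes data.frame with columns \code{probe_id}, \code{chrom},
#'   \code{pos}, \code{gc}, \code{is_snp}.
#' @param samples data.frame with a \code{sample_id} column plus annotation
#'   (plate, site, case, age, male, pc1..pc3, high_quality as available).
#' @return A \linkS4class{CNPExperiment}.
#' @export
CNPExperiment <- function(lrr, baf, probes, samples) {
    stopifnot(identical(dim(lrr), dim(baf)),
              nrow(lrr) == nrow(probes), ncol(lrr) == nrow(samples))
    o <- order(probes$chrom, probes$pos)
    probes <- probes[o, , drop = FALSE]
    lrr <- lrr[o, , drop = FALSE]
    baf <- baf[o, , drop = FALSE]
    rr <- GRanges(probes$chrom, IRanges(probes$pos, probes$pos))
    S4Vectors::mcols(rr) <- DataFrame(probe_id = probes$probe_id,
                                      gc = probes$gc, is_snp = probes$is_snp)
    names(rr) <- probes$probe_id
    cd <- DataFrame(samples, row.names = samples$sample_id)
    dimnames(lrr) <- dimnames(baf) <- list(probes$probe_id,
                                           samples$sample_id)
    se <- SummarizedExperiment(assays = list(lrr = lrr, baf = baf),
                               rowRanges = rr, colData = cd)
    new("CNPExperiment", se)
}

#' Read GenomeStudio-style intensity exports
#'
#' Reads tab-delimited matrices of log2 R ratios and B allele frequencies
#' (probe rows, sample columns, first column the probe identifier) and aligns
#' them to the probe and sample manifests. Probes or samples absent from the
#' manifests are dropped with a warning; non-numeric cells become missing
#' values with a warning. A dimension mismatch after alignment is an error.
#'
#' @param pathLrr,pathBaf paths to the two matrices.
#' @param probes,samples manifests as in \code{\link{CNPExperiment}}.
#' @return A \linkS4class{CNPExperiment} in manifest order.
#' @export
readIntensities <- function(pathLrr, pathBaf, probes, samples) {
    readOne <- function(path) {
        d <- utils::read.delim(path, check.names = FALSE,
                               stringsAsFactors = FALSE)
        ids <- as.character(d[[1]])
        m <- as.matrix(d[, -1, drop = FALSE])
        if (!is.numeric(m)) {
            mm <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m),
                                          dimnames = dimnames(m)))
            nbad <- sum(is.na(mm) & !is.na(m) & m != "NA" & m != "",
                        na.rm = TRUE)
            if (nbad > 0)
                warning(nbad, " non-numeric cell(s) in ", path,
                        " set to missing")
            m <- mm
        }
        rownames(m) <- ids
        m
    }
    lrr <- readOne(pathLrr)
    baf <- readOne(pathBaf)
    alignOne <- function(m, what) {
        unknownP <- setdiff(rownames(m), probes$probe_id)
        unknownS <- setdiff(colnames(m), samples$sample_id)
        if (length(unknownP))
            warning(length(unknownP), " unknown probe id(s) dropped from ",
                    what)
        if (length(unknownS))
            warning(length(unknownS), " unknown sample id(s) dropped from ",
                    what)
        if (!all(probes$probe_id %in% rownames(m)) ||
            !all(samples$sample_id %in% colnames(m)))
            stop("matrix ", what,
                 " does not cover all manifest probes/samples")
        m[probes$probe_id, samples$sample_id, drop = FALSE]
    }
    CNPExperiment(alignOne(lrr, "lrr"), alignOne(baf, "baf"), probes, samples)
}

#' Write an intensity matrix in the tab-delimited export dialect
#'
#' @param mat numeric matrix (probes x samples) with dimnames.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeIntensityMatrix <- function(mat, path) {
    # 17 significant digits so values survive the decimal round trip exactly
    txt <- matrix(formatC(mat, digits = 17, format = "g"), nrow(mat),
                  dimnames = dimnames(mat))
    txt[is.na(mat)] <- "NA"
    d <- data.frame(probe_id = rownames(mat), txt, check.names = FALSE,
                    stringsAsFactors = FALSE)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read CNV regions from BED or native TSV
#'
#' BED input (0-based half-open) is converted to the internal 1-based
#' inclusive convention at the boundary, so the record
#' \code{chr4 9370865 9410140} becomes the region spanning
#' 9,370,866-9,410,140 bp. The native TSV dialect (columns \code{region_id},
#' \code{chrom}, \code{start}, \code{end}, optionally \code{source} and
#' \code{n_probes}) is already 1-based inclusive. Records with start > end
#' are rejected.
#'
#' @param path input file; dialect chosen by extension (\code{.bed} vs
#'   anything else).
#' @return A \code{GRanges} with metadata columns \code{region_id},
#'   \code{source} and \code{n_probes}.
#' @export
readRegions <- function(path) {
    if (grepl("\\.bed$", path, ignore.case = TRUE)) {
        n <- length(readLines(path, n = 1L))
        if (n == 0L) return(GRanges())
        gr <- rtracklayer::import(path, format = "BED")
        if (is.null(gr$name) || all(is.na(gr$name)))
            gr$name <- paste0("region_", seq_along(gr))
        out <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)))
        S4Vectors::mcols(out) <- DataFrame(region_id = gr$name,
                                           source = "bed",
                                           n_probes = NA_integer_)
        return(out)
    }
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (nrow(d) == 0L) return(GRanges())
    bad <- d$start > d$end
    if (any(bad)) {
        warning(sum(bad), " region record(s) with start > end rejected")
        d <- d[!bad, , drop = FALSE]
    }
    if (nrow(d) == 0L) return(GRanges())
    out <- GRanges(d$chrom, IRanges(d$start, d$end))
    S4Vectors::mcols(out) <- DataFrame(
        region_id = if (!is.null(d$region_id)) d$region_id else
            paste0("region_", seq_len(nrow(d))),
        source = if (!is.null(d$source)) d$source else "tsv",
        n_probes = if (!is.null(d$n_probes)) as.integer(d$n_probes) else
            NA_integer_)
    # known CNV regions from reference catalogues must span >= 4 markers
    drop <- out$source == "thousand_genomes" & !is.na(out$n_probes) &
        out$n_probes < 4L
    if (any(drop)) {
        warning(sum(drop), " thousand_genomes region(s) with fewer than 4 ",
                "markers dropped")
        out <- out[!drop]
    }
    out
}

#' Summarise a CNV region to one value per sample
#'
#' \code{method = "median"} takes the per-sample median of the log2 R ratios
#' across the probes in the region, ignoring missing values. \code{method =
#' "pc1"} projects the samples x probes submatrix (column mean centred, no
#' scaling) onto its first principal axis; the sign is fixed so the summary
#' correlates positively with the per-sample probe mean, making the
#' orientation deterministic.
#'
#' @param x a \linkS4class{CNPExperiment}.
#' @param region a length-1 \code{GRanges} (with a \code{region_id} column)
#'   naming the region.
#' @param method \code{"median"} (default) or \code{"pc1"}.
#' @return A \linkS4class{RegionSummary}.
#' @export
summarizeRegion <- function(x, region, method = c("median", "pc1")) {
    method <- match.arg(method)
    rid <- if (!is.null(region$region_id)) region$region_id[1] else "region"
    sub <- subsetByOverlaps(x, region)
    if (nrow(sub) == 0L)
        stop("no probes in region ", rid)
    m <- t(assay(sub, "lrr"))           # samples x probes
    vals <- if (method == "median") {
        v <- apply(m, 1, stats::median, na.rm = TRUE)
        v[!is.finite(v)] <- NA_real_
        v
    } else {
        pc1Summary(m)
    }
    cd <- colData(x)
    plate <- if ("plate" %in% names(cd)) as.character(cd$plate) else
        rep("plate1", ncol(x))
    hq <- if ("high_quality" %in% names(cd)) as.logical(cd$high_quality) else
        rep(TRUE, ncol(x))
    new("RegionSummary", regionId = rid, summary = vals, method = method,
        plate = plate, highQuality = hq)
}

# First principal component of a samples x probes matrix, column-centred,
# oriented to correlate positively with per-sample means. Rows with missing
# values are imputed at the column mean for the projection only.
pc1Summary <- function(m) {
    mu <- colMeans(m, na.rm = TRUE)
    mc <- sweep(m, 2, mu)
    allNA <- rowSums(!is.na(mc)) == 0L
    mc[is.na(mc)] <- 0
    sv <- svd(mc, nu = 1, nv = 1)
    v <- sv$u[, 1] * sv$d[1]
    rm0 <- rowMeans(m, na.rm = TRUE)
    if (isTRUE(stats::cor(v[!allNA], rm0[!allNA]) < 0)) v <- -v
    v[allNA] <- NA_real_
    names(v) <- rownames(m)
    v
}

#' Write and read copy number calls
#'
#' Calls are serialized as a TSV of per-sample posterior probability columns
#' \code{cn0..cn4} plus hard calls, with a JSON sidecar (same path with
#' \code{.json} appended) recording the region, the component-to-copy-number
#' mapping and package version.
#'
#' @param calls a \linkS4class{CopyNumberCalls}.
#' @param path output TSV path.
#' @return \code{path} invisibly (writer); a \code{CopyNumberCalls} (reader).
#' @export
writeCalls <- function(calls, path) {
    d <- data.frame(sample_id = calls@sampleId,
                    region_id = calls@regionId,
                    calls@prob,
                    hard_call = calls@hardCall,
                    check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    meta <- list(region_id = calls@regionId,
                 cn_map = as.integer(calls@mapping),
                 package = "CNPmix",
                 version = as.character(utils::packageVersion("CNPmix")))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
    invisible(path)
}

#' @rdname writeCalls
#' @export
readCalls <- function(path) {
    d <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
    meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    new("CopyNumberCalls", regionId = meta$region_id,
        mapping = as.integer(meta$cn_map),
        prob = as.matrix(d[, paste0("cn", 0:4)]),
        hardCall = as.integer(d$hard_call),
        sampleId = as.character(d$sample_id))
}

#' Read an INI-style key=value configuration file
#'
#' Lines of the form \code{key = value}; \code{#} starts a comment; optional
#' \code{[section]} headers prefix keys as \code{section.key}. Values that
#' parse as numbers are returned numeric, \code{true}/\code{false} as logical.
#'
#' @param path configuration file.
#' @return Named list of settings.
#' @export
readConfig <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    out <- list()
    section <- ""
    for (ln in lines[nzchar(lines)]) {
        if (grepl("^\\[.*\\]$", ln)) {
            section <- gsub("^\\[|\\]$", "", ln)
            next
        }
        kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
        if (length(kv) < 2) next
        key <- trimws(kv[1])
        if (nzchar(section)) key <- paste(section, key, sep = ".")
        val <- trimws(paste(kv[-1], collapse = "="))
        num <- suppressWarnings(as.numeric(val))
        out[[key]] <- if (!is.na(num)) num
            else if (tolower(val) %in% c("true", "false"))
                as.logical(toupper(val))
            else val
    }
    out
}
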