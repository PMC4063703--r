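#' Construct a SignalSet
#'
#' @param probes `GRanges` of width-1 probe midpoints (stranded). Probes are
#'   sorted; positions must be unique within a strand.
#' @param values numeric matrix, `length(probes)` rows, one column per array.
#' @param genotype,replicate per-column labels (recycled checks apply).
#' @param floor intensity floor applied to the values (guards later ratios
#'   against division by zero); floored cells are reported via a message.
#' @return A [SignalSet-class].
#' @export
SignalSet <- function(probes, values, genotype, replicate, floor = 1e-6) {
    values <- as.matrix(values)
    stopifnot(length(probes) == nrow(values),
              length(genotype) == ncol(values),
              length(replicate) == ncol(values))
    o <- order(as.factor(seqnames(probes)), start(probes),
               as.character(strand(probes)))
    probes <- probes[o]
    values <- values[o, , drop = FALSE]
    nlow <- sum(values < floor)
    if (nlow > 0L) {
        message(nlow, " intensities below floor ", floor, " were floored")
        values[values < floor] <- floor
    }
    colnames(values) <- paste(genotype, replicate, sep = "_")
    se <- SummarizedExperiment(
        assays = list(signal = values),
        rowRanges = probes,
        colData = DataFrame(genotype = as.character(genotype),
                            replicate = as.integer(replicate),
                            row.names = colnames(values)))
    new("SignalSet", se)
}

setMethod("show", "SignalSet", function(object) {
    cd <- colData(object)
    cat(sprintf("SignalSet: %d probes x %d arrays (%s)\n",
                nrow(object), ncol(object),
                paste(sprintf("%s x%d", names(table(cd$genotype)),
                              table(cd$genotype)), collapse = ", ")))
})

#' @rdname SignalSet
#' @param x a `SignalSet`.
#' @export
trackInfo <- function(x) as.data.frame(colData(x))

#' @rdname SignalSet
#' @export
probeRanges <- function(x) rowRanges(x)

.genotypeCols <- function(set, genotype) {
    j <- which(colData(set)$genotype == genotype)
    if (!length(j)) stop("no arrays with genotype '", genotype, "'")
    j
}

## ---- long-format TSV I/O ---------------------------------------------------

#' Read / write strand-specific signal in long TSV format
#'
#' Columns: `chrom`, `position`, `strand`, `genotype`, `replicate`, `value`.
#' All tracks must share the probe grid of their strand. `writeSignalTSV`
#' emits rows in a deterministic order (arrays in column order, probes in
#' genomic order), so writing a set twice gives byte-identical files;
#' `readSignalTSV` keeps the genotype order of first appearance (the first
#' genotype plays the reference role downstream).
#'
#' @param path TSV file.
#' @return `readSignalTSV`: a [SignalSet-class]; `writeSignalTSV`: the path,
#'   invisibly.
#' @export
readSignalTSV <- function(path) {
    d <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    need <- c("chrom", "position", "strand", "genotype", "replicate", "value")
    if (!all(need %in% colnames(d)))
        stop("signal TSV must have columns: ", paste(need, collapse = ", "))
    track <- paste(d$genotype, d$replicate, sep = "_")
    probe <- paste(d$chrom, d$position, d$strand)
    grid <- sort(unique(probe))
    tracks <- unique(track)    # order of first appearance: genotype order is meaningful
    m <- matrix(NA_real_, length(grid), length(tracks),
                dimnames = list(grid, tracks))
    m[cbind(match(probe, grid), match(track, tracks))] <- d$value
    if (anyNA(m))
        stop("tracks do not share a common probe grid (",
             sum(is.na(m)), " missing probe/track combinations)")
    first <- match(grid, probe)
    probes <- GRanges(d$chrom[first], IRanges(d$position[first], width = 1L),
                      strand = d$strand[first])
    first_track <- match(tracks, track)
    SignalSet(probes, m, genotype = d$genotype[first_track],
              replicate = d$replicate[first_track])
}

#' @rdname readSignalTSV
#' @param set a [SignalSet-class].
#' @export
writeSignalTSV <- function(set, path) {
    rr <- rowRanges(set)
    cd <- colData(set)
    x <- assay(set, "signal")
    blocks <- lapply(seq_len(ncol(set)), function(j)
        data.frame(chrom = as.character(seqnames(rr)), position = start(rr),
                   strand = as.character(strand(rr)),
                   genotype = cd$genotype[j], replicate = cd$replicate[j],
                   value = x[, j], stringsAsFactors = FALSE))
    d <- do.call(rbind, blocks)   # arrays in column order, probes pre-sorted
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

## ---- normalization ---------------------------------------------------------

#' Quantile-normalize all tracks of a signal set
#'
#' Every track (one strand of one array) is forced onto the common
#' distribution given by the across-track mean of order statistics; ranks
#' within a track are preserved and ties receive the mean of the tied
#' quantile values. Idempotent; after normalization the sorted value vectors
#' of all tracks are identical.
#'
#' @param set a [SignalSet-class]; when both strands are present they must
#'   have equal probe counts (the tracks are normalized jointly).
#' @param floor intensity floor re-applied after normalization.
#' @return A normalized [SignalSet-class].
#' @export
quantileNormalize <- function(set, floor = 1e-6) {
    rr <- rowRanges(set)
    s <- as.character(strand(rr))
    strands <- unique(s)
    idx <- lapply(strands, function(z) which(s == z))
    n_per <- lengths(idx)
    if (length(unique(n_per)) != 1L)
        stop("unequal probe counts across strands (",
             paste(n_per, collapse = " vs "), "): cannot normalize jointly")
    if (length(strands) * ncol(set) < 2L)
        stop("need at least 2 tracks to quantile-normalize")
    m <- do.call(cbind, lapply(idx, function(ix) assay(set, "signal")[ix, , drop = FALSE]))
    qn <- limma::normalizeQuantiles(m, ties = TRUE)
    out <- assay(set, "signal")
    for (k in seq_along(strands))
        out[idx[[k]], ] <- qn[, (k - 1L) * ncol(set) + seq_len(ncol(set))]
    out[out < floor] <- floor
    res <- set
    SummarizedExperiment::assay(res, "signal") <- out
    res
}

## ---- region summarization --------------------------------------------------

# per-gene, per-column region statistic; ranges is a GRanges parallel to the
# genes of interest (strand-aware probe membership by midpoint)
.regionStatByGene <- function(set, ranges, stat = c("mean", "median")) {
    stat <- match.arg(stat)
    f <- if (stat == "mean") mean else stats::median
    x <- assay(set, "signal")
    ov <- findOverlaps(ranges, rowRanges(set))
    rows <- split(S4Vectors::subjectHits(ov),
                  factor(S4Vectors::queryHits(ov), levels = seq_along(ranges)))
    out <- matrix(NA_real_, length(ranges), ncol(set),
                  dimnames = list(NULL, colnames(x)))
    for (i in seq_along(ranges)) {
        ix <- rows[[i]]
        if (length(ix))
            out[i, ] <- apply(x[ix, , drop = FALSE], 2L, f)
    }
    out
}

#' Summarize signal over a region
#'
#' The chosen statistic of the intensities of probes whose midpoints fall in
#' the region, on the region's strand. Returns `NA` (a flagged missing value,
#' not an error) when no probe falls in the region.
#'
#' @param set a [SignalSet-class].
#' @param region a single stranded `GRanges` interval.
#' @param stat `"mean"` or `"median"`.
#' @param genotype,replicate optional track selection; when omitted, a named
#'   vector with one value per array is returned.
#' @return Numeric scalar (track selected) or named vector.
#' @export
regionSignal <- function(set, region, stat = c("mean", "median"),
                         genotype = NULL, replicate = NULL) {
    stopifnot(length(region) == 1L)
    v <- .regionStatByGene(set, region, match.arg(stat))[1L, ]
    cd <- colData(set)
    keep <- rep(TRUE, ncol(set))
    if (!is.null(genotype)) keep <- keep & cd$genotype == genotype
    if (!is.null(replicate)) keep <- keep & cd$replicate == replicate
    v <- v[keep]
    if (length(v) == 1L) unname(v) else v
}

#' Gene expression: median over probes, mean over replicates
#'
#' For each gene, the median of the intensities of in-span probes on the
#' gene's own strand is computed per replicate, and the replicate medians are
#' averaged. A gene with no probe in any replicate is flagged unmeasured
#' (`NA`).
#'
#' @param set a [SignalSet-class].
#' @param annotation a [GenomeAnnotation-class].
#' @param genotype genotype label to summarize.
#' @param ids genes to report (default all).
#' @param region `"span"` (ORF plus UTRs, the default) or `"orf"`.
#' @return Named numeric vector of expression values.
#' @export
geneExpression <- function(set, annotation, genotype, ids = NULL,
                           region = c("span", "orf")) {
    region <- match.arg(region)
    all_ids <- geneIds(annotation)
    if (is.null(ids)) ids <- all_ids
    i <- match(ids, all_ids)
    if (anyNA(i)) stop("unknown gene_id: ", paste(ids[is.na(i)], collapse = ", "))
    gr <- if (region == "span") annotation@genes[i] else annotation@orf[i]
    m <- .regionStatByGene(set, gr, "median")
    j <- .genotypeCols(set, genotype)
    stats::setNames(rowMeans(m[, j, drop = FALSE]), ids)
}
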