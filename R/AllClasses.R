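#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges findOverlaps granges strand seqnames start
#'   end width reduce
#' @importFrom GenomeInfoDb seqinfo seqlengths seqlevels Seqinfo
#' @importFrom SummarizedExperiment SummarizedExperiment rowRanges colData
#'   assay assayNames
NULL

#' Genome annotation: gene models queryable by id and interval
#'
#' Container for one gene model per gene: the coding interval (`orf`),
#' optional 5'/3' UTRs, and the gene span (union of ORF and UTRs). All
#' components of a gene share chromosome and strand, UTRs abut the ORF on the
#' appropriate side, and gene identifiers are unique. Chromosome lengths are
#' carried in the `Seqinfo` of the `genes` slot.
#'
#' @slot genes `GRanges` of gene spans with metadata columns `gene_id`,
#'   `biotype`, `has_utr5`, `has_utr3`.
#' @slot orf `GRanges` of coding intervals, parallel to `genes`, with
#'   metadata column `gene_id`.
#' @slot utr5,utr3 `GRanges` of UTR intervals (only for genes that have
#'   them), with metadata column `gene_id`.
#'
#' @seealso [annotationFromTable()], [readGFF3()]
#' @export
setClass("GenomeAnnotation",
    slots = c(genes = "GRanges", orf = "GRanges",
              utr5 = "GRanges", utr3 = "GRanges"))

setValidity("GenomeAnnotation", function(object) {
    g <- object@genes
    msg <- character()
    need <- c("gene_id", "biotype")
    if (!all(need %in% colnames(mcols(g))))
        return("slot 'genes' must carry metadata columns gene_id and biotype")
    ids <- mcols(g)$gene_id
    if (anyNA(ids) || any(!nzchar(ids)))
        msg <- c(msg, "gene_id must be non-empty")
    if (anyDuplicated(ids))
        msg <- c(msg, sprintf("duplicated gene_id: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    o <- object@orf
    if (length(o) != length(g) || !identical(mcols(o)$gene_id, ids))
        msg <- c(msg, "slot 'orf' must be parallel to 'genes' (same gene_id order)")
    if (length(o) == length(g)) {
        same <- as.character(seqnames(o)) == as.character(seqnames(g)) &
                as.character(strand(o)) == as.character(strand(g))
        if (!all(same))
            msg <- c(msg, "orf and span must share chromosome and strand")
        if (any(start(o) < start(g) | end(o) > end(g)))
            msg <- c(msg, "span must contain orf")
    }
    for (side in c("utr5", "utr3")) {
        u <- slot(object, side)
        if (length(u) == 0L) next
        j <- match(mcols(u)$gene_id, ids)
        if (anyNA(j)) { msg <- c(msg, sprintf("%s refers to unknown gene_id", side)); next }
        if (any(as.character(seqnames(u)) != as.character(seqnames(g))[j]) ||
            any(as.character(strand(u)) != as.character(strand(g))[j])) {
            msg <- c(msg, sprintf("%s must share chromosome and strand with its gene", side))
            next
        }
        plus <- as.character(strand(u)) == "+"
        left_of_orf <- xor(side == "utr3", plus)   # utr5 left of ORF on +, right on -
        ok_abut <- ifelse(left_of_orf,
                          end(u) == start(object@orf)[j] - 1L,
                          start(u) == end(object@orf)[j] + 1L)
        if (!all(ok_abut))
            msg <- c(msg, sprintf("%s must abut the ORF on the gene's %s side",
                                  side, if (side == "utr3") "3'" else "5'"))
    }
    sl <- seqlengths(g)
    if (length(g) && any(!is.na(sl))) {
        len <- sl[as.character(seqnames(g))]
        bad <- !is.na(len) & (start(g) < 1L | end(g) > len)
        if (any(bad))
            msg <- c(msg, sprintf("gene(s) outside chromosome bounds: %s",
                     paste(ids[bad], collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' Strand-specific tiling signal set
#'
#' A `RangedSummarizedExperiment` whose rows are probe positions (width-1
#' ranges at the probe midpoint, stranded) and whose columns are arrays
#' (genotype x replicate). The assay `"signal"` holds linear-scale,
#' non-negative intensities. A *track* in the sense of the analysis is the
#' restriction of one column to one strand.
#'
#' @seealso [SignalSet()], [quantileNormalize()], [geneExpression()]
#' @export
setClass("SignalSet", contains = "RangedSummarizedExperiment")

setValidity("SignalSet", function(object) {
    msg <- character()
    if (!"signal" %in% assayNames(object))
        return("assay 'signal' is required")
    cd <- colData(object)
    if (!all(c("genotype", "replicate") %in% colnames(cd)))
        return("colData must contain 'genotype' and 'replicate'")
    rr <- rowRanges(object)
    if (any(width(rr) != 1L))
        msg <- c(msg, "probes must be width-1 positions (probe midpoints)")
    key <- paste(as.character(seqnames(rr)), start(rr), as.character(strand(rr)))
    if (anyDuplicated(key))
        msg <- c(msg, "probe positions must be unique per strand")
    tab <- table(as.character(cd$genotype))
    if (length(tab) > 1L && length(unique(tab)) != 1L)
        msg <- c(msg, "replicate counts must be equal across genotypes")
    x <- assay(object, "signal")
    if (length(x) && (any(!is.finite(x)) || any(x < 0)))
        msg <- c(msg, "signal intensities must be finite and non-negative")
    if (length(msg)) msg else TRUE
})

#' AP-MS unique-peptide count matrix
#'
#' Long-format store of unique-peptide counts indexed by
#' (bait, genotype background, prey). The optional no-tag control purification
#' is a bait named by `controlBait`; [filterNonspecific()] removes every prey
#' recovered in it.
#'
#' @slot counts `data.frame` with columns `bait`, `background`, `prey`,
#'   `peptides` (non-negative integers), one row per combination.
#' @slot controlBait name of the no-tag control bait, or `NA_character_`.
#' @slot removedPreys preys removed by [filterNonspecific()] (empty before
#'   filtering).
#'
#' @seealso [PeptideMatrix()], [inferDependencies()]
#' @export
setClass("PeptideMatrix",
    slots = c(counts = "data.frame", controlBait = "character",
              removedPreys = "character"))

setValidity("PeptideMatrix", function(object) {
    df <- object@counts
    need <- c("bait", "background", "prey", "peptides")
    if (!all(need %in% colnames(df)))
        return("counts must have columns bait, background, prey, peptides")
    msg <- character()
    p <- df$peptides
    if (length(p) && (any(!is.finite(p)) || any(p < 0) || any(p != round(p))))
        msg <- c(msg, "peptide counts must be non-negative integers")
    if (anyDuplicated(df[c("bait", "background", "prey")]))
        msg <- c(msg, "duplicated (bait, background, prey) entries")
    if (length(object@controlBait) != 1L)
        msg <- c(msg, "controlBait must be a single string (or NA)")
    if (length(msg)) msg else TRUE
})
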