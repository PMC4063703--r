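#' 3'UTR/ORF signal ratio for one gene and genotype
#'
#' Per replicate, the ratio of the average probe signal in the annotated
#' 3'UTR to the average probe signal in the ORF (same-strand probes only);
#' the replicate ratios are then averaged. A value near 1 means signal
#' continues at ORF level into the UTR; values rising between genotypes
#' indicate read-through past the normal termination site.
#'
#' @param set a [SignalSet-class].
#' @param annotation a [GenomeAnnotation-class].
#' @param geneId gene with an annotated 3'UTR.
#' @param genotype genotype label.
#' @param stat per-region probe statistic, `"mean"` (default) or `"median"`.
#' @return Positive ratio, or `NA` if either region has no probe.
#' @export
utrOrfRatio <- function(set, annotation, geneId, genotype,
                        stat = c("mean", "median")) {
    stat <- match.arg(stat)
    i <- .geneIndex(annotation, geneId)
    ids3 <- mcols(annotation@utr3)$gene_id
    if (!geneId %in% ids3)
        stop("gene '", geneId, "' has no annotated 3'UTR")
    utr <- .regionStatByGene(set, annotation@utr3[match(geneId, ids3)], stat)
    orf <- .regionStatByGene(set, annotation@orf[i], stat)
    j <- .genotypeCols(set, genotype)
    mean(utr[1L, j] / orf[1L, j])
}

#' Call transcription-termination read-through (the gTERM set)
#'
#' For every gene with an annotated 3'UTR and probes in both regions, the
#' 3'UTR/ORF ratio is computed in each genotype ([utrOrfRatio()]); a gene is
#' flagged `is_gterm` when the mutant ratio is at least `rrThreshold` times
#' the reference ratio (inclusive) *and* its coding region shows no
#' expression difference (not called under/over on the ORF interval).
#'
#' @param set a normalized [SignalSet-class].
#' @param annotation a [GenomeAnnotation-class].
#' @param de ORF-level differential-expression table used as the
#'   "no difference in the coding region" gate; computed via
#'   `callDE(..., region = "orf")` when `NULL`.
#' @param rrThreshold ratio-of-ratios threshold (default 1.5).
#' @param stat per-region probe statistic (default `"mean"`).
#' @param reference,treatment genotype labels (defaults as in [callDE()]).
#' @param ... further arguments passed to [callDE()] when `de` is `NULL`.
#' @return data.frame with columns `gene_id`, `ratio_wt`, `ratio_mut`,
#'   `ratio_of_ratios`, `orf_unchanged`, `is_gterm`, ordered by `gene_id`;
#'   ineligible genes (no 3'UTR or empty probe region) are excluded.
#' @export
callReadthrough <- function(set, annotation, de = NULL, rrThreshold = 1.5,
                            stat = c("mean", "median"),
                            reference = NULL, treatment = NULL, ...) {
    stat <- match.arg(stat)
    stopifnot(rrThreshold > 1)
    gts <- unique(colData(set)$genotype)
    if (is.null(reference)) reference <- gts[1L]
    if (is.null(treatment)) treatment <- setdiff(gts, reference)[1L]
    if (is.null(de))
        de <- callDE(set, annotation, region = "orf",
                     reference = reference, treatment = treatment, ...)

    ids3 <- sort(mcols(annotation@utr3)$gene_id)
    k3 <- match(ids3, mcols(annotation@utr3)$gene_id)
    ki <- match(ids3, geneIds(annotation))
    utr <- .regionStatByGene(set, annotation@utr3[k3], stat)
    orf <- .regionStatByGene(set, annotation@orf[ki], stat)
    ratio <- utr / orf
    jr <- .genotypeCols(set, reference)
    jt <- .genotypeCols(set, treatment)
    ratio_wt <- rowMeans(ratio[, jr, drop = FALSE])
    ratio_mut <- rowMeans(ratio[, jt, drop = FALSE])
    eligible <- !is.na(ratio_wt) & !is.na(ratio_mut)
    n_dropped <- sum(!eligible)
    if (n_dropped)
        message(n_dropped, " gene(s) excluded from read-through analysis: ",
                "no probes in 3'UTR or ORF")
    orf_unchanged <- de$call[match(ids3, de$gene_id)] == "unchanged"
    rr <- ratio_mut / ratio_wt
    res <- data.frame(gene_id = ids3, ratio_wt = ratio_wt,
                      ratio_mut = ratio_mut, ratio_of_ratios = rr,
                      orf_unchanged = orf_unchanged,
                      is_gterm = rr >= rrThreshold & orf_unchanged,
                      stringsAsFactors = FALSE, row.names = NULL)
    res[eligible, , drop = FALSE]
}

#' Size-normalized RT-PCR band ratio
#'
#' `(band intensity / band size) / (reference intensity / reference size)`:
#' normalizes each amplicon's band intensity by its length before taking the
#' ratio to the internal loading-control band, so amplicons of different
#' sizes are comparable.
#'
#' @param intensity,size_bp band intensity (arbitrary units) and amplicon
#'   length of the band(s) of interest (vectorized).
#' @param ref_intensity,ref_size_bp same for the reference band.
#' @return Ratio(s).
#' @export
bandRatio <- function(intensity, size_bp, ref_intensity, ref_size_bp) {
    if (any(size_bp <= 0) || any(ref_size_bp <= 0))
        stop("band sizes must be positive")
    if (any(intensity < 0)) stop("band intensities must be non-negative")
    if (any(ref_intensity <= 0)) stop("reference band intensity must be positive")
    (intensity / size_bp) / (ref_intensity / ref_size_bp)
}

#' @rdname bandRatio
#' @param path 3-column TSV (`label`, `intensity`, `size_bp`).
#' @param reference label of the reference band (default `"R1"`).
#' @return `bandRatioTable`: data.frame with `label` and `ratio` columns.
#' @export
bandRatioTable <- function(path, reference = "R1") {
    d <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    stopifnot(all(c("label", "intensity", "size_bp") %in% colnames(d)))
    r <- match(reference, d$label)
    if (is.na(r)) stop("reference band '", reference, "' not found")
    data.frame(label = d$label,
               ratio = bandRatio(d$intensity, d$size_bp,
                                 d$intensity[r], d$size_bp[r]),
               stringsAsFactors = FALSE)
}
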