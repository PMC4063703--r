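#' Signed fold change between two expression values
#'
#' The signed-FC convention used with thresholds such as "FC <= -1.9": the
#' ratio `mut/wt` when the mutant value is the larger, and `-(wt/mut)`
#' otherwise, so the magnitude is always >= 1 and
#' `signedFoldChange(a, b) == -signedFoldChange(b, a)` whenever `a != b`.
#'
#' @param expr_wt,expr_mut positive expression values (vectorized).
#' @return Signed fold change(s), `|fc| >= 1`.
#' @export
signedFoldChange <- function(expr_wt, expr_mut) {
    if (any(!is.finite(expr_wt) | !is.finite(expr_mut)) ||
        any(expr_wt <= 0 | expr_mut <= 0))
        stop("expression values must be positive (apply an intensity floor upstream)")
    ifelse(expr_mut >= expr_wt, expr_mut / expr_wt, -(expr_wt / expr_mut))
}

.tLog2P <- function(a, b, var.equal = TRUE) {
    # a, b: linear per-replicate values; t-test on log2 scale
    la <- log2(a); lb <- log2(b)
    if (stats::sd(la) == 0 && stats::sd(lb) == 0) {
        # degenerate zero-variance groups (e.g. noise-free simulations)
        return(if (isTRUE(all.equal(mean(la), mean(lb)))) 1 else 0)
    }
    tryCatch(stats::t.test(lb, la, var.equal = var.equal)$p.value,
             error = function(e) NA_real_)
}

.ranksumP <- function(a, b)
    suppressWarnings(stats::wilcox.test(b, a, exact = FALSE)$p.value)

#' Call differential expression between two genotypes
#'
#' For every measurable gene, the per-replicate gene value (median of in-span
#' probes, see [geneExpression()]) is computed; expressions are the replicate
#' means, the fold change is [signedFoldChange()], and the p-value comes from
#' the configured test on the per-replicate values (Welch t on log2 scale by
#' default; Welch t and rank-sum as alternatives -- at triplicate sample
#' sizes the pooled t holds its nominal size, whereas Welch is markedly
#' conservative). A gene is called `under` when
#' `fc <= -fcThreshold` (inclusive) and `p < alpha`, `over` symmetrically,
#' `unmeasured` when any replicate lacks probes, else `unchanged`.
#'
#' @param set a normalized [SignalSet-class] with >= 2 replicates per genotype.
#' @param annotation a [GenomeAnnotation-class].
#' @param fcThreshold positive fold-change threshold (default 1.9).
#' @param alpha significance level (default 0.01).
#' @param test `"t_on_log2"` (pooled variance, default), `"welch_t_on_log2"`
#'   or `"wilcoxon_ranksum"`.
#' @param region gene region summarized: `"span"` (default) or `"orf"`.
#' @param reference,treatment genotype labels; default to the first and second
#'   genotype present in the set (reference plays the wild-type role).
#' @param adjust `"none"` (default, raw p as reported in this analysis style)
#'   or `"BH"` for Benjamini-Hochberg; when `"BH"`, calls use adjusted p.
#' @return data.frame with columns `gene_id`, `expr_wt`, `expr_mut`, `fc`,
#'   `p`, `call`, `biotype`, ordered by `gene_id`.
#' @export
callDE <- function(set, annotation, fcThreshold = 1.9, alpha = 0.01,
                   test = c("t_on_log2", "welch_t_on_log2", "wilcoxon_ranksum"),
                   region = c("span", "orf"),
                   reference = NULL, treatment = NULL,
                   adjust = c("none", "BH")) {
    test <- match.arg(test)
    region <- match.arg(region)
    adjust <- match.arg(adjust)
    stopifnot(fcThreshold > 1, alpha > 0, alpha < 1)
    gts <- unique(colData(set)$genotype)
    if (is.null(reference)) reference <- gts[1L]
    if (is.null(treatment)) treatment <- setdiff(gts, reference)[1L]
    jr <- .genotypeCols(set, reference)
    jt <- .genotypeCols(set, treatment)
    if (length(jr) < 2L || length(jt) < 2L)
        stop("need >= 2 replicates per genotype for a within-group variance")

    ids <- geneIds(annotation)
    o <- order(ids)
    ids <- ids[o]
    gr <- if (region == "span") annotation@genes[o] else annotation@orf[o]
    m <- .regionStatByGene(set, gr, "median")
    pfun <- switch(test,
        t_on_log2 = function(a, b) .tLog2P(a, b, var.equal = TRUE),
        welch_t_on_log2 = function(a, b) .tLog2P(a, b, var.equal = FALSE),
        wilcoxon_ranksum = .ranksumP)
    expr_wt <- rowMeans(m[, jr, drop = FALSE])
    expr_mut <- rowMeans(m[, jt, drop = FALSE])
    measured <- !is.na(expr_wt) & !is.na(expr_mut)
    p <- rep(NA_real_, length(ids))
    p[measured] <- vapply(which(measured),
                          function(i) pfun(m[i, jr], m[i, jt]), numeric(1))
    p_call <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
    fc <- rep(NA_real_, length(ids))
    fc[measured] <- signedFoldChange(expr_wt[measured], expr_mut[measured])
    call <- rep("unchanged", length(ids))
    call[measured & fc <= -fcThreshold & !is.na(p_call) & p_call < alpha] <- "under"
    call[measured & fc >= fcThreshold & !is.na(p_call) & p_call < alpha] <- "over"
    call[!measured] <- "unmeasured"
    res <- data.frame(gene_id = ids, expr_wt = expr_wt, expr_mut = expr_mut,
                      fc = fc, p = p, call = call,
                      biotype = mcols(annotation@genes)$biotype[o],
                      stringsAsFactors = FALSE, row.names = NULL)
    if (adjust == "BH") res$p_adj <- p_call
    res
}
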