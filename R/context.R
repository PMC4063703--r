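#' Intergenic distance to the upstream same-strand neighbour (IGR)
#'
#' Signed gap, in bp, between the 3' end of the upstream same-strand partner
#' (its 3'UTR end when annotated, since gene spans include UTRs) and the 5'
#' end of the focal gene: 0 when abutting, negative when the spans overlap.
#'
#' @param annotation a [GenomeAnnotation-class].
#' @param pairing a `gene_pairing` with relation `"upstream_same_strand"`
#'   (from [upstreamSameStrandPartner()]).
#' @return Signed integer bp.
#' @export
igrDistance <- function(annotation, pairing) {
    stopifnot(inherits(pairing, "gene_pairing"))
    if (pairing$relation != "upstream_same_strand")
        stop("igrDistance requires an upstream_same_strand pairing")
    .checkSameChrom(annotation, pairing)
    pairing$distance_bp
}

#' Intergenic distance to the downstream reverse-oriented gene (IGRterm)
#'
#' Signed gap between the focal gene's 3' end and the 3'-end-facing boundary
#' of the first downstream gene in reverse orientation, measured on gene
#' spans; negative exactly when the two spans overlap (convergent
#' overlapping genes).
#'
#' @param annotation a [GenomeAnnotation-class].
#' @param pairing a `gene_pairing` with relation `"downstream_reverse"`
#'   (from [downstreamReversePartner()]).
#' @return Signed integer bp.
#' @export
igrTermDistance <- function(annotation, pairing) {
    stopifnot(inherits(pairing, "gene_pairing"))
    if (pairing$relation != "downstream_reverse")
        stop("igrTermDistance requires a downstream_reverse pairing")
    .checkSameChrom(annotation, pairing)
    pairing$distance_bp
}

.checkSameChrom <- function(annotation, pairing) {
    g <- annotation@genes
    ids <- geneIds(annotation)
    ch <- as.character(seqnames(g))
    if (ch[.geneIndex(annotation, pairing$focal)] !=
        ch[.geneIndex(annotation, pairing$partner)])
        stop("invalid pairing: genes on different chromosomes")
    invisible(TRUE)
}

#' Fraction of a gene covered by antisense transcription (F_as)
#'
#' [antisenseOverlapBp()] divided by the gene span length; in `[0, 1]`.
#'
#' @inheritParams antisenseOverlapBp
#' @return Fraction in `[0, 1]`.
#' @export
antisenseFraction <- function(annotation, geneId) {
    i <- .geneIndex(annotation, geneId)
    antisenseOverlapBp(annotation, geneId) / width(annotation@genes)[i]
}

#' Per-gene genomic-context observations
#'
#' Computes, for every gene of the annotation, one of the context quantities:
#' `igr` (distance to the upstream same-strand neighbour), `igr_term`
#' (distance to the first downstream reverse-oriented gene) or `f_as`
#' (fraction covered by antisense transcription). Genes without the relevant
#' partner get `NA` and are excluded from permutation universes downstream.
#'
#' @param annotation a [GenomeAnnotation-class].
#' @param quantity one of `"igr"`, `"igr_term"`, `"f_as"`.
#' @param biotype optional biotype stratum to restrict the universe to.
#' @return data.frame with columns `gene_id`, `quantity`, `value`.
#' @export
contextObservations <- function(annotation,
                                quantity = c("igr", "igr_term", "f_as"),
                                biotype = NULL) {
    quantity <- match.arg(quantity)
    ids <- geneIds(annotation)
    if (!is.null(biotype))
        ids <- ids[mcols(annotation@genes)$biotype %in% biotype]
    val <- switch(quantity,
        igr = vapply(ids, function(g) {
            p <- upstreamSameStrandPartner(annotation, g)
            if (is.null(p)) NA_real_ else as.numeric(p$distance_bp)
        }, numeric(1)),
        igr_term = vapply(ids, function(g) {
            p <- downstreamReversePartner(annotation, g)
            if (is.null(p)) NA_real_ else as.numeric(p$distance_bp)
        }, numeric(1)),
        f_as = .antisenseFractionAll(annotation, ids))
    data.frame(gene_id = ids, quantity = quantity, value = unname(val),
               stringsAsFactors = FALSE, row.names = NULL)
}

# vectorized F_as: reduce opposite-strand cover once per (chrom, strand)
.antisenseFractionAll <- function(annotation, ids) {
    g <- annotation@genes
    i <- match(ids, geneIds(annotation))
    ch <- as.character(seqnames(g)); s <- as.character(strand(g))
    out <- numeric(length(i))
    for (key in unique(paste(ch[i], s[i]))) {
        parts <- strsplit(key, " ")[[1L]]
        sel <- which(ch[i] == parts[1L] & s[i] == parts[2L])
        opp <- which(ch == parts[1L] & s != parts[2L])
        if (!length(opp)) { out[sel] <- 0; next }
        cover <- reduce(IRanges(start(g)[opp], end(g)[opp]))
        foc <- IRanges(start(g)[i[sel]], end(g)[i[sel]])
        ov <- IRanges::findOverlaps(foc, cover)
        w <- width(IRanges::pintersect(foc[S4Vectors::queryHits(ov)],
                                       cover[S4Vectors::subjectHits(ov)]))
        covered <- tapply(w, factor(S4Vectors::queryHits(ov),
                                    levels = seq_along(foc)), sum)
        covered[is.na(covered)] <- 0
        out[sel] <- as.numeric(covered) / width(foc)
    }
    out
}

## ---- permutation test ------------------------------------------------------

#' Permutation test of a gene-set median against random gene sets
#'
#' Compares the median of a per-gene quantity over an observed gene set with
#' the empirical null distribution of medians over random gene sets of the
#' same size drawn (without replacement within a set) from the universe of
#' genes with a defined value. In `"exhaustive"` mode all subsets are
#' enumerated (guarded to at most 10^6 subsets) and p-values are exact
#' (`k / n_subsets`); in `"sampled"` mode (default) `nRandomSets` independent
#' sets are drawn and the add-one estimate `(k + 1) / (n + 1)` is reported,
#' together with the reporting-style bound `"< 1/n"` when no null median is
#' as extreme as the observed one. Ties between a null median and the
#' observed statistic count as extreme on both sides (conservative).
#'
#' @param values named numeric vector: the quantity per gene (names are gene
#'   ids); `NA` values are removed from the universe (with a message).
#' @param observed character vector of gene ids forming the observed set.
#' @param nRandomSets number of random sets in sampled mode (default 10000).
#' @param setSize size of each random set (default: size of the observed set).
#' @param seed integer seed; in sampled mode an unset seed is drawn and
#'   reported via a message so the run stays reproducible.
#' @param mode `"sampled"` or `"exhaustive"`.
#' @param alternative direction of the reported `p` / `p_report`: `"less"`
#'   (observed median unusually small, the default) or `"greater"`.
#' @return An object of class `"context_test"`: a list with `observed_stat`,
#'   `null_stats`, `k_le`, `k_ge`, `p_le`, `p_ge`, `p`, `p_report`, `mode`,
#'   `n_sets`, `set_size`, `universe_size`, `seed`.
#' @export
permutationMedianTest <- function(values, observed, nRandomSets = 10000L,
                                  setSize = length(observed), seed = NULL,
                                  mode = c("sampled", "exhaustive"),
                                  alternative = c("less", "greater")) {
    mode <- match.arg(mode)
    alternative <- match.arg(alternative)
    if (is.null(names(values))) stop("'values' must be named by gene id")
    if (anyNA(values)) {
        message(sum(is.na(values)),
                " gene(s) without a defined value excluded from the universe")
        values <- values[!is.na(values)]
    }
    missing <- setdiff(observed, names(values))
    if (length(missing))
        stop("observed genes without a value in the universe: ",
             paste(missing, collapse = ", "))
    stopifnot(setSize >= 1L, setSize <= length(values), nRandomSets >= 1L)
    obs <- stats::median(values[observed])
    v <- unname(values)
    N <- length(v)

    if (mode == "exhaustive") {
        n_sub <- choose(N, setSize)
        if (n_sub > 1e6)
            stop("exhaustive mode limited to <= 1e6 subsets (requested ",
                 format(n_sub, big.mark = ","), ")")
        idx <- utils::combn(N, setSize)
        null_stats <- apply(idx, 2L, function(j) stats::median(v[j]))
        n <- length(null_stats)
        k_le <- sum(null_stats <= obs); k_ge <- sum(null_stats >= obs)
        p_le <- k_le / n; p_ge <- k_ge / n
    } else {
        if (is.null(seed)) {
            seed <- sample.int(.Machine$integer.max, 1L)
            message("no seed supplied; using generated seed ", seed)
        }
        set.seed(seed)
        null_stats <- vapply(seq_len(nRandomSets),
                             function(i) stats::median(v[sample.int(N, setSize)]),
                             numeric(1))
        n <- nRandomSets
        k_le <- sum(null_stats <= obs); k_ge <- sum(null_stats >= obs)
        p_le <- (k_le + 1) / (n + 1); p_ge <- (k_ge + 1) / (n + 1)
    }
    k <- if (alternative == "less") k_le else k_ge
    p <- if (alternative == "less") p_le else p_ge
    p_report <- if (k == 0L) sprintf("< 1/%d", n) else sprintf("%.4g", p)
    structure(list(observed_stat = obs, null_stats = null_stats,
                   k_le = k_le, k_ge = k_ge, p_le = p_le, p_ge = p_ge,
                   p = p, p_report = p_report, alternative = alternative,
                   mode = mode, n_sets = n, set_size = setSize,
                   universe_size = N, seed = seed),
              class = "context_test")
}

#' @export
print.context_test <- function(x, ...) {
    cat(sprintf("Permutation median test (%s mode, %d sets of %d from %d genes)\n",
                x$mode, x$n_sets, x$set_size, x$universe_size))
    cat(sprintf("  observed median: %g | null range: [%g, %g]\n",
                x$observed_stat, min(x$null_stats), max(x$null_stats)))
    cat(sprintf("  k_le = %d, k_ge = %d | p (%s) = %s\n",
                x$k_le, x$k_ge, x$alternative, x$p_report))
    invisible(x)
}

## ---- rank tests ------------------------------------------------------------

#' Wilcoxon signed-rank test of departure from zero
#'
#' Two-sided signed-rank test that a sample of (log-)ratios is centred at
#' zero. Zeros are removed first; the null distribution is exact for n <= 25
#' without ties among the absolute values, and a normal approximation with
#' tie correction is used otherwise. An all-zero input yields p = 1 with a
#' degenerate-input warning.
#'
#' @param logratios numeric vector.
#' @param exact force (`TRUE`/`FALSE`) or auto-select (`NULL`) the exact null.
#' @return Two-sided p-value.
#' @export
wilcoxonDepartureFromZero <- function(logratios, exact = NULL) {
    stopifnot(length(logratios) >= 1L)
    x <- logratios[logratios != 0]
    if (!length(x)) {
        warning("all values are zero: no evidence of departure, p = 1")
        return(1)
    }
    ties <- anyDuplicated(abs(x)) > 0L
    if (is.null(exact)) exact <- length(x) <= 25L && !ties
    if (exact && ties)
        stop("exact null unavailable with tied absolute values")
    suppressWarnings(
        stats::wilcox.test(x, mu = 0, exact = exact, correct = !exact)$p.value)
}

#' Two-sided Mann-Whitney rank-sum comparison
#'
#' The replicate-comparison convention used for e.g. ChIP-qPCR enrichments:
#' exact when the smaller group has <= 8 observations and there are no ties,
#' normal approximation with tie correction otherwise. `exact = TRUE` forces
#' the exact null for larger tie-free samples.
#'
#' @param a,b numeric vectors.
#' @param exact force or auto-select (`NULL`) the exact null.
#' @return Two-sided p-value.
#' @export
ranksumCompare <- function(a, b, exact = NULL) {
    stopifnot(length(a) >= 1L, length(b) >= 1L)
    ties <- anyDuplicated(c(a, b)) > 0L
    if (is.null(exact)) exact <- min(length(a), length(b)) <= 8L && !ties
    if (exact && ties)
        stop("exact null unavailable with ties")
    suppressWarnings(
        stats::wilcox.test(a, b, exact = exact, correct = !exact)$p.value)
}

#' Two-sample Kolmogorov-Smirnov comparison of a gene set against its null
#'
#' Compares the empirical distribution of a quantity (e.g. F_as) over an
#' observed gene set with the pooled values of random gene sets, returning
#' the two-sample D statistic and the asymptotic two-sided p-value.
#'
#' @param observed_values,null_values non-empty numeric vectors.
#' @return list with elements `D` and `p`.
#' @export
ksSetVsNull <- function(observed_values, null_values) {
    stopifnot(length(observed_values) >= 1L, length(null_values) >= 1L)
    r <- suppressWarnings(stats::ks.test(observed_values, null_values,
                                         exact = FALSE))
    list(D = unname(r$statistic), p = r$p.value)
}
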