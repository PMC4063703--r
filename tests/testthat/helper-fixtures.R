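suppressPackageStartupMessages({
    library(GenomicRanges)
    library(SummarizedExperiment)
})

# compact gene-table builder: one row per gene, spans given as orf unless UTRs set
toyAnnotation <- function(..., chromLengths = NULL) {
    rows <- list(...)
    tbl <- do.call(rbind, lapply(rows, function(r) {
        d <- data.frame(gene_id = r$id,
                        chrom = if (is.null(r$chrom)) "chrI" else r$chrom,
                        strand = if (is.null(r$strand)) "+" else r$strand,
                        orf_start = r$orf[1], orf_end = r$orf[2],
                        stringsAsFactors = FALSE)
        d$utr5_start <- if (is.null(r$utr5)) NA_integer_ else r$utr5[1]
        d$utr5_end <- if (is.null(r$utr5)) NA_integer_ else r$utr5[2]
        d$utr3_start <- if (is.null(r$utr3)) NA_integer_ else r$utr3[1]
        d$utr3_end <- if (is.null(r$utr3)) NA_integer_ else r$utr3[2]
        d$biotype <- if (is.null(r$biotype)) "mRNA" else r$biotype
        d
    }))
    annotationFromTable(tbl, chromLengths = chromLengths)
}

gene <- function(id, orf, strand = "+", chrom = "chrI",
                 utr5 = NULL, utr3 = NULL, biotype = "mRNA")
    list(id = id, orf = orf, strand = strand, chrom = chrom,
         utr5 = utr5, utr3 = utr3, biotype = biotype)

# toy signal set: probes at given positions (single chromosome)
toySignal <- function(positions, values, strand = "+", chrom = "chrI",
                      genotype = NULL, replicate = NULL) {
    values <- as.matrix(values)
    if (is.null(genotype)) genotype <- rep("wt", ncol(values))
    if (is.null(replicate)) replicate <- seq_len(ncol(values))
    probes <- GRanges(chrom, IRanges(positions, width = 1L),
                      strand = rep_len(strand, length(positions)))
    SignalSet(probes, values, genotype = genotype, replicate = replicate)
}

# random gene layout (possibly overlapping spans) for pairing property tests
randomGeneTable <- function(n, n_chrom = 2) {
    data.frame(id = sprintf("r%03d", seq_len(n)),
               chrom = paste0("chr", sample.int(n_chrom, n, replace = TRUE)),
               strand = sample(c("+", "-"), n, replace = TRUE),
               start = st <- sample.int(5000L, n),
               end = st + sample.int(800L, n),
               stringsAsFactors = FALSE)
}

tableToAnnotation <- function(tb) {
    annotationFromTable(data.frame(
        gene_id = tb$id, chrom = tb$chrom, strand = tb$strand,
        orf_start = tb$start, orf_end = tb$end, stringsAsFactors = FALSE))
}

## ---- exhaustive-scan oracles over the plain gene table ----------------------

oracleUpstream <- function(tb, id) {
    g <- tb[tb$id == id, ]
    cand <- tb[tb$chrom == g$chrom & tb$strand == g$strand & tb$id != id, ]
    if (g$strand == "+") {
        cand <- cand[cand$start < g$start & cand$end < g$end, , drop = FALSE]
        if (!nrow(cand)) return(NULL)
        cand <- cand[order(-cand$end, cand$id), , drop = FALSE]
        list(partner = cand$id[1], d = g$start - cand$end[1] - 1L)
    } else {
        cand <- cand[cand$end > g$end & cand$start > g$start, , drop = FALSE]
        if (!nrow(cand)) return(NULL)
        cand <- cand[order(cand$start, cand$id), , drop = FALSE]
        list(partner = cand$id[1], d = cand$start[1] - g$end - 1L)
    }
}

oracleDownstreamReverse <- function(tb, id) {
    g <- tb[tb$id == id, ]
    cand <- tb[tb$chrom == g$chrom & tb$strand != g$strand & tb$id != id, ]
    if (g$strand == "+") {
        cand <- cand[cand$end >= g$end, , drop = FALSE]
        if (!nrow(cand)) return(NULL)
        cand$d <- cand$start - g$end - 1L
    } else {
        cand <- cand[cand$start <= g$start, , drop = FALSE]
        if (!nrow(cand)) return(NULL)
        cand$d <- g$start - cand$end - 1L
    }
    cand <- cand[order(cand$d, cand$id), , drop = FALSE]
    list(partner = cand$id[1], d = cand$d[1])
}

# per-base boolean-mask oracle for antisense coverage
oracleAntisenseBp <- function(tb, id) {
    g <- tb[tb$id == id, ]
    opp <- tb[tb$chrom == g$chrom & tb$strand != g$strand, , drop = FALSE]
    covered <- rep(FALSE, g$end - g$start + 1L)
    for (k in seq_len(nrow(opp))) {
        lo <- max(g$start, opp$start[k]); hi <- min(g$end, opp$end[k])
        if (lo <= hi) covered[(lo:hi) - g$start + 1L] <- TRUE
    }
    sum(covered)
}

## ---- enumeration oracles for the rank tests ---------------------------------

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
enumSignedRankP <- function(x) {
    x <- x[x != 0]
    n <- length(x)
    r <- rank(abs(x))
    v_obs <- sum(r[x > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    V <- as.vector(signs %*% r)
    min(1, 2 * min(mean(V <= v_obs), mean(V >= v_obs)))
}

# exact two-sided rank-sum p by enumerating all C(n1+n2, n1) group assignments
enumRankSumP <- function(a, b) {
    n1 <- length(a); N <- n1 + length(b)
    r <- rank(c(a, b))
    w_obs <- sum(r[seq_len(n1)])
    cmb <- utils::combn(N, n1)
    W <- colSums(matrix(r[cmb], nrow = n1))
    min(1, 2 * min(mean(W <= w_obs), mean(W >= w_obs)))
}

# brute-force dependency-edge oracle over the long peptide table
oracleEdges <- function(df, controlBait, minPeptides = 2L, wt = "wt") {
    if (!is.na(controlBait)) df <- df[df$bait != controlBait, , drop = FALSE]
    get <- function(b, bg, p) {
        i <- which(df$bait == b & df$background == bg & df$prey == p)
        if (length(i)) df$peptides[i] else 0L
    }
    out <- list()
    for (b in sort(unique(df$bait))) {
        if (!wt %in% df$background[df$bait == b]) next
        for (bg in setdiff(sort(unique(df$background[df$bait == b])), wt)) {
            for (p in sort(unique(df$prey[df$bait == b & df$background == wt]))) {
                if (tolower(p) == tolower(bg)) next
                cwt <- get(b, wt, p)
                if (cwt >= minPeptides && get(b, bg, p) == 0L)
                    out[[length(out) + 1L]] <- data.frame(
                        prey = p, bait = b, requires = bg,
                        count_wt = cwt, count_del = 0L,
                        stringsAsFactors = FALSE)
            }
        }
    }
    if (!length(out))
        return(data.frame(prey = character(), bait = character(),
                          requires = character(), count_wt = integer(),
                          count_del = integer(), stringsAsFactors = FALSE))
    res <- do.call(rbind, out)
    res <- res[order(res$prey, res$bait, res$requires), , drop = FALSE]
    rownames(res) <- NULL
    res
}
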