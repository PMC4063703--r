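#' Simulation configuration
#'
#' Parameters of the synthetic genome, signal and AP-MS generators. The
#' defaults describe the benchmark conditions used throughout the package:
#' a 500-gene, 3-chromosome genome; triplicate two-genotype log-normal probe
#' signal at 20 bp spacing with log2 noise sd 0.1; 47 under- and 14
#' over-expressed genes at 3-fold; 50 read-through genes with a 3-fold 3'UTR
#' elevation, most of them paired with a convergent overlapping antisense
#' gene; deliberately short upstream gaps for the under-expressed set and
#' full antisense coverage for 35% of it.
#'
#' @param seed integer master seed (annotation, signal and peptide draws use
#'   `seed`, `seed + 1`, `seed + 2`).
#' @param n_chroms,n_genes genome size.
#' @param gene_length_range,utr5_length_range,utr3_length_range,gap_range bp
#'   ranges (uniform integer draws).
#' @param probe_spacing probe grid step in bp.
#' @param n_replicates replicates per genotype.
#' @param log2_noise_sd per-probe log2 noise sd.
#' @param baseline_log2_mean,baseline_log2_sd per-gene baseline level (log2).
#' @param background_log2_mean intergenic background level (log2).
#' @param frac_convergent_overlapping fraction of read-through genes given a
#'   convergent overlapping antisense partner.
#' @param overlap_range convergent-overlap size range in bp.
#' @param n_de_down,n_de_up,de_fold injected differential expression.
#' @param n_readthrough,readthrough_fold injected 3'UTR read-through.
#' @param short_igr_set_size,short_igr_range deliberately short upstream
#'   same-strand gaps (assigned within the under-expressed set by default).
#' @param antisense_full_cover_frac fraction of the under-expressed set fully
#'   covered by an antisense gene.
#' @param genotypes two genotype labels, reference first.
#' @return A list of class `"sim_config"`.
#' @export
simulationConfig <- function(seed = 1L,
                             n_chroms = 3L,
                             n_genes = 500L,
                             gene_length_range = c(600L, 2400L),
                             utr5_length_range = c(60L, 180L),
                             utr3_length_range = c(120L, 360L),
                             gap_range = c(300L, 1500L),
                             probe_spacing = 20L,
                             n_replicates = 3L,
                             log2_noise_sd = 0.1,
                             baseline_log2_mean = 10,
                             baseline_log2_sd = 1,
                             background_log2_mean = 4,
                             frac_convergent_overlapping = 0.8,
                             overlap_range = c(50L, 400L),
                             n_de_down = 47L,
                             n_de_up = 14L,
                             de_fold = 3,
                             n_readthrough = 50L,
                             readthrough_fold = 3,
                             short_igr_set_size = 47L,
                             short_igr_range = c(1L, 30L),
                             antisense_full_cover_frac = 0.35,
                             genotypes = c("wt", "mut")) {
    cfg <- as.list(environment())
    stopifnot(cfg$n_genes >= 1L, cfg$n_chroms >= 1L,
              cfg$n_de_down + cfg$n_de_up + cfg$n_readthrough <= cfg$n_genes,
              cfg$de_fold > 1, cfg$readthrough_fold > 1,
              cfg$log2_noise_sd >= 0, cfg$probe_spacing >= 1L,
              cfg$n_replicates >= 1L, length(cfg$genotypes) == 2L,
              cfg$frac_convergent_overlapping >= 0,
              cfg$frac_convergent_overlapping <= 1,
              cfg$antisense_full_cover_frac >= 0,
              cfg$antisense_full_cover_frac <= 1)
    for (r in c("gene_length_range", "utr5_length_range", "utr3_length_range",
                "gap_range", "overlap_range", "short_igr_range"))
        stopifnot(length(cfg[[r]]) == 2L, cfg[[r]][1L] >= 1L,
                  cfg[[r]][2L] >= cfg[[r]][1L])
    structure(cfg, class = "sim_config")
}

.rint <- function(rng)
    if (rng[1L] == rng[2L]) rng[1L] else
        sample.int(rng[2L] - rng[1L] + 1L, 1L) + rng[1L] - 1L

#' Simulate a genome annotation with ground-truth gene sets
#'
#' Lays out non-overlapping genes (5'UTR + ORF + 3'UTR) left-to-right on each
#' chromosome with random strands, then plants the structures the context
#' statistics detect: the short-gap set takes its predecessor's strand and a
#' gap from `short_igr_range`; convergent read-through genes (forced to the
#' plus strand) receive an opposite-strand partner overlapping their 3' end;
#' fully covered genes receive an antisense gene spanning exactly their span.
#' Planted antisense genes are ordinary (ORF-only) genes of the annotation.
#'
#' @param cfg a [simulationConfig()].
#' @return list with elements `annotation` (a [GenomeAnnotation-class]) and
#'   `truth` (gene-id sets: `de_down`, `de_up`, `readthrough`, `short_igr`,
#'   `antisense_covered`).
#' @export
simulateAnnotation <- function(cfg) {
    stopifnot(inherits(cfg, "sim_config"))
    set.seed(cfg$seed)
    n <- cfg$n_genes
    ids <- sprintf("g%04d", seq_len(n))
    chrom_names <- paste0("chr", utils::as.roman(seq_len(cfg$n_chroms)))
    chrom_idx <- sort(rep_len(seq_len(cfg$n_chroms), n))
    first_on_chrom <- !duplicated(chrom_idx)

    rt <- sort(sample(ids, cfg$n_readthrough))
    conv <- sort(sample(rt, round(cfg$frac_convergent_overlapping * length(rt))))
    prev_id <- c(NA_character_, ids[-n])
    prev_id[first_on_chrom] <- NA_character_
    elig_short <- ids[!first_on_chrom & !(ids %in% rt) &
                      !(prev_id %in% c(conv, NA))]
    short <- sort(sample(elig_short,
                         min(cfg$short_igr_set_size, length(elig_short))))
    pool <- setdiff(ids, union(rt, short))
    de_down <- if (cfg$n_de_down >= length(short)) {
        sort(c(short, sample(pool, cfg$n_de_down - length(short))))
    } else sort(sample(short, cfg$n_de_down))
    cover <- sort(sample(de_down,
                         round(cfg$antisense_full_cover_frac * length(de_down))))
    de_up <- sort(sample(setdiff(ids, c(rt, de_down)), cfg$n_de_up))

    strands <- sample(c("+", "-"), n, replace = TRUE)
    strands[ids %in% conv] <- "+"
    # a short gap is upstream only for a plus-strand gene whose predecessor
    # is on the plus strand too
    for (i in which(ids %in% short)) {
        strands[i] <- "+"
        strands[i - 1L] <- "+"
    }

    rows <- vector("list", n)
    extras <- list()
    pos <- 0L
    chrom_len <- integer(cfg$n_chroms)
    for (i in seq_len(n)) {
        if (first_on_chrom[i]) pos <- 500L
        gap <- if (ids[i] %in% short) .rint(cfg$short_igr_range)
               else .rint(cfg$gap_range)
        u5 <- .rint(cfg$utr5_length_range)
        o <- .rint(cfg$gene_length_range)
        u3 <- .rint(cfg$utr3_length_range)
        span_start <- pos + gap + 1L
        span_end <- span_start + u5 + o + u3 - 1L
        ch <- chrom_names[chrom_idx[i]]
        left <- if (strands[i] == "+") u5 else u3   # leftmost block on genome
        rows[[i]] <- data.frame(
            gene_id = ids[i], chrom = ch, strand = strands[i],
            orf_start = span_start + left, orf_end = span_start + left + o - 1L,
            utr5_start = if (strands[i] == "+") span_start else span_end - u5 + 1L,
            utr5_end = if (strands[i] == "+") span_start + u5 - 1L else span_end,
            utr3_start = if (strands[i] == "+") span_end - u3 + 1L else span_start,
            utr3_end = if (strands[i] == "+") span_end else span_start + u3 - 1L,
            biotype = "mRNA", stringsAsFactors = FALSE)
        pos <- span_end
        if (ids[i] %in% conv) {
            ov <- .rint(cfg$overlap_range)
            as_len <- .rint(c(600L, 1500L))
            as_start <- span_end - ov + 1L
            as_end <- as_start + as_len - 1L
            extras[[length(extras) + 1L]] <- data.frame(
                gene_id = paste0(ids[i], "_rv"), chrom = ch, strand = "-",
                orf_start = as_start, orf_end = as_end,
                utr5_start = NA_integer_, utr5_end = NA_integer_,
                utr3_start = NA_integer_, utr3_end = NA_integer_,
                biotype = "mRNA", stringsAsFactors = FALSE)
            pos <- max(pos, as_end)
        }
        if (ids[i] %in% cover) {
            extras[[length(extras) + 1L]] <- data.frame(
                gene_id = paste0(ids[i], "_as"), chrom = ch,
                strand = if (strands[i] == "+") "-" else "+",
                orf_start = span_start, orf_end = span_end,
                utr5_start = NA_integer_, utr5_end = NA_integer_,
                utr3_start = NA_integer_, utr3_end = NA_integer_,
                biotype = "mRNA", stringsAsFactors = FALSE)
        }
        chrom_len[chrom_idx[i]] <- pos + 1000L
    }
    tbl <- do.call(rbind, c(rows, extras))
    annotation <- annotationFromTable(
        tbl, chromLengths = stats::setNames(chrom_len, chrom_names))
    list(annotation = annotation,
         truth = list(de_down = de_down, de_up = de_up, readthrough = rt,
                      short_igr = short, antisense_covered = cover))
}

#' Simulate strand-specific tiling signal with injected effects
#'
#' Probes are laid on a regular grid (both strands) over each chromosome.
#' The per-probe log2 level is the intergenic background, or the gene's
#' baseline where the probe falls inside a gene span on the probe's strand.
#' Injected effects apply to the mutant genotype only: +/- `log2(de_fold)`
#' over the whole gene for differentially expressed genes, and
#' `+log2(readthrough_fold)` on 3'UTR probes only for read-through genes.
#' Gaussian log2 noise (`log2_noise_sd`) is added per probe and array;
#' intensities are `2^level`, so injected folds are exact in the noise-free
#' limit.
#'
#' @param annotation,truth output of [simulateAnnotation()].
#' @param cfg the same [simulationConfig()].
#' @return A [SignalSet-class] (columns: reference replicates first).
#' @export
simulateSignal <- function(annotation, truth, cfg) {
    stopifnot(inherits(cfg, "sim_config"))
    set.seed(cfg$seed + 1L)
    sl <- chromLengths(annotation)
    probe_list <- lapply(names(sl), function(ch) {
        p <- seq.int(cfg$probe_spacing %/% 2L + 1L, sl[[ch]],
                     by = cfg$probe_spacing)
        GRanges(ch, IRanges(rep(p, 2L), width = 1L),
                strand = rep(c("+", "-"), each = length(p)),
                seqinfo = seqinfo(geneSpans(annotation)))
    })
    probes <- sort(do.call(c, probe_list))
    np <- length(probes)
    ncols <- 2L * cfg$n_replicates
    genotype <- rep(cfg$genotypes, each = cfg$n_replicates)
    replicate <- rep(seq_len(cfg$n_replicates), 2L)
    mut_cols <- which(genotype == cfg$genotypes[2L])

    ids <- geneIds(annotation)
    baseline <- stats::rnorm(length(ids), cfg$baseline_log2_mean,
                             cfg$baseline_log2_sd)
    level <- rep(cfg$background_log2_mean, np)
    ov <- findOverlaps(geneSpans(annotation), probes)
    level[S4Vectors::subjectHits(ov)] <- baseline[S4Vectors::queryHits(ov)]
    L <- matrix(level, np, ncols)

    add_effect <- function(gr, genes, delta) {
        if (!length(genes)) return()
        sel <- gr[mcols(gr)$gene_id %in% genes]
        hit <- S4Vectors::subjectHits(findOverlaps(sel, probes))
        if (length(hit)) L[hit, mut_cols] <<- L[hit, mut_cols] + delta
    }
    add_effect(geneSpans(annotation), truth$de_down, -log2(cfg$de_fold))
    add_effect(geneSpans(annotation), truth$de_up, +log2(cfg$de_fold))
    add_effect(utr3Ranges(annotation), truth$readthrough,
               +log2(cfg$readthrough_fold))

    if (cfg$log2_noise_sd > 0)
        L <- L + matrix(stats::rnorm(np * ncols, 0, cfg$log2_noise_sd), np, ncols)
    SignalSet(probes, 2^L, genotype = genotype, replicate = replicate)
}

#' Simulate an AP-MS unique-peptide matrix with a planted module
#'
#' Builds a single-bait purification series (wild type plus one deletion
#' background per module member) in which the planted module members are
#' recovered in the wild type but absent whenever any other member is
#' deleted, a stable core complex is recovered everywhere, and planted
#' contaminants appear in the no-tag control. Returns the matrix together
#' with the dependency edges [inferDependencies()] must recover.
#'
#' @param cfg a [simulationConfig()] (only `seed` is used).
#' @param bait bait protein name.
#' @param module planted mutually dependent module members.
#' @param core stable core-complex preys.
#' @param contaminants preys planted in the control (and the bait runs).
#' @param plantModule set `FALSE` to generate a matrix without the module
#'   (all module preys stay bound everywhere): expected edges are then empty.
#' @return list with `matrix` (a [PeptideMatrix-class], control bait
#'   `"no_tag"`) and `expected_edges` (data.frame as from
#'   [inferDependencies()] with `minPeptides = 2`).
#' @export
simulatePeptideMatrix <- function(cfg,
                                  bait = "Yth1",
                                  module = c("Swd2.2", "Ppn1", "Dis2"),
                                  core = c("Cft1", "Cft2", "Ysh1", "Pta1",
                                           "Pfs2", "Ssu72"),
                                  contaminants = c("Hsp90", "Act1", "Rpl3"),
                                  plantModule = TRUE) {
    stopifnot(inherits(cfg, "sim_config"))
    set.seed(cfg$seed + 2L)
    backgrounds <- c("wt", .normName(module))
    rows <- list()
    add <- function(b, bg, prey, k)
        rows[[length(rows) + 1L]] <<- data.frame(
            bait = b, background = bg, prey = prey, peptides = as.integer(k),
            stringsAsFactors = FALSE)
    core_wt <- stats::rpois(length(core), 15) + 5L
    mod_wt <- stats::setNames(stats::rpois(length(module), 8) + 2L, module)
    for (bg in backgrounds) {
        for (j in seq_along(core))
            add(bait, bg, core[j], max(1L, core_wt[j] + sample(-2:2, 1L)))
        for (m in module) {
            gone <- plantModule && bg != "wt"        # any member deleted
            absent_self <- .normName(m) == bg
            if (!gone && !absent_self) add(bait, bg, m, mod_wt[[m]])
        }
        for (ct in contaminants)
            add(bait, bg, ct, stats::rpois(1L, 3) + 1L)
    }
    for (ct in contaminants) add("no_tag", "wt", ct, stats::rpois(1L, 4) + 1L)
    pm <- PeptideMatrix(do.call(rbind, rows), controlBait = "no_tag")

    expected <- if (plantModule) {
        do.call(rbind, lapply(module, function(m) {
            req <- setdiff(.normName(module), .normName(m))
            data.frame(prey = m, bait = bait, requires = req,
                       count_wt = mod_wt[[m]], count_del = 0L,
                       stringsAsFactors = FALSE)
        }))
    } else data.frame(prey = character(), bait = character(),
                      requires = character(), count_wt = integer(),
                      count_del = integer(), stringsAsFactors = FALSE)
    if (nrow(expected)) {
        expected <- expected[order(expected$prey, expected$bait,
                                   expected$requires), , drop = FALSE]
        rownames(expected) <- NULL
    }
    list(matrix = pm, expected_edges = expected)
}
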