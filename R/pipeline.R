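#' Run the full analysis pipeline
#'
#' Chains the stages end-to-end: annotation -> signal -> quantile
#' normalization -> differential expression -> read-through calling ->
#' genomic-context tests, writing result tables, a machine-readable summary
#' JSON and a run log into `outDir`. Inputs are either file paths (GFF3
#' annotation, long-format signal TSV), in-memory objects, or a
#' [simulationConfig()] from which a synthetic data set (with ground truth,
#' enabling recovery metrics in the summary) is generated. Deterministic
#' given `seed`: running twice writes identical summary JSON.
#'
#' Context tests mirror the analysis design: for the under-expressed gene
#' set, a permutation test of the median upstream intergenic distance (IGR),
#' a Wilcoxon departure-from-zero test on the log2 expression ratios of the
#' upstream partner over the focal gene in the reference genotype, and a
#' Kolmogorov-Smirnov comparison of antisense coverage fractions against
#' pooled random sets; for the read-through (gTERM) set, a permutation test
#' of the median distance to the first downstream reverse-oriented gene
#' (IGRterm).
#'
#' @param outDir output directory (created if needed).
#' @param annotation GFF3 path or [GenomeAnnotation-class] (ignored when
#'   `simConfig` is given).
#' @param signal signal TSV path or [SignalSet-class] (ignored when
#'   `simConfig` is given).
#' @param simConfig optional [simulationConfig()]; when supplied, annotation
#'   and signal are simulated and recovery metrics against ground truth are
#'   reported.
#' @param seed seed for the permutation stages (and, with `simConfig`,
#'   overrides its seed).
#' @param fcThreshold,alpha,deTest differential-expression parameters
#'   (see [callDE()]).
#' @param rrThreshold read-through threshold (see [callReadthrough()]).
#' @param nRandomSets random sets per permutation test.
#' @param normalize quantile-normalize before analysis (default `TRUE`).
#' @return Invisibly, a list with the stage results (`annotation`, `signal`,
#'   `de`, `readthrough`, `context`, `summary`).
#' @export
runPipeline <- function(outDir, annotation = NULL, signal = NULL,
                        simConfig = NULL, seed = 1L,
                        fcThreshold = 1.9, alpha = 0.01,
                        deTest = "t_on_log2", rrThreshold = 1.5,
                        nRandomSets = 10000L, normalize = TRUE) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    stage <- function(name, expr)
        tryCatch(expr, error = function(e)
            stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 call. = FALSE))

    truth <- NULL
    ann <- stage("annotation", {
        if (!is.null(simConfig)) {
            stopifnot(inherits(simConfig, "sim_config"))
            simConfig$seed <- as.integer(seed)
            sim <- simulateAnnotation(simConfig)
            truth <- sim$truth
            sim$annotation
        } else if (is(annotation, "GenomeAnnotation")) {
            annotation
        } else if (is.character(annotation) && file.exists(annotation)) {
            readGFF3(annotation)
        } else stop("no annotation provided (path does not exist?)")
    })
    sig <- stage("signal", {
        if (!is.null(simConfig)) simulateSignal(ann, truth, simConfig)
        else if (is(signal, "SignalSet")) signal
        else if (is.character(signal) && file.exists(signal)) readSignalTSV(signal)
        else stop("no signal provided (path does not exist?)")
    })
    if (normalize) sig <- stage("normalize", quantileNormalize(sig))

    gts <- unique(colData(sig)$genotype)
    de <- stage("de", callDE(sig, ann, fcThreshold = fcThreshold,
                             alpha = alpha, test = deTest))
    de_orf <- stage("de", callDE(sig, ann, fcThreshold = fcThreshold,
                                 alpha = alpha, test = deTest, region = "orf"))
    rt <- stage("readthrough",
                callReadthrough(sig, ann, de = de_orf,
                                rrThreshold = rrThreshold))
    utils::write.table(de, file.path(outDir, "de_results.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(rt, file.path(outDir, "readthrough_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    down_set <- de$gene_id[de$call == "under"]
    gterm_set <- rt$gene_id[rt$is_gterm]
    ctx <- stage("context",
                 .contextStage(ann, sig, down_set, gterm_set, gts[1L],
                               nRandomSets, seed, outDir))

    summary <- list(
        parameters = list(fc_threshold = fcThreshold, alpha = alpha,
                          rr_threshold = rrThreshold, de_test = deTest,
                          n_random_sets = nRandomSets, seed = seed,
                          normalized = normalize),
        n_genes = nrow(de),
        n_under = length(down_set), n_over = sum(de$call == "over"),
        n_gterm = length(gterm_set),
        context = ctx$summary)
    if (!is.null(truth)) {
        recov <- function(called, injected)
            list(sensitivity = if (length(injected))
                     mean(injected %in% called) else NA,
                 precision = if (length(called))
                     mean(called %in% injected) else NA)
        summary$recovery <- list(
            de_down = recov(down_set, truth$de_down),
            de_up = recov(de$gene_id[de$call == "over"], truth$de_up),
            readthrough = recov(gterm_set, truth$readthrough))
    }
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(c("tilingRT run log",
                 paste0("package version: ",
                        as.character(utils::packageVersion("tilingRT"))),
                 paste0("seed: ", seed),
                 paste0("genotypes: ", paste(gts, collapse = " vs ")),
                 paste0("parameters: fc_threshold=", fcThreshold,
                        " alpha=", alpha, " rr_threshold=", rrThreshold,
                        " n_random_sets=", nRandomSets,
                        " normalized=", normalize)),
               file.path(outDir, "run_log.txt"))
    invisible(list(annotation = ann, signal = sig, de = de, readthrough = rt,
                   context = ctx, summary = summary, truth = truth))
}

.contextStage <- function(ann, sig, down_set, gterm_set, reference,
                          nRandomSets, seed, outDir) {
    out <- list()
    summary <- list()

    igr_obs <- contextObservations(ann, "igr")
    igr_vals <- stats::setNames(igr_obs$value, igr_obs$gene_id)
    down_ok <- down_set[down_set %in% names(igr_vals)[!is.na(igr_vals)]]
    if (length(down_ok) >= 2L) {
        out$igr <- permutationMedianTest(igr_vals, down_ok,
                                         nRandomSets = nRandomSets,
                                         seed = seed, alternative = "less")
        summary$igr <- list(observed_median = out$igr$observed_stat,
                            k_le = out$igr$k_le, p = out$igr$p,
                            p_report = out$igr$p_report)
        utils::write.table(data.frame(null_median = out$igr$null_stats),
                           file.path(outDir, "igr_null_medians.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)

        # log2 partner/focal expression ratios in the reference genotype
        lr <- vapply(down_ok, function(g) {
            p <- upstreamSameStrandPartner(ann, g)
            e <- geneExpression(sig, ann, reference, c(p$partner, g))
            if (any(is.na(e)) || any(e <= 0)) NA_real_
            else log2(e[[1L]] / e[[2L]])
        }, numeric(1))
        lr <- lr[!is.na(lr)]
        if (length(lr) >= 1L) {
            out$partner_logratios <- lr
            summary$partner_wilcoxon_p <- wilcoxonDepartureFromZero(lr)
        }

        fas_obs <- contextObservations(ann, "f_as")
        fas_vals <- stats::setNames(fas_obs$value, fas_obs$gene_id)
        set.seed(seed)
        pooled <- as.vector(vapply(seq_len(nRandomSets), function(i)
            fas_vals[sample.int(length(fas_vals), length(down_ok))],
            numeric(length(down_ok))))
        ks <- ksSetVsNull(fas_vals[down_ok], pooled)
        out$f_as <- ks
        summary$f_as <- ks
    }

    igrt_obs <- contextObservations(ann, "igr_term")
    igrt_vals <- stats::setNames(igrt_obs$value, igrt_obs$gene_id)
    gterm_ok <- gterm_set[gterm_set %in% names(igrt_vals)[!is.na(igrt_vals)]]
    if (length(gterm_ok) >= 2L) {
        out$igr_term <- permutationMedianTest(igrt_vals, gterm_ok,
                                              nRandomSets = nRandomSets,
                                              seed = seed, alternative = "less")
        summary$igr_term <- list(observed_median = out$igr_term$observed_stat,
                                 k_le = out$igr_term$k_le, p = out$igr_term$p,
                                 p_report = out$igr_term$p_report)
    }
    list(results = out, summary = summary)
}
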