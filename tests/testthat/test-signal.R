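test_that("quantile normalization averages order statistics across tracks", {
    set <- toySignal(c(10, 30, 50), cbind(c(1, 2, 3), c(2, 4, 6)))
    qn <- assay(quantileNormalize(set, floor = 0), "signal")
    expect_equal(unname(qn[, 1]), c(1.5, 3, 4.5))
    expect_equal(unname(qn[, 2]), c(1.5, 3, 4.5))
    # ranks preserved under a non-monotone input ordering
    set2 <- toySignal(c(10, 30, 50), cbind(c(3, 1, 2), c(6, 2, 4)))
    qn2 <- assay(quantileNormalize(set2, floor = 0), "signal")
    expect_equal(unname(qn2[, 1]), c(4.5, 1.5, 3))
})

test_that("quantile normalization is idempotent and equalizes sorted values", {
    set.seed(1)
    set <- toySignal(seq(10, 400, by = 10),
                     matrix(2^rnorm(40 * 4, 8, 1), 40, 4),
                     genotype = rep(c("wt", "mut"), each = 2),
                     replicate = rep(1:2, 2))
    qn1 <- quantileNormalize(set)
    x <- assay(qn1, "signal")
    for (j in 2:ncol(x))
        expect_identical(sort(x[, 1]), sort(x[, j]))
    qn2 <- quantileNormalize(qn1)
    expect_equal(assay(qn2, "signal"), x)
    # identical tracks are a fixed point
    same <- toySignal(c(10, 20, 30), cbind(c(1, 5, 9), c(1, 5, 9)))
    expect_equal(assay(quantileNormalize(same, floor = 0), "signal")[, 1],
                 c(1, 5, 9), ignore_attr = TRUE)
})

test_that("joint normalization refuses unequal probe counts across strands", {
    probes <- GRanges("chrI", IRanges(c(10, 20, 30), width = 1),
                      strand = c("+", "+", "-"))
    set <- SignalSet(probes, matrix(1:6, 3, 2), genotype = c("wt", "wt"),
                     replicate = 1:2)
    expect_error(quantileNormalize(set), "unequal probe counts")
})

test_that("region summarization uses probe midpoints and the requested statistic", {
    set <- toySignal(c(10, 20, 30, 40), cbind(c(4, 4, 4, 4)))
    reg <- GRanges("chrI", IRanges(5, 45), strand = "+")
    expect_equal(regionSignal(set, reg, "mean"), 4)
    set2 <- toySignal(c(10, 20, 30), cbind(c(1, 2, 9)))
    expect_equal(regionSignal(set2, GRanges("chrI", IRanges(1, 50), strand = "+"),
                              "median"), 2)
    # probes outside the region, or a region on the other strand, yield NA
    expect_true(is.na(regionSignal(set2, GRanges("chrI", IRanges(100, 200),
                                                 strand = "+"), "mean")))
    expect_true(is.na(regionSignal(set2, GRanges("chrI", IRanges(1, 50),
                                                 strand = "-"), "mean")))
})

test_that("gene expression is mean over replicates of per-replicate probe medians", {
    ann <- toyAnnotation(gene("gA", orf = c(5, 45)))
    one <- toySignal(25, cbind(7))
    expect_equal(unname(geneExpression(one, ann, "wt", "gA")), 7)
    two <- toySignal(c(10, 20, 30), cbind(c(2, 2, 2), c(4, 4, 4)),
                     genotype = c("wt", "wt"), replicate = 1:2)
    expect_equal(unname(geneExpression(two, ann, "wt", "gA")), 3)
})

test_that("gene expression matches a naive two-loop oracle and ignores probe order", {
    set.seed(5)
    ann <- toyAnnotation(gene("gA", orf = c(1, 200)),
                         gene("gB", orf = c(301, 600)))
    pos <- seq(10, 590, by = 20)
    vals <- matrix(2^rnorm(length(pos) * 3, 8, 0.5), length(pos), 3)
    set <- toySignal(pos, vals, genotype = rep("wt", 3), replicate = 1:3)
    # naive oracle: loop over replicates, loop over probes
    naive <- function(lo, hi) {
        meds <- numeric(3)
        for (j in 1:3) {
            inside <- c()
            for (k in seq_along(pos))
                if (pos[k] >= lo && pos[k] <= hi) inside <- c(inside, vals[k, j])
            meds[j] <- median(inside)
        }
        mean(meds)
    }
    e <- geneExpression(set, ann, "wt")
    expect_equal(unname(e["gA"]), naive(1, 200))
    expect_equal(unname(e["gB"]), naive(301, 600))
    # permuting probe rows leaves the result unchanged
    perm <- sample(seq_along(pos))
    setp <- toySignal(pos[perm], vals[perm, ], genotype = rep("wt", 3),
                      replicate = 1:3)
    expect_equal(geneExpression(setp, ann, "wt"), e)
})

test_that("pre-normalization expression scales exactly with the probe signal", {
    set.seed(6)
    ann <- toyAnnotation(gene("gA", orf = c(1, 200)),
                         gene("gB", orf = c(301, 600)))
    pos <- seq(10, 590, by = 20)
    vals <- matrix(2^rnorm(length(pos) * 3, 8, 0.5), length(pos), 3)
    set <- toySignal(pos, vals, genotype = rep("wt", 3), replicate = 1:3)
    scaled <- vals
    scaled[pos <= 200, ] <- scaled[pos <= 200, ] * 2.5
    sets <- toySignal(pos, scaled, genotype = rep("wt", 3), replicate = 1:3)
    expect_equal(unname(geneExpression(sets, ann, "wt", "gA")),
                 2.5 * unname(geneExpression(set, ann, "wt", "gA")))
    expect_equal(geneExpression(sets, ann, "wt", "gB"),
                 geneExpression(set, ann, "wt", "gB"))
})

test_that("signal sets round-trip through the long TSV format", {
    cfg <- simulationConfig(seed = 4, n_genes = 20L, n_de_down = 2L,
                            n_de_up = 1L, n_readthrough = 2L,
                            short_igr_set_size = 2L, n_replicates = 2L)
    sim <- simulateAnnotation(cfg)
    set <- simulateSignal(sim$annotation, sim$truth, cfg)
    f <- tempfile(fileext = ".tsv")
    writeSignalTSV(set, f)
    set2 <- readSignalTSV(f)
    expect_identical(colnames(assay(set)), colnames(assay(set2)))
    expect_identical(trackInfo(set)$genotype, trackInfo(set2)$genotype)
    expect_equal(unname(assay(set, "signal")), unname(assay(set2, "signal")),
                 tolerance = 1e-12)
    expect_equal(start(probeRanges(set)), start(probeRanges(set2)))
    # incomplete grids are rejected
    d <- read.table(f, header = TRUE, sep = "\t")
    write.table(d[-1, ], f, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readSignalTSV(f), "common probe grid")
})
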