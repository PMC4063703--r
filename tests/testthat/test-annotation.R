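test_that("gene table maps to gene models with spans and UTR flags", {
    ann <- toyAnnotation(
        gene("gA", orf = c(1001, 2000), utr3 = c(2001, 2200)),
        gene("gB", orf = c(3001, 4000)))
    expect_identical(geneIds(ann), c("gA", "gB"))
    spans <- geneSpans(ann)
    expect_equal(start(spans), c(1001, 3001))
    expect_equal(end(spans), c(2200, 4000))
    expect_identical(mcols(spans)$has_utr3, c(TRUE, FALSE))
    gm <- geneModel(ann, "gB")
    expect_null(gm$utr3)
})

test_that("annotation validity rejects duplicated ids, escaped bounds and detached UTRs", {
    expect_error(toyAnnotation(gene("gA", orf = c(1, 100)),
                               gene("gA", orf = c(200, 300))),
                 "duplicated gene_id")
    suppressWarnings(   # GRanges itself warns about the out-of-bound range
        expect_error(toyAnnotation(gene("gA", orf = c(1, 100)),
                                   chromLengths = c(chrI = 50)),
                     "outside chromosome bounds"))
    expect_error(toyAnnotation(gene("gA", orf = c(1001, 2000),
                                    utr3 = c(2010, 2200))),
                 "abut")
    # a minus-strand 3'UTR abuts the ORF on the left
    ann <- toyAnnotation(gene("gC", orf = c(500, 900), strand = "-",
                              utr3 = c(300, 499), utr5 = c(901, 950)))
    expect_s4_class(ann, "GenomeAnnotation")
})

test_that("upstream same-strand partner picks the nearest 3' end", {
    ann <- toyAnnotation(gene("far", orf = c(1500, 2000)),
                         gene("near", orf = c(3000, 4000)),
                         gene("focal", orf = c(5000, 6000)))
    p <- upstreamSameStrandPartner(ann, "focal")
    expect_identical(p$partner, "near")
    expect_identical(p$distance_bp, 5000L - 4000L - 1L)
    # first gene on the chromosome has no upstream partner
    expect_null(upstreamSameStrandPartner(ann, "far"))
})

test_that("skipOpposite = FALSE requires the adjacent gene to be same-strand", {
    ann <- toyAnnotation(gene("up", orf = c(1000, 2000)),
                         gene("blocker", orf = c(2500, 3000), strand = "-"),
                         gene("focal", orf = c(4000, 5000)))
    expect_identical(upstreamSameStrandPartner(ann, "focal")$partner, "up")
    expect_null(upstreamSameStrandPartner(ann, "focal", skipOpposite = FALSE))
})

test_that("downstream reverse partner handles convergent overlap with negative distance", {
    ann <- toyAnnotation(gene("focal", orf = c(1, 1000)),
                         gene("rv", orf = c(900, 1800), strand = "-"))
    p <- downstreamReversePartner(ann, "focal")
    expect_identical(p$partner, "rv")
    expect_true(p$distance_bp < 0)
    expect_identical(p$distance_bp, 900L - 1000L - 1L)
    # convergent partners are mutual
    expect_identical(downstreamReversePartner(ann, "rv")$partner, "focal")
    # no opposite-strand gene reaching past the focal 3' end
    ann2 <- toyAnnotation(gene("focal", orf = c(1000, 2000)),
                          gene("left", orf = c(100, 800), strand = "-"))
    expect_null(downstreamReversePartner(ann2, "focal"))
})

test_that("pairing operations agree with the exhaustive-scan oracle on random layouts", {
    set.seed(42)
    for (rep in 1:15) {
        tb <- randomGeneTable(sample(5:30, 1))
        ann <- tableToAnnotation(tb)
        for (id in tb$id) {
            up <- upstreamSameStrandPartner(ann, id)
            oup <- oracleUpstream(tb, id)
            if (is.null(oup)) expect_null(up) else {
                expect_identical(up$partner, oup$partner)
                expect_identical(up$distance_bp, as.integer(oup$d))
            }
            dn <- downstreamReversePartner(ann, id)
            odn <- oracleDownstreamReverse(tb, id)
            if (is.null(odn)) expect_null(dn) else {
                expect_identical(dn$partner, odn$partner)
                expect_identical(dn$distance_bp, as.integer(odn$d))
            }
        }
    }
})

test_that("antisense overlap counts union coverage, not summed overlaps", {
    ann <- toyAnnotation(gene("g", orf = c(1001, 2000)),
                         gene("a1", orf = c(1501, 1700), strand = "-"),
                         gene("a2", orf = c(1601, 1900), strand = "-"))
    expect_identical(antisenseOverlapBp(ann, "g"), 400L)
    solo <- toyAnnotation(gene("g", orf = c(1001, 2000)))
    expect_identical(antisenseOverlapBp(solo, "g"), 0L)
    inside <- toyAnnotation(gene("g", orf = c(1001, 2000)),
                            gene("big", orf = c(500, 2500), strand = "-"))
    expect_identical(antisenseOverlapBp(inside, "g"), 1000L)
})

test_that("antisense overlap matches the per-base mask oracle and survives strand flips", {
    set.seed(7)
    for (rep in 1:10) {
        tb <- randomGeneTable(sample(5:25, 1))
        ann <- tableToAnnotation(tb)
        flipped <- tb
        flipped$strand <- ifelse(tb$strand == "+", "-", "+")
        annf <- tableToAnnotation(flipped)
        for (id in tb$id) {
            expect_identical(antisenseOverlapBp(ann, id),
                             as.integer(oracleAntisenseBp(tb, id)))
            expect_identical(antisenseOverlapBp(ann, id),
                             antisenseOverlapBp(annf, id))
        }
    }
})

test_that("GFF3 writing and re-reading round-trips the gene models", {
    cfg <- simulationConfig(seed = 9, n_genes = 25L, n_de_down = 3L,
                            n_de_up = 2L, n_readthrough = 3L,
                            short_igr_set_size = 3L)
    ann <- simulateAnnotation(cfg)$annotation
    f <- tempfile(fileext = ".gff3")
    writeGFF3(ann, f)
    ann2 <- readGFF3(f)
    expect_identical(geneIds(ann), geneIds(ann2))
    expect_equal(start(geneSpans(ann)), start(geneSpans(ann2)))
    expect_equal(end(geneSpans(ann)), end(geneSpans(ann2)))
    expect_identical(as.character(strand(geneSpans(ann))),
                     as.character(strand(geneSpans(ann2))))
    expect_equal(start(orfRanges(ann)), start(orfRanges(ann2)))
    expect_identical(mcols(utr3Ranges(ann))$gene_id,
                     mcols(utr3Ranges(ann2))$gene_id)
    expect_identical(chromLengths(ann), chromLengths(ann2))
    # and a second write of the re-read annotation is byte-identical
    f2 <- tempfile(fileext = ".gff3")
    writeGFF3(ann2, f2)
    expect_identical(readLines(f), readLines(f2))
})

test_that("malformed GFF3 lines are reported with their line number", {
    f <- tempfile(fileext = ".gff3")
    writeLines(c("##gff-version 3",
                 "chrI\tsrc\tgene\t1\t100\t.\t+\t.\tID=g1",
                 "chrI\tsrc\tgene\t200"), f)
    expect_error(readGFF3(f), "line 3")
})

test_that("chromosome lengths can come from a lengths TSV", {
    ann <- toyAnnotation(gene("gA", orf = c(100, 400)))
    f <- tempfile(fileext = ".gff3")
    writeGFF3(ann, f)
    lf <- tempfile(fileext = ".tsv")
    writeLines("chrI\t9999", lf)
    ann2 <- readGFF3(f, chromLengths = lf)
    expect_identical(unname(chromLengths(ann2)["chrI"]), 9999L)
})
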