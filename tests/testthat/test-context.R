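test_that("IGR measures the UTR-to-UTR gap of tandem gene pairs", {
    ann <- toyAnnotation(
        gene("up", orf = c(500, 949), utr3 = c(950, 1000)),
        gene("focal", orf = c(1101, 1500), utr5 = c(1051, 1100)))
    p <- upstreamSameStrandPartner(ann, "focal")
    expect_equal(igrDistance(ann, p), 50)
    # abutting features
    ann0 <- toyAnnotation(gene("up", orf = c(500, 1000)),
                          gene("focal", orf = c(1001, 1500)))
    expect_equal(igrDistance(ann0, upstreamSameStrandPartner(ann0, "focal")), 0)
    # 50 bp overlap
    annov <- toyAnnotation(gene("up", orf = c(500, 1000)),
                           gene("focal", orf = c(951, 1500)))
    expect_equal(igrDistance(annov, upstreamSameStrandPartner(annov, "focal")), -50)
})

test_that("IGRterm is the signed span gap of convergent pairs", {
    gap <- toyAnnotation(gene("t", orf = c(1, 1000)),
                         gene("rv", orf = c(1101, 2000), strand = "-"))
    expect_equal(igrTermDistance(gap, downstreamReversePartner(gap, "t")), 100)
    ov <- toyAnnotation(gene("t", orf = c(1, 1000)),
                        gene("rv", orf = c(901, 1800), strand = "-"))
    expect_equal(igrTermDistance(ov, downstreamReversePartner(ov, "t")), -100)
    # relation mismatches are rejected
    tandem <- toyAnnotation(gene("a", orf = c(1, 1000)),
                            gene("b", orf = c(1101, 2000)))
    up <- upstreamSameStrandPartner(tandem, "b")
    expect_error(igrTermDistance(tandem, up), "downstream_reverse")
    expect_error(igrDistance(gap, downstreamReversePartner(gap, "t")),
                 "upstream_same_strand")
    # cross-chromosome pairings are invalid
    two <- toyAnnotation(gene("a", orf = c(1, 1000)),
                         gene("b", orf = c(1101, 2000), chrom = "chrII"))
    fake <- structure(list(focal = "a", partner = "b",
                           relation = "upstream_same_strand",
                           distance_bp = 5L), class = "gene_pairing")
    expect_error(igrDistance(two, fake), "different chromosomes")
})

test_that("antisense fraction spans [0, 1] and matches the mask oracle", {
    ann <- toyAnnotation(gene("g", orf = c(1001, 2000)),
                         gene("half", orf = c(1501, 2000), strand = "-"))
    expect_equal(antisenseFraction(ann, "g"), 0.5)
    expect_equal(antisenseFraction(ann, "half"), 1)
    solo <- toyAnnotation(gene("g", orf = c(1001, 2000)))
    expect_equal(antisenseFraction(solo, "g"), 0)
    # vectorized universe agrees with the per-gene route
    set.seed(21)
    tb <- randomGeneTable(20)
    a <- tableToAnnotation(tb)
    obs <- contextObservations(a, "f_as")
    expect_equal(obs$value,
                 vapply(obs$gene_id, function(g) antisenseFraction(a, g),
                        numeric(1)),
                 ignore_attr = TRUE)
})

test_that("exhaustive permutation test enumerates all subsets exactly", {
    vals <- c(g1 = 1, g2 = 2, g3 = 3, g4 = 4)
    r <- permutationMedianTest(vals, c("g1", "g2"), mode = "exhaustive",
                               setSize = 2)
    expect_equal(sort(r$null_stats), c(1.5, 2, 2.5, 2.5, 3, 3.5))
    expect_identical(r$k_le, 1L)
    expect_equal(r$p_le, 1 / 6)
    # degenerate case: the observed set is the whole universe
    rall <- permutationMedianTest(vals, names(vals), nRandomSets = 50,
                                  seed = 1, setSize = 4)
    expect_equal(rall$p_le, 1)
    expect_equal(rall$p_ge, 1)
    expect_error(permutationMedianTest(vals, "g1", setSize = 9),
                 "setSize")
})

test_that("sampled permutation test is seeded, add-one, and tie-conservative", {
    set.seed(33)
    vals <- setNames(c(1, 2, rep(100, 38)), sprintf("g%02d", 1:40))
    r1 <- permutationMedianTest(vals, c("g01", "g02"), nRandomSets = 50,
                                seed = 99)
    r2 <- permutationMedianTest(vals, c("g01", "g02"), nRandomSets = 50,
                                seed = 99)
    expect_identical(r1$null_stats, r2$null_stats)
    expect_identical(r1$k_le, 0L)
    expect_equal(r1$p_le, 1 / 51)
    expect_identical(r1$p_report, "< 1/50")
    # ties count on both sides: k_le + k_ge >= n
    tied <- setNames(rep(c(1, 2), 10), sprintf("t%02d", 1:20))
    rt <- permutationMedianTest(tied, c("t01", "t03"), nRandomSets = 200,
                                seed = 5)
    expect_gte(rt$k_le + rt$k_ge, rt$n_sets)
    # NA values leave the universe, observed genes must have values
    withna <- c(vals, gNA = NA)
    expect_message(permutationMedianTest(withna, c("g01", "g02"),
                                         nRandomSets = 10, seed = 1),
                   "excluded")
    expect_error(suppressMessages(
        permutationMedianTest(withna, c("g01", "gNA"), nRandomSets = 10,
                              seed = 1)), "without a value")
})

test_that("signed-rank departure test: boundary cases and one exact enumeration", {
    expect_warning(p0 <- wilcoxonDepartureFromZero(c(0, 0, 0)), "zero")
    expect_equal(p0, 1)
    expect_equal(wilcoxonDepartureFromZero(c(1, 2, 3)), 0.25)
    set.seed(17)
    x <- rnorm(12)
    expect_equal(wilcoxonDepartureFromZero(x), enumSignedRankP(x))
    # large-n path returns a valid approximate p
    y <- rnorm(60, 0.2)
    p <- wilcoxonDepartureFromZero(y)
    expect_true(p > 0 && p <= 1)
})

test_that("rank-sum comparison: textbook case, identical groups, exact vs enumeration", {
    expect_equal(ranksumCompare(c(1, 2, 3), c(10, 11, 12)), 0.1)
    expect_gte(ranksumCompare(c(1, 2, 3, 4), c(1, 2, 3, 4)), 0.99)
    set.seed(19)
    for (i in 1:5) {
        a <- rnorm(sample(3:6, 1)); b <- rnorm(sample(3:6, 1))
        expect_equal(ranksumCompare(a, b, exact = TRUE), enumRankSumP(a, b))
    }
})

test_that("KS set-vs-null comparison: degenerate extremes and ECDF-sweep oracle", {
    same <- c(0.1, 0.4, 0.4, 0.9)
    r <- ksSetVsNull(same, same)
    expect_equal(r$D, 0)
    expect_equal(r$p, 1)
    disjoint <- ksSetVsNull(c(1, 2, 3), c(10, 11, 12))
    expect_equal(disjoint$D, 1)
    set.seed(23)
    x <- rnorm(15); y <- rnorm(20, 0.5)
    grid <- sort(c(x, y))
    d_oracle <- max(abs(ecdf(x)(grid) - ecdf(y)(grid)))
    expect_equal(ksSetVsNull(x, y)$D, d_oracle)
})

test_that("IGR and IGRterm are invariant under reverse-complementing the annotation", {
    set.seed(29)
    tb <- randomGeneTable(25, n_chrom = 1)
    L <- 10000L
    rc <- data.frame(id = tb$id, chrom = tb$chrom,
                     strand = ifelse(tb$strand == "+", "-", "+"),
                     start = L - tb$end + 1L, end = L - tb$start + 1L,
                     stringsAsFactors = FALSE)
    a1 <- tableToAnnotation(tb)
    a2 <- tableToAnnotation(rc)
    for (q in c("igr", "igr_term")) {
        o1 <- contextObservations(a1, q)
        o2 <- contextObservations(a2, q)
        expect_equal(o1$value, o2$value[match(o1$gene_id, o2$gene_id)])
    }
})
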