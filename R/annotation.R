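#' Build a GenomeAnnotation from a gene table
#'
#' The workhorse constructor used by [readGFF3()], the synthetic-data
#' generator, and tests. One row per gene; UTR coordinates may be `NA` when a
#' UTR is not annotated. Coordinates are 1-based inclusive (the GFF3 and
#' GRanges convention).
#'
#' @param tbl data.frame with columns `gene_id`, `chrom`, `strand` (`"+"` or
#'   `"-"`), `orf_start`, `orf_end`, and optionally `utr5_start`, `utr5_end`,
#'   `utr3_start`, `utr3_end` (NA = absent) and `biotype` (default `"mRNA"`).
#' @param chromLengths named integer vector of chromosome lengths; when `NULL`
#'   lengths are left unset.
#' @return A [GenomeAnnotation-class] object.
#' @export
annotationFromTable <- function(tbl, chromLengths = NULL) {
    tbl <- as.data.frame(tbl)
    stopifnot(all(c("gene_id", "chrom", "strand", "orf_start", "orf_end") %in%
                  colnames(tbl)))
    n <- nrow(tbl)
    for (col in c("utr5_start", "utr5_end", "utr3_start", "utr3_end"))
        if (!col %in% colnames(tbl)) tbl[[col]] <- NA_integer_
    if (!"biotype" %in% colnames(tbl)) tbl$biotype <- "mRNA"
    span_start <- pmin(tbl$orf_start, tbl$utr5_start, tbl$utr3_start, na.rm = TRUE)
    span_end <- pmax(tbl$orf_end, tbl$utr5_end, tbl$utr3_end, na.rm = TRUE)
    chroms <- unique(as.character(tbl$chrom))
    si <- if (is.null(chromLengths)) {
        Seqinfo(seqnames = chroms)
    } else {
        if (!all(chroms %in% names(chromLengths)))
            stop("chromLengths missing entries for: ",
                 paste(setdiff(chroms, names(chromLengths)), collapse = ", "))
        Seqinfo(seqnames = names(chromLengths),
                seqlengths = as.integer(chromLengths))
    }
    mk <- function(keep, s, e) {
        gr <- GRanges(as.character(tbl$chrom)[keep],
                      IRanges(s[keep], e[keep]),
                      strand = as.character(tbl$strand)[keep],
                      seqinfo = si)
        mcols(gr)$gene_id <- as.character(tbl$gene_id)[keep]
        gr
    }
    genes <- mk(rep(TRUE, n), span_start, span_end)
    mcols(genes)$biotype <- as.character(tbl$biotype)
    mcols(genes)$has_utr5 <- !is.na(tbl$utr5_start)
    mcols(genes)$has_utr3 <- !is.na(tbl$utr3_start)
    new("GenomeAnnotation",
        genes = genes,
        orf = mk(rep(TRUE, n), tbl$orf_start, tbl$orf_end),
        utr5 = mk(!is.na(tbl$utr5_start), tbl$utr5_start, tbl$utr5_end),
        utr3 = mk(!is.na(tbl$utr3_start), tbl$utr3_start, tbl$utr3_end))
}

#' Accessors for GenomeAnnotation
#'
#' @param x,annotation a [GenomeAnnotation-class].
#' @return `geneIds`: character vector; `geneSpans`, `orfRanges`,
#'   `utr5Ranges`, `utr3Ranges`: `GRanges`; `chromLengths`: named integer
#'   vector; `geneModel`: list describing one gene.
#' @name annotation-accessors
#' @export
geneIds <- function(x) mcols(x@genes)$gene_id

#' @rdname annotation-accessors
#' @export
geneSpans <- function(x) x@genes

#' @rdname annotation-accessors
#' @export
orfRanges <- function(x) x@orf

#' @rdname annotation-accessors
#' @export
utr5Ranges <- function(x) x@utr5

#' @rdname annotation-accessors
#' @export
utr3Ranges <- function(x) x@utr3

#' @rdname annotation-accessors
#' @export
chromLengths <- function(x) seqlengths(x@genes)

#' @rdname annotation-accessors
#' @param geneId single gene identifier.
#' @export
geneModel <- function(annotation, geneId) {
    i <- .geneIndex(annotation, geneId)
    ids3 <- mcols(annotation@utr3)$gene_id
    ids5 <- mcols(annotation@utr5)$gene_id
    list(gene_id = geneId,
         biotype = mcols(annotation@genes)$biotype[i],
         strand = as.character(strand(annotation@genes))[i],
         span = annotation@genes[i],
         orf = annotation@orf[i],
         utr5 = if (geneId %in% ids5) annotation@utr5[match(geneId, ids5)] else NULL,
         utr3 = if (geneId %in% ids3) annotation@utr3[match(geneId, ids3)] else NULL)
}

setMethod("show", "GenomeAnnotation", function(object) {
    cat(sprintf("GenomeAnnotation: %d genes on %d chromosome(s)\n",
                length(object@genes), length(seqlevels(object@genes))))
    cat(sprintf("  with 3'UTR: %d | with 5'UTR: %d | biotypes: %s\n",
                sum(mcols(object@genes)$has_utr3),
                sum(mcols(object@genes)$has_utr5),
                paste(names(table(mcols(object@genes)$biotype)), collapse = ", ")))
})

setMethod("length", "GenomeAnnotation", function(x) length(x@genes))

.geneIndex <- function(annotation, geneId) {
    i <- match(geneId, geneIds(annotation))
    if (is.na(i)) stop("unknown gene_id: ", geneId)
    i
}

## ---- GFF3 I/O --------------------------------------------------------------

.UTR5_NAMES <- c("five_prime_UTR", "5'UTR", "UTR5", "five_prime_utr")
.UTR3_NAMES <- c("three_prime_UTR", "3'UTR", "UTR3", "three_prime_utr")

#' Read a genome annotation from GFF3
#'
#' Expects `gene` rows (with `ID` and optionally `biotype` attributes), `CDS`
#' rows and UTR rows carrying a `Parent` (or `ID`) pointing at the gene.
#' Genes without an annotated 3'UTR are retained (flagged via `has_utr3`) so
#' downstream read-through analysis can exclude them while expression analysis
#' keeps them. Chromosome lengths are taken from `chromLengths`, else from
#' `##sequence-region` pragmas, else from the maximal annotated coordinate.
#'
#' @param path GFF3 file.
#' @param utrFeatureNames list with elements `utr5` and `utr3`: feature type
#'   names accepted for the two UTRs.
#' @param chromLengths optional named vector, or path to a two-column TSV
#'   (chrom, length).
#' @return A [GenomeAnnotation-class].
#' @export
readGFF3 <- function(path, utrFeatureNames = list(utr5 = .UTR5_NAMES,
                                                  utr3 = .UTR3_NAMES),
                     chromLengths = NULL) {
    lines <- readLines(path)
    body <- !startsWith(lines, "#") & nzchar(lines)
    nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
    if (any(nfield != 9L)) {
        bad <- which(body)[which(nfield != 9L)[1L]]
        stop(sprintf("malformed GFF3 line %d in '%s': expected 9 tab-separated fields",
                     bad, path))
    }
    gr <- rtracklayer::import(path, format = "gff3")
    typ <- as.character(gr$type)
    is_gene <- typ == "gene"
    if (!any(is_gene)) stop("no 'gene' features found in ", path)
    gid <- as.character(gr$ID)
    parent <- vapply(gr$Parent, function(p) if (length(p)) p[[1L]] else NA_character_,
                     character(1))
    owner <- ifelse(is.na(parent), gid, parent)

    genes <- gr[is_gene]
    ids <- as.character(genes$ID)
    if (anyNA(ids)) stop("gene feature without ID attribute in ", path)
    if (anyDuplicated(ids))
        stop("duplicated gene_id in ", path, ": ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))

    pick <- function(types) {
        sel <- typ %in% types
        sub <- gr[sel]
        key <- owner[sel]
        # hull per gene (isoform handling is a non-goal: one interval per gene)
        sp <- split(seq_along(sub), key)
        t(vapply(sp, function(ix) c(min(start(sub)[ix]), max(end(sub)[ix])),
                 numeric(2)))
    }
    cds <- pick("CDS")
    if (is.null(dim(cds)) || nrow(cds) == 0L) stop("no CDS features found in ", path)
    u5 <- pick(utrFeatureNames$utr5)
    u3 <- pick(utrFeatureNames$utr3)
    at <- function(m, id, j) if (!is.null(dim(m)) && id %in% rownames(m)) m[id, j] else NA_integer_

    tbl <- data.frame(
        gene_id = ids,
        chrom = as.character(seqnames(genes)),
        strand = as.character(strand(genes)),
        orf_start = vapply(ids, at, numeric(1), m = cds, j = 1L),
        orf_end = vapply(ids, at, numeric(1), m = cds, j = 2L),
        utr5_start = vapply(ids, at, numeric(1), m = u5, j = 1L),
        utr5_end = vapply(ids, at, numeric(1), m = u5, j = 2L),
        utr3_start = vapply(ids, at, numeric(1), m = u3, j = 1L),
        utr3_end = vapply(ids, at, numeric(1), m = u3, j = 2L),
        biotype = if (!is.null(genes$biotype)) {
            ifelse(is.na(genes$biotype), "mRNA", as.character(genes$biotype))
        } else "mRNA",
        stringsAsFactors = FALSE)
    if (anyNA(tbl$orf_start))
        stop("gene(s) without CDS: ",
             paste(tbl$gene_id[is.na(tbl$orf_start)], collapse = ", "))

    cl <- .resolveChromLengths(chromLengths, path, tbl)
    annotationFromTable(tbl, chromLengths = cl)
}

.resolveChromLengths <- function(chromLengths, path, tbl) {
    if (is.character(chromLengths) && length(chromLengths) == 1L &&
        file.exists(chromLengths)) {
        d <- utils::read.table(chromLengths, sep = "\t", header = FALSE,
                               stringsAsFactors = FALSE)
        chromLengths <- stats::setNames(as.integer(d[[2L]]), d[[1L]])
    }
    if (!is.null(chromLengths)) return(chromLengths)
    prag <- grep("^##sequence-region", readLines(path), value = TRUE)
    if (length(prag)) {
        parts <- strsplit(trimws(prag), "\\s+")
        return(stats::setNames(vapply(parts, function(p) as.integer(p[4L]), integer(1)),
                               vapply(parts, `[`, character(1), 2L)))
    }
    ends <- tapply(pmax(tbl$orf_end, tbl$utr3_end, tbl$utr5_end, na.rm = TRUE),
                   tbl$chrom, max)
    stats::setNames(as.integer(ends), names(ends))
}

#' Write a GenomeAnnotation to GFF3
#'
#' Emits one `gene` row per gene plus `CDS` and UTR child rows;
#' `##sequence-region` pragmas carry the chromosome lengths.
#' `readGFF3(writeGFF3(x, f))` round-trips losslessly.
#'
#' @param annotation a [GenomeAnnotation-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGFF3 <- function(annotation, path) {
    ids <- geneIds(annotation)
    row <- function(gr, type, id, parent = NA_character_) {
        attr <- if (is.na(parent)) {
            sprintf("ID=%s;biotype=%s", id,
                    mcols(annotation@genes)$biotype[match(id, ids)])
        } else sprintf("ID=%s;Parent=%s", paste0(id, ":", tolower(type)), parent)
        sprintf("%s\ttilingRT\t%s\t%d\t%d\t.\t%s\t.\t%s",
                as.character(seqnames(gr)), type, start(gr), end(gr),
                as.character(strand(gr)), attr)
    }
    out <- c("##gff-version 3")
    sl <- chromLengths(annotation)
    for (ch in names(sl))
        if (!is.na(sl[[ch]]))
            out <- c(out, sprintf("##sequence-region %s 1 %d", ch, sl[[ch]]))
    ids5 <- mcols(annotation@utr5)$gene_id
    ids3 <- mcols(annotation@utr3)$gene_id
    for (i in seq_along(ids)) {
        id <- ids[i]
        out <- c(out, row(annotation@genes[i], "gene", id))
        if (id %in% ids5)
            out <- c(out, row(annotation@utr5[match(id, ids5)],
                              "five_prime_UTR", id, id))
        out <- c(out, row(annotation@orf[i], "CDS", id, id))
        if (id %in% ids3)
            out <- c(out, row(annotation@utr3[match(id, ids3)],
                              "three_prime_UTR", id, id))
    }
    writeLines(out, path)
    invisible(path)
}

## ---- gene pairings ---------------------------------------------------------

.pairing <- function(focal, partner, relation, distance)
    structure(list(focal = focal, partner = partner, relation = relation,
                   distance_bp = as.integer(distance)),
              class = "gene_pairing")

#' @export
print.gene_pairing <- function(x, ...) {
    cat(sprintf("gene pairing [%s]: %s ~ %s, distance %d bp\n",
                x$relation, x$focal, x$partner, x$distance_bp))
    invisible(x)
}

#' Nearest same-strand upstream neighbour (the gDWN-1 partner)
#'
#' Finds, orientation-aware, the nearest gene on the same chromosome and
#' strand lying upstream of the focal gene (both its ends 5' of the focal
#' gene's corresponding ends, so slightly overlapping tandem pairs still
#' pair, with a negative distance). The intergenic distance is measured
#' between gene spans (3'UTR end of the partner to 5'UTR start of the focal
#' gene when UTRs are annotated, since spans include them). Ties are broken
#' by lexicographic gene_id.
#'
#' @param annotation a [GenomeAnnotation-class].
#' @param geneId focal gene.
#' @param skipOpposite if `TRUE` (default) opposite-strand genes lying in
#'   between are ignored; if `FALSE` the pairing is returned only when the
#'   nearest upstream gene on *any* strand is the same-strand one.
#' @return A `gene_pairing` (focal, partner, relation, `distance_bp` = IGR,
#'   negative when the spans overlap), or `NULL` when no upstream same-strand
#'   gene exists.
#' @export
upstreamSameStrandPartner <- function(annotation, geneId, skipOpposite = TRUE) {
    i <- .geneIndex(annotation, geneId)
    g <- annotation@genes
    s <- as.character(strand(g))[i]
    ch <- as.character(seqnames(g))[i]
    on_chrom <- as.character(seqnames(g)) == ch & geneIds(annotation) != geneId
    same <- on_chrom & as.character(strand(g)) == s
    if (s == "+") {
        cand <- which(same & start(g) < start(g)[i] & end(g) < end(g)[i])
        if (!length(cand)) return(NULL)
        best_end <- max(end(g)[cand])
        cand <- cand[end(g)[cand] == best_end]
        j <- cand[order(geneIds(annotation)[cand])][1L]
        if (!skipOpposite) {
            blockers <- which(on_chrom & start(g) < start(g)[i] &
                              end(g) < end(g)[i] & end(g) > end(g)[j])
            if (length(blockers)) return(NULL)
        }
        d <- start(g)[i] - end(g)[j] - 1L
    } else {
        cand <- which(same & end(g) > end(g)[i] & start(g) > start(g)[i])
        if (!length(cand)) return(NULL)
        best_start <- min(start(g)[cand])
        cand <- cand[start(g)[cand] == best_start]
        j <- cand[order(geneIds(annotation)[cand])][1L]
        if (!skipOpposite) {
            blockers <- which(on_chrom & end(g) > end(g)[i] &
                              start(g) > start(g)[i] & start(g) < start(g)[j])
            if (length(blockers)) return(NULL)
        }
        d <- start(g)[j] - end(g)[i] - 1L
    }
    .pairing(geneId, geneIds(annotation)[j], "upstream_same_strand", d)
}

#' First downstream gene in reverse orientation (the gTERM+1RV partner)
#'
#' Finds, orientation-aware, the first gene on the opposite strand whose span
#' reaches to or beyond the focal gene's 3' end, i.e. the reverse-oriented
#' gene a read-through transcript would run into. `distance_bp` is the gap
#' between the focal 3' end and the partner's 3'-end-facing boundary; it is
#' negative exactly when the two spans overlap (the convergent-overlap case).
#'
#' @inheritParams upstreamSameStrandPartner
#' @return A `gene_pairing` with relation `"downstream_reverse"`, or `NULL`.
#' @export
downstreamReversePartner <- function(annotation, geneId) {
    i <- .geneIndex(annotation, geneId)
    g <- annotation@genes
    s <- as.character(strand(g))[i]
    ch <- as.character(seqnames(g))[i]
    opp <- as.character(seqnames(g)) == ch &
           as.character(strand(g)) != s & geneIds(annotation) != geneId
    if (s == "+") {
        cand <- which(opp & end(g) >= end(g)[i])
        if (!length(cand)) return(NULL)
        d_all <- start(g)[cand] - end(g)[i] - 1L
    } else {
        cand <- which(opp & start(g) <= start(g)[i])
        if (!length(cand)) return(NULL)
        d_all <- start(g)[i] - end(g)[cand] - 1L
    }
    dmin <- min(d_all)
    cand <- cand[d_all == dmin]
    j <- cand[order(geneIds(annotation)[cand])][1L]
    .pairing(geneId, geneIds(annotation)[j], "downstream_reverse", dmin)
}

#' Bases of a gene covered by opposite-strand genes
#'
#' Length of the intersection of the focal gene's span with the union of all
#' opposite-strand gene spans on its chromosome.
#'
#' @inheritParams upstreamSameStrandPartner
#' @return Integer bp in `[0, span width]`.
#' @export
antisenseOverlapBp <- function(annotation, geneId) {
    i <- .geneIndex(annotation, geneId)
    g <- annotation@genes
    s <- as.character(strand(g))[i]
    ch <- as.character(seqnames(g))[i]
    opp <- which(as.character(seqnames(g)) == ch & as.character(strand(g)) != s)
    if (!length(opp)) return(0L)
    cover <- reduce(IRanges(start(g)[opp], end(g)[opp]))
    ov <- IRanges::intersect(IRanges(start(g)[i], end(g)[i]), cover)
    as.integer(sum(width(ov)))
}
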