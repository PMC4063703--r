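#' Construct a PeptideMatrix
#'
#' @param counts data.frame with columns `bait`, `background`, `prey`,
#'   `peptides` (unique-peptide counts). Zero-count rows may be omitted:
#'   absent combinations count as zero.
#' @param controlBait name of the no-tag control bait (a value of the `bait`
#'   column), or `NA` when no control purification is available.
#' @return A [PeptideMatrix-class].
#' @export
PeptideMatrix <- function(counts, controlBait = NA_character_) {
    counts <- as.data.frame(counts)
    for (col in c("bait", "background", "prey"))
        counts[[col]] <- as.character(counts[[col]])
    counts$peptides <- as.integer(counts$peptides)
    new("PeptideMatrix", counts = counts,
        controlBait = as.character(controlBait), removedPreys = character())
}

#' @rdname PeptideMatrix
#' @param path long-format TSV with columns `bait`, `background`, `prey` and
#'   `unique_peptides` (or `peptides`).
#' @export
readPeptideMatrix <- function(path, controlBait = NA_character_) {
    d <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    if ("unique_peptides" %in% colnames(d) && !"peptides" %in% colnames(d))
        names(d)[names(d) == "unique_peptides"] <- "peptides"
    PeptideMatrix(d, controlBait = controlBait)
}

#' @rdname PeptideMatrix
#' @param x a `PeptideMatrix`.
#' @export
peptideCounts <- function(x) x@counts

#' @rdname PeptideMatrix
#' @export
baits <- function(x) sort(unique(x@counts$bait))

#' @rdname PeptideMatrix
#' @export
preys <- function(x) sort(unique(x@counts$prey))

setMethod("show", "PeptideMatrix", function(object) {
    cat(sprintf("PeptideMatrix: %d baits x %d backgrounds x %d preys (%d entries)\n",
                length(unique(object@counts$bait)),
                length(unique(object@counts$background)),
                length(unique(object@counts$prey)), nrow(object@counts)))
    if (!is.na(object@controlBait))
        cat("  no-tag control: ", object@controlBait, "\n", sep = "")
    if (length(object@removedPreys))
        cat("  removed as non-specific: ",
            paste(object@removedPreys, collapse = ", "), "\n", sep = "")
})

.count <- function(df, bait, background, prey) {
    i <- which(df$bait == bait & df$background == background & df$prey == prey)
    if (length(i)) df$peptides[i] else 0L
}

#' Remove non-specific preys using the no-tag control
#'
#' Every prey recovered with at least one unique peptide in the no-tag
#' control purification is discarded as non-specific from all entries of the
#' matrix. Idempotent; the removal list is recorded on the object.
#'
#' @param matrix a [PeptideMatrix-class] with a control bait.
#' @return The filtered [PeptideMatrix-class].
#' @export
filterNonspecific <- function(matrix) {
    if (is.na(matrix@controlBait))
        stop("no no-tag control purification present: cannot filter")
    df <- matrix@counts
    bad <- unique(df$prey[df$bait == matrix@controlBait & df$peptides >= 1L])
    out <- matrix
    out@counts <- df[!df$prey %in% bad, , drop = FALSE]
    rownames(out@counts) <- NULL
    out@removedPreys <- sort(unique(c(matrix@removedPreys, bad)))
    if (length(bad))
        message("removed ", length(bad), " non-specific prey(s): ",
                paste(sort(bad), collapse = ", "))
    out
}

# deletion backgrounds name the deleted gene; prey <-> background matching is
# case-insensitive ("Ppn1" prey vs "ppn1" deletion)
.normName <- function(x) tolower(x)

#' Infer deletion-dependency edges from an AP-MS matrix
#'
#' For each bait and each deletion background, a prey depends on the deleted
#' gene when it is recovered with at least `minPeptides` unique peptides in
#' the wild-type background but is absent (zero peptides, the default rule)
#' in the deletion background. The prey whose own gene is deleted is skipped
#' (trivially absent). With `rule = "fold_drop"` a prey instead qualifies
#' when its count drops to at most `count_wt / foldDrop`.
#'
#' @param matrix a filtered [PeptideMatrix-class].
#' @param minPeptides minimum wild-type unique-peptide count (default 2; a
#'   single peptide is weak evidence).
#' @param wildtypeLabel background label of the wild-type purification.
#' @param rule `"absent"` (default) or `"fold_drop"`.
#' @param foldDrop fold reduction required under `rule = "fold_drop"`.
#' @return data.frame of edges: `prey`, `bait`, `requires` (deletion label),
#'   `count_wt`, `count_del`.
#' @export
inferDependencies <- function(matrix, minPeptides = 2L, wildtypeLabel = "wt",
                              rule = c("absent", "fold_drop"), foldDrop = 10) {
    rule <- match.arg(rule)
    df <- matrix@counts
    if (!is.na(matrix@controlBait))
        df <- df[df$bait != matrix@controlBait, , drop = FALSE]
    edges <- list()
    for (bait in sort(unique(df$bait))) {
        sub <- df[df$bait == bait, , drop = FALSE]
        bgs <- setdiff(sort(unique(sub$background)), wildtypeLabel)
        if (!wildtypeLabel %in% sub$background) {
            warning("bait '", bait, "' has no '", wildtypeLabel,
                    "' background: contrasts skipped")
            next
        }
        wt <- sub[sub$background == wildtypeLabel, , drop = FALSE]
        for (bg in bgs) {
            for (i in seq_len(nrow(wt))) {
                prey <- wt$prey[i]
                if (.normName(prey) == .normName(bg)) next
                cwt <- wt$peptides[i]
                if (cwt < minPeptides) next
                cdel <- .count(sub, bait, bg, prey)
                hit <- if (rule == "absent") cdel == 0L
                       else cdel <= cwt / foldDrop
                if (hit)
                    edges[[length(edges) + 1L]] <-
                        data.frame(prey = prey, bait = bait, requires = bg,
                                   count_wt = cwt, count_del = cdel,
                                   stringsAsFactors = FALSE)
            }
        }
    }
    if (!length(edges))
        return(data.frame(prey = character(), bait = character(),
                          requires = character(), count_wt = integer(),
                          count_del = integer(), stringsAsFactors = FALSE))
    out <- do.call(rbind, edges)
    out <- out[order(out$prey, out$bait, out$requires), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Mutually dependent co-purification modules
#'
#' Two proteins are mutually dependent when each requires the other's gene
#' for association (edges in both directions, possibly via different baits).
#' Modules are the connected components (of size >= 2) of the resulting
#' mutual-dependency graph -- e.g. a phosphatase sub-module that detaches as
#' a unit from its host complex.
#'
#' @param edges edge table from [inferDependencies()].
#' @return list of character vectors (sorted protein names), largest first.
#' @export
dependencyModules <- function(edges) {
    if (!nrow(edges)) return(list())
    key <- unique(data.frame(a = .normName(edges$prey),
                             b = .normName(edges$requires)))
    mutual <- key[paste(key$b, key$a) %in% paste(key$a, key$b), , drop = FALSE]
    if (!nrow(mutual)) return(list())
    nodes <- unique(c(mutual$a, mutual$b))
    comp <- stats::setNames(seq_along(nodes), nodes)
    repeat {
        changed <- FALSE
        for (i in seq_len(nrow(mutual))) {
            ca <- comp[mutual$a[i]]; cb <- comp[mutual$b[i]]
            if (ca != cb) { comp[comp == max(ca, cb)] <- min(ca, cb); changed <- TRUE }
        }
        if (!changed) break
    }
    pretty <- stats::setNames(edges$prey, .normName(edges$prey))
    mods <- lapply(split(names(comp), comp),
                   function(ns) sort(unname(pretty[ns])))
    mods <- mods[lengths(mods) >= 2L]
    mods[order(-lengths(mods))]
}

#' Export a dependency graph as GraphViz DOT
#'
#' @param edges edge table from [inferDependencies()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
exportDependencyDot <- function(edges, path) {
    lines <- c("digraph dependencies {",
               sprintf("  \"%s\" -> \"%s\" [label=\"%s\"];",
                       edges$prey, edges$requires, edges$bait),
               "}")
    writeLines(lines, path)
    invisible(path)
}
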