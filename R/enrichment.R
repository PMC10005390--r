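#' @importFrom stats phyper
NULL

#' Read a GMT gene-set file
#'
#' One set per line: term id, description, then member genes, tab
#' separated.
#'
#' @param path file path.
#' @return named list of character vectors; names are term ids, the
#'   \code{"description"} attribute on each element keeps the second
#'   column.
#' @export
readGMT <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    out <- lapply(lines, function(l) {
        f <- strsplit(l, "\t", fixed = TRUE)[[1]]
        if (length(f) < 3L) stop("malformed GMT line: ", substr(l, 1, 40))
        genes <- unique(f[-(1:2)])
        attr(genes, "description") <- f[2]
        genes
    })
    names(out) <- vapply(lines, function(l)
        strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
    out
}

#' Read a two-column gene-to-term annotation TSV
#'
#' @param path file path to a headerless (or headered) TSV with columns
#'   gene, term.
#' @param header whether the file has a header row.
#' @return named list term -> gene id vector, as [readGMT()] returns.
#' @export
readGeneTermTSV <- function(path, header = FALSE) {
    df <- utils::read.table(path, sep = "\t", header = header,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("expected two columns: gene, term")
    split(df[[1]], df[[2]])
}

#' Hypergeometric over-representation test
#'
#' For each term, tests whether the study set overlaps the term's gene set
#' more than expected under sampling without replacement from the
#' universe: p = P(X >= k) with X ~ Hypergeometric(N, K, n), where N is
#' the universe size, K the term size, n the study size and k the
#' overlap. P-values are Benjamini-Hochberg adjusted across all tested
#' terms; a term is significant when the adjusted p < alpha.
#'
#' Study genes outside the universe are dropped with a warning; annotated
#' genes outside the universe are likewise ignored. Terms with zero study
#' overlap are still reported (k = 0, p = 1).
#'
#' @param study character vector of study gene ids (e.g. the common DEGs
#'   of a heterosis group).
#' @param annotation named list term -> gene ids ([readGMT()] /
#'   [readGeneTermTSV()] output).
#' @param universe background gene ids; typically all genes tested for
#'   differential expression.
#' @param alpha significance threshold on the adjusted p (default 0.05).
#' @param termNames optional named character vector of term descriptions.
#' @return data.frame(term, name, k, n, K, N, p, padj, foldEnrichment,
#'   significant), sorted by adjusted p then term id.
#' @examples
#' ann <- list(T1 = paste0("g", 1:5), T2 = paste0("g", 6:10))
#' hypergeometricEnrichment(paste0("g", 1:4), ann, paste0("g", 1:10))
#' @export
hypergeometricEnrichment <- function(study, annotation, universe,
                                     alpha = 0.05, termNames = NULL) {
    universe <- unique(universe)
    if (length(universe) == 0L) stop("empty universe")
    study <- unique(study)
    drop <- setdiff(study, universe)
    if (length(drop)) {
        warning(length(drop), " study genes outside the universe dropped")
        study <- intersect(study, universe)
    }
    if (length(study) == 0L) stop("empty study set")
    N <- length(universe)
    n <- length(study)
    rows <- lapply(names(annotation), function(term) {
        termGenes <- intersect(annotation[[term]], universe)
        K <- length(termGenes)
        k <- length(intersect(study, termGenes))
        p <- if (K == 0L) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
        data.frame(term = term,
                   name = if (!is.null(termNames) && term %in% names(termNames))
                              termNames[[term]]
                          else attr(annotation[[term]], "description") %||% term,
                   k = k, n = n, K = K, N = N, p = p,
                   foldEnrichment = if (K == 0L) NA_real_ else (k / n) / (K / N),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$padj <- bhAdjust(out$p)
    out$significant <- out$padj < alpha
    out <- out[order(out$padj, out$p, out$term), ]
    rownames(out) <- NULL
    out[, c("term", "name", "k", "n", "K", "N", "p", "padj",
            "foldEnrichment", "significant")]
}

#' Top enriched terms for a bubble plot
#'
#' The usual bubble-plot export: the n best terms by adjusted p (ties
#' broken lexicographically by term id), with overlap size (bubble size)
#' and fold enrichment.
#'
#' @param table an [hypergeometricEnrichment()] result.
#' @param n number of terms to keep (whole table if larger).
#' @param rankBy column to rank on, default "padj".
#' @return the top-n rows, columns term, name, k, foldEnrichment, padj.
#' @export
topTerms <- function(table, n = 10, rankBy = "padj") {
    if (nrow(table) == 0L) stop("empty enrichment table")
    ord <- order(table[[rankBy]], table$term)
    table[ord, ][seq_len(min(n, nrow(table))),
                 c("term", "name", "k", "foldEnrichment", "padj")]
}
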