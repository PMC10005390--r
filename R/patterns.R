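#' @importFrom utils write.table head
NULL

# Relation triple -> pattern lookup. Each comparison is coded 0 when not
# significant, otherwise the sign of the mean difference:
#   rFM = sign(F - M), rFH = sign(H - F), rMH = sign(H - M).
# The twelve patterns occupy twelve of the 27 possible triples; every
# other triple (including internally contradictory ones such as a
# significant F>M with both parent-hybrid comparisons non-significant) is
# unclassified.
patternLookup <- local({
    key <- function(fm, fh, mh) paste(fm, fh, mh, sep = ",")
    tab <- c(
        "1,-1,1"   = "P1",   # F>M, M<H<F
        "-1,1,-1"  = "P2",   # F<M, F<H<M
        "-1,1,0"   = "P3",   # F<M, H=M (so H>F)
        "1,-1,0"   = "P4",   # F>M, H=M (so H<F)
        "1,0,1"    = "P5",   # F>M, H=F (so H>M)
        "-1,0,-1"  = "P6",   # F<M, H=F (so H<M)
        "0,-1,-1"  = "P7",   # F=M, H below both
        "1,-1,-1"  = "P8",
        "-1,-1,-1" = "P9",
        "0,1,1"    = "P10",  # F=M, H above both
        "1,1,1"    = "P11",
        "-1,1,1"   = "P12")
    tab
})

#' Classify trio genes into the twelve expression patterns
#'
#' Maps each gene's three pairwise calls (female-vs-male FM,
#' female-vs-hybrid FH, male-vs-hybrid MH) to one of the patterns P1-P12:
#' a relation "X = Y" means that comparison is NOT significant, "X < Y" /
#' "X > Y" means it IS significant with the group means in that order.
#' P1/P2 are additive (hybrid strictly between the parents, all three
#' comparisons significant), P3-P6 dominant (hybrid equal to one parent,
#' different from the other, parents different), P7-P12 over-dominant
#' (hybrid below or above both parents). Call triples matching no pattern
#' — including contradictory ones — return "unclassified".
#'
#' @param sigFM,sigFH,sigMH logical vectors: is each comparison
#'   significant.
#' @param dirFM,dirFH,dirMH numeric signs of the mean differences,
#'   \code{sign(F - M)}, \code{sign(H - F)}, \code{sign(H - M)}; only
#'   consulted where the comparison is significant.
#' @return character vector of labels in \code{P1..P12, unclassified}.
#'   Genes significant in no comparison are a precondition violation and
#'   raise an error (the DEG universe is filtered upstream).
#' @examples
#' classifyGene(sigFM = TRUE, dirFM = 1, sigFH = TRUE, dirFH = -1,
#'              sigMH = FALSE, dirMH = 0)  # P4
#' @export
classifyGene <- function(sigFM, dirFM, sigFH, dirFH, sigMH, dirMH) {
    n <- length(sigFM)
    stopifnot(lengths(list(dirFM, sigFH, dirFH, sigMH, dirMH)) == n)
    if (any(!sigFM & !sigFH & !sigMH))
        stop("gene significant in no comparison: not in the DEG universe")
    r <- function(sig, dir) ifelse(sig, sign(dir), 0)
    key <- paste(r(sigFM, dirFM), r(sigFH, dirFH), r(sigMH, dirMH),
                 sep = ",")
    lab <- unname(patternLookup[key])
    lab[is.na(lab)] <- "unclassified"
    lab
}

#' Category of a pattern label
#'
#' @param pattern character vector of \code{P1..P12} or
#'   \code{unclassified}.
#' @return "additive" (P1-P2), "dominant" (P3-P6), "over-dominant"
#'   (P7-P12) or "none".
#' @export
patternCategory <- function(pattern) {
    out <- unname(PATTERN_CATEGORY[pattern])
    if (anyNA(out)) stop("unknown pattern label")
    out
}

#' Assemble the trio call set for one hybrid
#'
#' Restricts the three DE tables to the DEG universe (union of the three
#' DEG sets) and records group mean FPKMs, significance flags and
#' directions of the mean differences.
#'
#' @param trio list of DE tables \code{FM}, \code{FH}, \code{MH} for one
#'   hybrid, as produced by [runTrioDE()] (FM: A = female, B = male;
#'   FH: A = female, B = hybrid; MH: A = male, B = hybrid).
#' @param hybrid hybrid id stored in the result.
#' @return a [TrioCallSet-class] over the DEG universe.
#' @export
buildTrioCallSet <- function(trio, hybrid = "") {
    stopifnot(all(c("FM", "FH", "MH") %in% names(trio)))
    if (!identical(trio$FM$gene, trio$FH$gene) ||
        !identical(trio$FM$gene, trio$MH$gene))
        stop("the three DE tables must share one gene universe")
    keep <- trio$FM$isDEG | trio$FH$isDEG | trio$MH$isDEG
    meanF <- trio$FM$meanA[keep]
    meanM <- trio$FM$meanB[keep]
    meanH <- trio$FH$meanB[keep]
    new("TrioCallSet",
        hybrid = hybrid,
        geneIds = trio$FM$gene[keep],
        meanF = meanF, meanM = meanM, meanH = meanH,
        sigFM = trio$FM$isDEG[keep],
        sigFH = trio$FH$isDEG[keep],
        sigMH = trio$MH$isDEG[keep],
        dirFM = as.integer(sign(meanF - meanM)),
        dirFH = as.integer(sign(meanH - meanF)),
        dirMH = as.integer(sign(meanH - meanM)))
}

#' Pattern table for one hybrid's trio
#'
#' Applies [classifyGene()] to every gene of the trio's DEG universe.
#'
#' @param trio either a [TrioCallSet-class] or a list of the three DE
#'   tables (see [buildTrioCallSet()]).
#' @param hybrid hybrid id recorded in the output.
#' @return data.frame(gene, pattern, category) — the per-hybrid pattern
#'   table; genes outside the DEG universe are absent.
#' @export
classifyTrio <- function(trio, hybrid = "") {
    cs <- if (is(trio, "TrioCallSet")) trio else buildTrioCallSet(trio, hybrid)
    if (length(cs) == 0L)
        return(data.frame(gene = character(), pattern = character(),
                          category = character(), stringsAsFactors = FALSE))
    pat <- classifyGene(cs@sigFM, cs@dirFM, cs@sigFH, cs@dirFH,
                        cs@sigMH, cs@dirMH)
    data.frame(gene = cs@geneIds, pattern = pat,
               category = patternCategory(pat),
               stringsAsFactors = FALSE)
}

#' Pattern counts and category percentages for one hybrid
#'
#' @param patternTable data.frame(gene, pattern, category) from
#'   [classifyTrio()].
#' @return list with \code{counts} (named P1..P12 plus unclassified) and
#'   \code{categoryPct} (additive/dominant/over-dominant percentages of
#'   the classified genes; they sum to 100).
#' @export
summarizePatterns <- function(patternTable) {
    if (nrow(patternTable) == 0L) stop("empty pattern table")
    counts <- table(factor(patternTable$pattern, levels = PATTERN_LEVELS))
    counts <- setNames(as.integer(counts), PATTERN_LEVELS)
    list(counts = counts,
         categoryPct = categoryPercentages(counts[paste0("P", 1:12)]))
}

#' Category percentages from pattern counts
#'
#' @param counts numeric vector or single-row matrix of counts for
#'   P1..P12 (in order, or named).
#' @return named percentages of classified genes falling in the additive
#'   (P1-P2), dominant (P3-P6) and over-dominant (P7-P12) categories.
#' @export
categoryPercentages <- function(counts) {
    counts <- drop(as.matrix(counts))
    if (length(counts) != 12L) stop("expected 12 pattern counts")
    if (!is.null(names(counts))) counts <- counts[paste0("P", 1:12)]
    tot <- sum(counts)
    if (tot == 0) stop("no classified genes")
    c(additive = 100 * sum(counts[1:2]) / tot,
      dominant = 100 * sum(counts[3:6]) / tot,
      `over-dominant` = 100 * sum(counts[7:12]) / tot)
}

roundHalfUp <- function(x, digits = 0) {
    m <- 10^digits
    sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Cross-hybrid per-pattern average and standard error
#'
#' Summarises a hybrids x patterns count table the way diallel pattern
#' tables are usually printed: the per-pattern arithmetic mean rounded to
#' the nearest integer (half away from zero) and the standard error using
#' the population standard deviation (n divisor) over sqrt(n), to two
#' decimals.
#'
#' @param counts hybrids x 12 matrix or data.frame of pattern counts
#'   (columns P1..P12), one row per hybrid; >= 2 hybrids.
#' @return data.frame(pattern, average, se).
#' @examples
#' aggregateAcrossHybrids(rbind(rep(1, 12), rep(3, 12)))[1, ]
#' # average 2, se 0.71
#' @export
aggregateAcrossHybrids <- function(counts) {
    counts <- as.matrix(counts)
    if (nrow(counts) < 2L) stop("need counts from >= 2 hybrids")
    if (ncol(counts) != 12L) stop("expected 12 pattern columns")
    n <- nrow(counts)
    avg <- colMeans(counts)
    popsd <- sqrt(colMeans(sweep(counts, 2, avg)^2))
    data.frame(pattern = paste0("P", 1:12),
               average = as.integer(roundHalfUp(avg)),
               se = roundHalfUp(popsd / sqrt(n), 2),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Row-scaled expression for pattern heatmaps
#'
#' Z-scores each requested gene's expression across samples and attaches
#' its pattern label — the standard input for a clustered heatmap of
#' pattern-annotated genes. Constant genes are flagged
#' (\code{zeroVariance}) and exported as all-zero rather than failing.
#'
#' @param expr genes x samples expression matrix (or SummarizedExperiment
#'   with an \code{fpkm} assay).
#' @param patternTable data.frame(gene, pattern, ...) as from
#'   [classifyTrio()].
#' @param genes gene ids to export; default all genes of the pattern
#'   table. Unknown ids raise an error.
#' @param file optional TSV path to write.
#' @return data.frame with gene, pattern, zeroVariance and one scaled
#'   column per sample.
#' @export
exportPatternHeatmapData <- function(expr, patternTable,
                                     genes = patternTable$gene,
                                     file = NULL) {
    if (is(expr, "SummarizedExperiment")) {
        an <- SummarizedExperiment::assayNames(expr)
        expr <- if ("fpkm" %in% an) assay(expr, "fpkm") else assay(expr)
    }
    expr <- as.matrix(expr)
    bad <- setdiff(genes, rownames(expr))
    if (length(bad)) stop("genes absent from the expression matrix: ",
                          paste(head(bad, 5), collapse = ", "))
    bad <- setdiff(genes, patternTable$gene)
    if (length(bad)) stop("genes absent from the pattern table: ",
                          paste(head(bad, 5), collapse = ", "))
    sub <- expr[genes, , drop = FALSE]
    mu <- rowMeans(sub)
    sdv <- apply(sub, 1, sd)
    z <- (sub - mu) / ifelse(sdv == 0, 1, sdv)
    z[sdv == 0, ] <- 0
    out <- data.frame(gene = genes,
                      pattern = patternTable$pattern[match(genes, patternTable$gene)],
                      zeroVariance = sdv == 0,
                      z, check.names = FALSE, stringsAsFactors = FALSE)
    if (!is.null(file))
        write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
    out
}
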