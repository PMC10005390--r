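#' @importFrom stats p.adjust pt cor var sd
NULL

#' Pairwise differential expression between two replicate groups
#'
#' Per-gene two-group test. The default is a Welch two-sample t-test on
#' log2(x + 1)-transformed expression, which is exact, fast and
#' self-contained; \code{method = "nb"} fits a negative-binomial Wald GLM
#' (via DESeq2) and expects raw counts. P-values are Benjamini-Hochberg
#' adjusted and genes are flagged as differentially expressed at the
#' given FDR.
#'
#' Genes with zero variance in both groups and equal means get p = 1 (no
#' evidence); zero variance with unequal means gives p = 0 (perfect
#' separation).
#'
#' @param groupA,groupB genes x replicates matrices on a common gene
#'   universe (>= 2 replicates each). FPKM for the Welch method, counts for
#'   the NB method.
#' @param method "welch" or "nb".
#' @param epsilon pseudo-expression added before the log2 fold change
#'   (and the log transform), default 1.
#' @param fdr DEG threshold on the adjusted p-value.
#' @param logTransform apply log2(x + epsilon) before the Welch test
#'   (default TRUE); set FALSE if the input is already on log scale.
#' @return data.frame with one row per gene: \code{gene, meanA, meanB,
#'   log2fc, stat, p, fdr, isDEG}. \code{log2fc} is
#'   log2((meanB + epsilon)/(meanA + epsilon)) — positive when B > A.
#' @examples
#' a <- matrix(c(4, 5, 6), 1, dimnames = list("g1", NULL))
#' b <- matrix(c(14, 15, 16), 1, dimnames = list("g1", NULL))
#' deTest(a, b, logTransform = FALSE)$stat  # Welch t = 12.247
#' @export
deTest <- function(groupA, groupB, method = c("welch", "nb"),
                   epsilon = 1, fdr = 0.05, logTransform = TRUE) {
    method <- match.arg(method)
    groupA <- as.matrix(groupA); groupB <- as.matrix(groupB)
    if (ncol(groupA) < 2L || ncol(groupB) < 2L)
        stop("insufficient replication: need >= 2 replicates per group")
    if (nrow(groupA) != nrow(groupB) ||
        !identical(rownames(groupA), rownames(groupB)))
        stop("gene universes of the two groups must match")
    meanA <- rowMeans(groupA)
    meanB <- rowMeans(groupB)
    res <- switch(method,
                  welch = welchRows(groupA, groupB, epsilon, logTransform),
                  nb = nbWaldRows(groupA, groupB))
    adj <- bhAdjust(res$p)
    data.frame(gene = rownames(groupA) %||% as.character(seq_len(nrow(groupA))),
               meanA = meanA, meanB = meanB,
               log2fc = log2((meanB + epsilon) / (meanA + epsilon)),
               stat = res$stat, p = res$p, fdr = adj,
               isDEG = adj <= fdr,
               row.names = NULL, stringsAsFactors = FALSE)
}

# vectorised Welch t over rows
welchRows <- function(a, b, epsilon, logTransform) {
    if (logTransform) {
        a <- log2(a + epsilon)
        b <- log2(b + epsilon)
    }
    n1 <- ncol(a); n2 <- ncol(b)
    m1 <- rowMeans(a); m2 <- rowMeans(b)
    v1 <- apply(a, 1, var); v2 <- apply(b, 1, var)
    se2 <- v1 / n1 + v2 / n2
    t <- (m2 - m1) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * pt(-abs(t), df)
    flat <- se2 == 0
    p[flat] <- ifelse(m1[flat] == m2[flat], 1, 0)
    t[flat] <- ifelse(m1[flat] == m2[flat], 0, Inf * sign(m2 - m1)[flat])
    list(stat = t, p = p)
}

# negative-binomial Wald GLM on counts, delegated to DESeq2
nbWaldRows <- function(a, b) {
    if (!requireNamespace("DESeq2", quietly = TRUE))
        stop("method = 'nb' requires the DESeq2 package")
    cts <- cbind(a, b)
    storage.mode(cts) <- "integer"
    cond <- factor(rep(c("A", "B"), c(ncol(a), ncol(b))), levels = c("A", "B"))
    colnames(cts) <- paste0("s", seq_len(ncol(cts)))
    dds <- DESeq2::DESeqDataSetFromMatrix(cts, S4Vectors::DataFrame(condition = cond),
                                          ~condition)
    dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
    res <- DESeq2::results(dds, contrast = c("condition", "B", "A"))
    p <- res$pvalue
    p[is.na(p)] <- 1
    list(stat = res$stat, p = p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted p(i) = min over j >= i (rank order) of p(j) * m / j, capped at
#' 1, returned in the original order.
#'
#' @param pvalues numeric vector in [0, 1] (NAs not allowed).
#' @return adjusted p-values, same length and order.
#' @examples
#' bhAdjust(c(0.005, 0.1))  # 0.01, 0.10
#' @export
bhAdjust <- function(pvalues) {
    if (length(pvalues) == 0L) return(numeric())
    if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
        stop("p-values must lie in [0, 1]")
    p.adjust(pvalues, method = "BH")
}

#' Run the three trio comparisons for every hybrid of a design
#'
#' For each hybrid the three pairwise tests are female-vs-male (FM),
#' female-vs-hybrid (FH) and male-vs-hybrid (MH), run by [deTest()] on the
#' replicate columns of each material. FPKM values are used for the default
#' Welch method (computed with [countsToFPKM()] if absent) and raw counts
#' for \code{method = "nb"}.
#'
#' @param se a SummarizedExperiment as produced by [simulateTrioCounts()]
#'   or assembled from files: assays \code{counts} and/or \code{fpkm},
#'   colData columns \code{line} and \code{role}.
#' @param design data.frame(hybrid, female, male); defaults to
#'   \code{metadata(se)$trioDesign}.
#' @param fdr DEG threshold.
#' @param method,epsilon passed to [deTest()].
#' @return named list (one element per hybrid) of lists with DE tables
#'   \code{FM}, \code{FH}, \code{MH}. For FM the A group is the female and
#'   B the male parent; for FH/MH the B group is the hybrid.
#' @export
runTrioDE <- function(se, design = S4Vectors::metadata(se)$trioDesign,
                      fdr = 0.05, method = c("welch", "nb"), epsilon = 1) {
    method <- match.arg(method)
    if (is.null(design)) stop("a trio design is required")
    cd <- as.data.frame(colData(se))
    an <- SummarizedExperiment::assayNames(se)
    mat <- if (method == "nb") {
        if (!"counts" %in% an) stop("method = 'nb' needs a counts assay")
        assay(se, "counts")
    } else if ("fpkm" %in% an) {
        assay(se, "fpkm")
    } else {
        assay(countsToFPKM(se), "fpkm")
    }
    cols <- function(line) mat[, cd$line == line, drop = FALSE]
    out <- lapply(seq_len(nrow(design)), function(i) {
        f <- cols(design$female[i]); m <- cols(design$male[i])
        h <- cols(design$hybrid[i])
        list(FM = deTest(f, m, method = method, epsilon = epsilon, fdr = fdr),
             FH = deTest(f, h, method = method, epsilon = epsilon, fdr = fdr),
             MH = deTest(m, h, method = method, epsilon = epsilon, fdr = fdr))
    })
    names(out) <- design$hybrid
    out
}

#' Extract per-hybrid DEG id sets
#'
#' @param trioDE result of [runTrioDE()].
#' @return named list per hybrid of character-vector sets \code{FM},
#'   \code{FH}, \code{MH}.
#' @export
degSets <- function(trioDE) {
    lapply(trioDE, function(tr)
        lapply(tr, function(tab) tab$gene[tab$isDEG]))
}

#' DEG-ratio statistic for one hybrid
#'
#' The percentage of parent-parent DEGs that are also differential in at
#' least one parent-hybrid comparison:
#' 100 * |FM intersect (FH union MH)| / |FM|.
#'
#' @param collection per-hybrid DEG sets, as from [degSets()].
#' @param hybrid hybrid id to evaluate.
#' @return percentage in [0, 100].
#' @examples
#' sets <- list(h1 = list(FM = paste0("g", 1:10), FH = paste0("g", 1:4),
#'                        MH = paste0("g", 3:8)))
#' degRatio(sets, "h1")  # 80
#' @export
degRatio <- function(collection, hybrid) {
    if (!hybrid %in% names(collection)) stop("unknown hybrid: ", hybrid)
    s <- collection[[hybrid]]
    if (length(s$FM) == 0L)
        stop("DEG ratio undefined: no parent-parent DEGs for ", hybrid)
    100 * length(intersect(s$FM, union(s$FH, s$MH))) / length(s$FM)
}

#' Per-hybrid DEG counts and DEG ratio
#'
#' The summary table of a trio DE run: number of DEGs in each of the three
#' comparisons and the [degRatio()] statistic (NA when the hybrid has no
#' parent-parent DEGs).
#'
#' @param trioDE result of [runTrioDE()].
#' @return data.frame(hybrid, nFM, nFH, nMH, degRatio).
#' @export
deSummary <- function(trioDE) {
    sets <- degSets(trioDE)
    data.frame(
        hybrid = names(sets),
        nFM = vapply(sets, function(s) length(s$FM), integer(1)),
        nFH = vapply(sets, function(s) length(s$FH), integer(1)),
        nMH = vapply(sets, function(s) length(s$MH), integer(1)),
        degRatio = vapply(names(sets), function(h) {
            if (length(sets[[h]]$FM) == 0L) NA_real_
            else degRatio(sets, h)
        }, numeric(1)),
        row.names = NULL, stringsAsFactors = FALSE)
}

#' Replicate-correlation quality control
#'
#' Pearson correlation of log2(FPKM + 1) profiles for every pair of
#' samples, plus the minimum within-material replicate correlation — the
#' usual check that biological replicates agree (correlations above 0.90
#' are typically expected).
#'
#' Samples with constant profiles have undefined correlations, reported as
#' NA rather than an error.
#'
#' @param fpkm genes x samples FPKM matrix, or a SummarizedExperiment with
#'   an \code{fpkm} (or \code{counts}) assay.
#' @param lines per-sample material labels; defaults to
#'   \code{colData(se)$line}.
#' @return list with \code{pairs} (full sample x sample correlation
#'   matrix) and \code{perMaterial} (data.frame line, minReplicateCor).
#' @export
replicateCorrelation <- function(fpkm, lines = NULL) {
    if (is(fpkm, "SummarizedExperiment")) {
        if (is.null(lines)) lines <- colData(fpkm)$line
        an <- SummarizedExperiment::assayNames(fpkm)
        fpkm <- if ("fpkm" %in% an) assay(fpkm, "fpkm")
                else assay(countsToFPKM(fpkm), "fpkm")
    }
    fpkm <- as.matrix(fpkm)
    if (ncol(fpkm) < 2L) stop("need >= 2 samples")
    lf <- log2(fpkm + 1)
    sds <- apply(lf, 2, sd)
    cc <- suppressWarnings(cor(lf))
    cc[sds == 0, ] <- NA_real_
    cc[, sds == 0] <- NA_real_
    diag(cc) <- 1
    perMat <- NULL
    if (!is.null(lines)) {
        perMat <- do.call(rbind, lapply(unique(lines), function(l) {
            idx <- which(lines == l)
            minr <- if (length(idx) < 2L) NA_real_ else {
                sub <- cc[idx, idx]
                min(sub[upper.tri(sub)])
            }
            data.frame(line = l, minReplicateCor = minr,
                       stringsAsFactors = FALSE)
        }))
    }
    list(pairs = cc, perMaterial = perMat)
}
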