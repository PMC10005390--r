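#' @importFrom stats cor hclust cutree as.dist
NULL

#' Soft-threshold coexpression adjacency
#'
#' Unsigned weighted-network adjacency a_ij = |cor(x_i, x_j)|^beta over
#' samples. The diagonal is 1; zero-variance genes are removed with a
#' warning.
#'
#' @param expr genes x samples numeric matrix.
#' @param beta soft-threshold power (default 11).
#' @return symmetric gene x gene matrix with entries in [0, 1].
#' @examples
#' x <- matrix(rnorm(30), 3, 10)
#' range(adjacencyMatrix(x, beta = 6))
#' @export
adjacencyMatrix <- function(expr, beta = 11) {
    expr <- as.matrix(expr)
    if (ncol(expr) < 3L) stop("need >= 3 samples for a coexpression network")
    if (beta < 1) stop("beta must be >= 1")
    sds <- apply(expr, 1, sd)
    if (any(sds == 0)) {
        warning(sum(sds == 0), " zero-variance genes removed")
        expr <- expr[sds > 0, , drop = FALSE]
    }
    a <- abs(cor(t(expr)))^beta
    diag(a) <- 1
    a
}

#' Topological overlap matrix
#'
#' Unsigned TOM: TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' l_ij the number of shared weighted neighbours (sum over u != i,j of
#' a_iu a_uj) and k_i the weighted connectivity (sum over u != i of
#' a_iu). High TOM means two genes are both connected and share
#' neighbourhoods. The diagonal is defined as 1.
#'
#' @param adjacency symmetric adjacency with unit diagonal, entries in
#'   [0, 1].
#' @return symmetric matrix in [0, 1].
#' @examples
#' a <- matrix(1, 3, 3)
#' tomSimilarity(a)[1, 2]  # complete graph: 1
#' @export
tomSimilarity <- function(adjacency) {
    a <- as.matrix(adjacency)
    if (nrow(a) != ncol(a) || max(abs(a - t(a))) > 1e-12)
        stop("adjacency must be square and symmetric")
    k <- rowSums(a) - diag(a)
    # (a %*% a)_ij counts u = i and u = j with weight a_ii a_ij = a_ij each
    l <- a %*% a - 2 * a
    denom <- outer(k, k, pmin) + 1 - a
    tom <- (l + a) / denom
    diag(tom) <- 1
    tom
}

#' Detect modules by hierarchical clustering of the TOM
#'
#' Average-linkage clustering on dissimilarity 1 - TOM, cut at a fixed
#' height; clusters smaller than the minimum module size become
#' "unassigned". Labels are deterministic, ranked by size (M1 largest).
#'
#' @param tom TOM similarity from [tomSimilarity()].
#' @param minModuleSize smallest admissible module (default 50).
#' @param cutHeight dendrogram cut height on 1 - TOM (default 0.98).
#' @return named character vector gene -> label ("M1", "M2", ...,
#'   "unassigned").
#' @export
detectModules <- function(tom, minModuleSize = 50, cutHeight = 0.98) {
    n <- nrow(tom)
    genes <- rownames(tom) %||% as.character(seq_len(n))
    if (minModuleSize > n) {
        warning("minModuleSize exceeds the gene count; all genes unassigned")
        return(setNames(rep("unassigned", n), genes))
    }
    hc <- hclust(as.dist(1 - tom), method = "average")
    cl <- cutree(hc, h = cutHeight)
    relabelBySize(setNames(cl, genes), minModuleSize)
}

# integer cluster ids -> size-ranked labels M1.., small clusters unassigned
relabelBySize <- function(cl, minModuleSize) {
    sizes <- sort(table(cl), decreasing = TRUE)
    keep <- names(sizes)[sizes >= minModuleSize]
    lab <- rep("unassigned", length(cl))
    for (i in seq_along(keep))
        lab[cl == keep[i]] <- paste0("M", i)
    setNames(lab, names(cl))
}

#' Module eigengene
#'
#' First principal component across samples of the gene-standardized
#' module submatrix, scaled to unit norm and sign-oriented so that its
#' mean correlation with the member genes is positive.
#'
#' @param expr genes x samples matrix.
#' @param genes member gene ids (rows of \code{expr}).
#' @return list with \code{eigengene} (named per-sample vector, unit
#'   norm) and \code{varianceExplained} (fraction in [0, 1]).
#' @export
moduleEigengene <- function(expr, genes) {
    if (length(genes) == 0L) stop("empty module")
    x <- as.matrix(expr)[genes, , drop = FALSE]
    sds <- apply(x, 1, sd)
    if (all(sds == 0)) stop("all-constant module: eigengene undefined")
    x <- x[sds > 0, , drop = FALSE]
    z <- (x - rowMeans(x)) / apply(x, 1, sd)
    sv <- svd(z)
    e <- sv$v[, 1]
    if (mean(cor(e, t(z))) < 0) e <- -e
    list(eigengene = setNames(e / sqrt(sum(e^2)), colnames(expr)),
         varianceExplained = sv$d[1]^2 / sum(sv$d^2))
}

#' Correlate module eigengenes with a trait
#'
#' Pearson r per module with a two-sided t-test p (df = n - 2);
#' significant when p < alpha.
#'
#' @param eigengenes modules x samples matrix (rows named by module).
#' @param trait per-sample numeric vector, same sample order.
#' @param alpha significance level (default 0.05).
#' @return data.frame(module, r, p, significant).
#' @export
moduleTraitCor <- function(eigengenes, trait, alpha = 0.05) {
    eigengenes <- as.matrix(eigengenes)
    n <- ncol(eigengenes)
    if (length(trait) != n) stop("trait length must match sample count")
    if (n < 3L) stop("need >= 3 samples to correlate")
    r <- as.numeric(cor(trait, t(eigengenes)))
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), n - 2)
    data.frame(module = rownames(eigengenes) %||%
                   paste0("M", seq_len(nrow(eigengenes))),
               r = r, p = p, significant = p < alpha,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Mid-parent heterosis transform of expression
#'
#' Re-expresses each gene, per hybrid, as the mid-parent heterosis value
#' of its expression: 100 * (FPKM_H - MP) / MP with
#' MP = (FPKM_F + FPKM_M) / 2 of the line-mean FPKMs. The companion trait
#' for module-trait correlation in this mode is the MPV of the measured
#' trait. Genes whose MP is zero for any hybrid are dropped with a
#' warning.
#'
#' @param lineFPKM genes x lines matrix of per-line mean FPKM (see
#'   [lineMeans()]).
#' @param design data.frame(hybrid, female, male).
#' @return genes x hybrids matrix of expression MPVs.
#' @export
mpvTransform <- function(lineFPKM, design) {
    lineFPKM <- as.matrix(lineFPKM)
    need <- unique(c(design$hybrid, design$female, design$male))
    missing <- setdiff(need, colnames(lineFPKM))
    if (length(missing))
        stop("lines missing from the FPKM matrix: ",
             paste(missing, collapse = ", "))
    mp <- (lineFPKM[, design$female, drop = FALSE] +
           lineFPKM[, design$male, drop = FALSE]) / 2
    h <- lineFPKM[, design$hybrid, drop = FALSE]
    bad <- apply(mp == 0, 1, any)
    if (any(bad)) {
        warning(sum(bad), " genes with a zero mid-parent expression dropped")
        mp <- mp[!bad, , drop = FALSE]
        h <- h[!bad, , drop = FALSE]
    }
    out <- 100 * (h - mp) / mp
    colnames(out) <- design$hybrid
    out
}

#' Per-line mean expression
#'
#' Averages replicate columns per material (line), the "mean FPKM was
#' taken for each gene" convention.
#'
#' @param se SummarizedExperiment with an \code{fpkm} (or only
#'   \code{counts}) assay and a colData \code{line} column, or a plain
#'   matrix plus \code{lines}.
#' @param lines per-sample line labels for matrix input.
#' @return genes x lines matrix.
#' @export
lineMeans <- function(se, lines = NULL) {
    if (is(se, "SummarizedExperiment")) {
        lines <- colData(se)$line
        an <- SummarizedExperiment::assayNames(se)
        m <- if ("fpkm" %in% an) assay(se, "fpkm")
             else assay(countsToFPKM(se), "fpkm")
    } else m <- as.matrix(se)
    if (is.null(lines)) stop("line labels required")
    ul <- unique(lines)
    out <- vapply(ul, function(l)
        rowMeans(m[, lines == l, drop = FALSE]), numeric(nrow(m)))
    colnames(out) <- ul
    out
}

#' Full coexpression-module analysis
#'
#' The minimal weighted-coexpression chain: soft-threshold adjacency
#' (|r|^beta), topological overlap, average-linkage clustering with a
#' fixed-height cut, a merge step joining modules whose eigengenes
#' correlate above \code{mergeCor}, eigengene computation, and
#' module-trait correlation.
#'
#' Two input modes mirror common practice: raw per-sample expression with
#' a per-sample trait, or the [mpvTransform()] matrix over hybrids with
#' the trait's MPV per hybrid.
#'
#' @param expr genes x samples matrix (already in the chosen mode).
#' @param trait per-sample trait vector (same order as columns), or NULL
#'   to skip the trait step.
#' @param beta,minModuleSize,cutHeight see [adjacencyMatrix()] /
#'   [detectModules()].
#' @param mergeCor eigengene-correlation threshold above which modules
#'   are merged (default 0.8).
#' @param alpha module-trait significance level.
#' @return a [ModuleResult-class].
#' @export
runCoexpressionModules <- function(expr, trait = NULL, beta = 11,
                                   minModuleSize = 50, cutHeight = 0.98,
                                   mergeCor = 0.8, alpha = 0.05) {
    expr <- as.matrix(expr)
    if (is.null(rownames(expr)))
        rownames(expr) <- paste0("g", seq_len(nrow(expr)))
    sds <- apply(expr, 1, sd)
    if (any(sds == 0)) {
        warning(sum(sds == 0), " zero-variance genes excluded from the network")
    }
    keep <- rownames(expr)[sds > 0]
    a <- suppressWarnings(adjacencyMatrix(expr[keep, , drop = FALSE], beta))
    labels <- detectModules(tomSimilarity(a), minModuleSize, cutHeight)

    # merge modules with near-identical eigengenes
    repeat {
        mods <- setdiff(unique(labels), "unassigned")
        if (length(mods) < 2L) break
        eg <- t(vapply(mods, function(m)
            moduleEigengene(expr, names(labels)[labels == m])$eigengene,
            numeric(ncol(expr))))
        cc <- cor(t(eg))
        diag(cc) <- 0
        if (max(cc) <= mergeCor) break
        idx <- which(cc == max(cc), arr.ind = TRUE)[1, ]
        labels[labels == mods[idx[2]]] <- mods[idx[1]]
    }
    mods <- setdiff(unique(labels), "unassigned")
    if (length(mods)) {
        sizes <- table(factor(labels[labels != "unassigned"], levels = mods))
        ord <- names(sort(sizes, decreasing = TRUE))
        relab <- setNames(paste0("M", seq_along(ord)), ord)
        labels[labels != "unassigned"] <- relab[labels[labels != "unassigned"]]
        mods <- unname(relab)
    }

    full <- setNames(rep("unassigned", nrow(expr)), rownames(expr))
    full[names(labels)] <- labels

    if (length(mods)) {
        egl <- lapply(mods, function(m)
            moduleEigengene(expr, names(full)[full == m]))
        eg <- do.call(rbind, lapply(egl, `[[`, "eigengene"))
        rownames(eg) <- mods
        ve <- setNames(vapply(egl, `[[`, numeric(1), "varianceExplained"),
                       mods)
    } else {
        eg <- matrix(numeric(), 0, ncol(expr))
        ve <- numeric()
    }

    mt <- if (!is.null(trait) && length(mods))
        moduleTraitCor(eg, trait, alpha) else data.frame()
    new("ModuleResult", labels = full, eigengenes = eg,
        varianceExplained = ve, moduleTrait = mt,
        beta = beta, minModuleSize = as.integer(minModuleSize))
}
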