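#' @importFrom utils read.table write.table
NULL

#' Write / read a genes x samples expression matrix as TSV
#'
#' First column \code{gene}, then one header-named column per sample.
#'
#' @param mat numeric matrix with gene rownames.
#' @param path file path.
#' @return \code{readExpressionTSV} returns the numeric matrix.
#' @export
writeExpressionTSV <- function(mat, path) {
    df <- data.frame(gene = rownames(mat), as.data.frame(mat),
                     check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeExpressionTSV
#' @export
readExpressionTSV <- function(path) {
    df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
}

#' Read / write the tabular pipeline inputs
#'
#' Plain TSVs with headers: sample sheet (\code{sample, line, role,
#' replicate}), trio design (\code{hybrid, female, male}) and trait table
#' (\code{line, trait}).
#'
#' @param df data.frame to write.
#' @param path file path.
#' @return readers return the data.frame.
#' @export
writeTableTSV <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeTableTSV
#' @export
readSampleSheet <- function(path) {
    df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
    need <- c("sample", "line", "role")
    if (!all(need %in% names(df)))
        stop("sample sheet needs columns: ", paste(need, collapse = ", "))
    roles <- c("female-parent", "male-parent", "hybrid")
    if (!all(df$role %in% roles))
        stop("role must be one of: ", paste(roles, collapse = ", "))
    df
}

#' @rdname writeTableTSV
#' @export
readTrioDesign <- function(path) {
    df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
    if (!all(c("hybrid", "female", "male") %in% names(df)))
        stop("trio design needs columns hybrid, female, male")
    df
}

#' @rdname writeTableTSV
#' @export
readTraitTable <- function(path) {
    df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
    if (!all(c("line", "trait") %in% names(df)))
        stop("trait table needs columns line, trait")
    df
}

#' Assemble a trio experiment from matrices and tables
#'
#' @param mat genes x samples matrix (columns must match the sample
#'   sheet's \code{sample} column).
#' @param sampleSheet data.frame(sample, line, role, replicate).
#' @param design data.frame(hybrid, female, male).
#' @param layer "counts" or "fpkm" — which assay the matrix is.
#' @param geneLengths optional per-gene lengths (bp), required to derive
#'   FPKM from counts.
#' @return a SummarizedExperiment with the design in its metadata.
#' @export
makeTrioExperiment <- function(mat, sampleSheet, design,
                               layer = c("counts", "fpkm"),
                               geneLengths = NULL) {
    layer <- match.arg(layer)
    if (!identical(colnames(mat), sampleSheet$sample))
        stop("matrix columns must match sample sheet order")
    rd <- if (is.null(geneLengths)) NULL
          else S4Vectors::DataFrame(length = geneLengths,
                                    row.names = rownames(mat))
    assays <- setNames(list(mat), layer)
    SummarizedExperiment(
        assays = assays,
        colData = S4Vectors::DataFrame(sampleSheet,
                                       row.names = sampleSheet$sample),
        rowData = rd,
        metadata = list(trioDesign = design))
}
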