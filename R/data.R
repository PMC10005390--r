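#' Bundled Chinese cabbage diallel summary tables
#'
#' Printed summary tables from a 4 x 4 diallel Chinese cabbage heterosis
#' trial (4 female x 4 male inbred lines, 16 F1 hybrids, leaf
#' transcriptomes in 3 biological replicates, plant gross weight as the
#' trait), shipped as worked-example inputs:
#'
#' \describe{
#'   \item{diallelPatternCounts()}{16 hybrids x 12 expression-pattern gene
#'     counts (columns P1..P12, rownames the hybrid codes).}
#'   \item{diallelHeterosisMPV()}{per-hybrid mid-parent heterosis value of
#'     plant gross weight and the published strong/middle/weak group
#'     label.}
#'   \item{diallelDEGCounts()}{per-hybrid DEG counts for the three trio
#'     comparisons plus the published DEG-ratio statistic.}
#' }
#'
#' @return \code{diallelPatternCounts}: integer matrix;
#'   \code{diallelHeterosisMPV} and \code{diallelDEGCounts}: data.frames.
#' @examples
#' categoryPercentages(diallelPatternCounts()["DE", ])
#' @name diallelData
NULL

extdata <- function(f)
    system.file("extdata", f, package = "heterosisTx", mustWork = TRUE)

#' @rdname diallelData
#' @export
diallelPatternCounts <- function() {
    df <- utils::read.table(extdata("diallel_pattern_counts.tsv"),
                            sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1])
    rownames(m) <- df$hybrid
    m
}

#' @rdname diallelData
#' @export
diallelHeterosisMPV <- function() {
    utils::read.table(extdata("diallel_heterosis_mpv.tsv"), sep = "\t",
                      header = TRUE, stringsAsFactors = FALSE)
}

#' @rdname diallelData
#' @export
diallelDEGCounts <- function() {
    utils::read.table(extdata("diallel_deg_counts.tsv"), sep = "\t",
                      header = TRUE, stringsAsFactors = FALSE)
}
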