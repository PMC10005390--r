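#' @importFrom jsonlite write_json
NULL

#' Run the full heterosis transcriptome pipeline
#'
#' End-to-end orchestration: (simulate or accept) trio counts, FPKM
#' normalisation, replicate-correlation QC, the three pairwise DE tests
#' per hybrid, twelve-pattern classification with per-hybrid and
#' cross-hybrid summaries, mid-parent heterosis grouping, group-common
#' DEG intersection, optional term enrichment of the group-common sets,
#' and coexpression-module detection with module-trait correlation.
#' Every output is a headered TSV under \code{outDir}, plus a JSON
#' manifest recording the package version, seed and thresholds so a run
#' can be reproduced from the manifest alone.
#'
#' @param outDir output directory (created if needed).
#' @param se a trio SummarizedExperiment ([simulateTrioCounts()] /
#'   [makeTrioExperiment()]); NULL simulates from \code{config}.
#' @param config [SimulationConfig-class] used when \code{se} is NULL.
#' @param traits data.frame(line, trait); defaults to the simulation's
#'   planted traits.
#' @param annotation optional term -> genes list for enrichment of the
#'   group-common DEG sets.
#' @param fdr DEG threshold (adjusted p).
#' @param deMethod "welch" or "nb".
#' @param strongCut,weakCut heterosis group thresholds (MPV percent).
#' @param alpha significance level for enrichment and module-trait tests.
#' @param beta,minModuleSize,cutHeight coexpression network settings.
#' @param moduleMode "mpv" correlates modules of the expression-MPV
#'   matrix with the trait's MPV across hybrids; "raw" uses per-sample
#'   expression and a per-sample trait.
#' @return invisibly, a list with every stage's in-memory result.
#' @export
runPipeline <- function(outDir, se = NULL, config = simulationConfig(),
                        traits = NULL, annotation = NULL,
                        fdr = 0.05, deMethod = "welch",
                        strongCut = 140, weakCut = 40, alpha = 0.05,
                        beta = 11, minModuleSize = 50, cutHeight = 0.98,
                        moduleMode = c("mpv", "raw")) {
    moduleMode <- match.arg(moduleMode)
    if (strongCut <= weakCut) stop("strongCut must exceed weakCut")
    if (fdr <= 0 || fdr >= 1) stop("fdr must be in (0, 1)")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(outDir, f)

    if (is.null(se)) se <- simulateTrioCounts(config)
    design <- S4Vectors::metadata(se)$trioDesign
    if (is.null(design)) stop("the experiment has no trio design")
    if (is.null(traits)) traits <- S4Vectors::metadata(se)$traits
    se <- countsToFPKM(se)
    writeExpressionTSV(assay(se, "counts"), out("counts.tsv"))
    writeExpressionTSV(assay(se, "fpkm"), out("fpkm.tsv"))
    writeTableTSV(as.data.frame(colData(se)), out("samples.tsv"))
    writeTableTSV(design, out("design.tsv"))

    qc <- replicateCorrelation(se)
    writeTableTSV(qc$perMaterial, out("replicate_qc.tsv"))

    trioDE <- runTrioDE(se, design, fdr = fdr, method = deMethod)
    summary1 <- deSummary(trioDE)
    writeTableTSV(summary1, out("de_summary.tsv"))

    patterns <- lapply(names(trioDE), function(h)
        cbind(hybrid = h, classifyTrio(trioDE[[h]], h)))
    patternsAll <- do.call(rbind, patterns)
    writeTableTSV(patternsAll, out("patterns.tsv"))

    countsTab <- t(vapply(patterns, function(p)
        summarizePatterns(p)$counts[paste0("P", 1:12)], integer(12)))
    rownames(countsTab) <- names(trioDE)
    pctTab <- t(apply(countsTab, 1, categoryPercentages))
    summaryRows <- if (nrow(countsTab) >= 2L)
        aggregateAcrossHybrids(countsTab) else NULL
    writeTableTSV(data.frame(hybrid = rownames(countsTab), countsTab),
                  out("pattern_counts.tsv"))
    writeTableTSV(data.frame(hybrid = rownames(pctTab), pctTab,
                             check.names = FALSE),
                  out("category_percentages.tsv"))
    if (!is.null(summaryRows))
        writeTableTSV(summaryRows, out("pattern_summary.tsv"))

    het <- NULL
    groupCommon <- list()
    if (!is.null(traits)) {
        het <- heterosisTable(traits, design, strongCut, weakCut)
        writeTableTSV(het, out("heterosis.tsv"))
        sets <- selectDegSets(degSets(trioDE), "union")
        for (g in c("strong", "weak")) {
            hyb <- het$hybrid[het$group == g]
            if (length(hyb) == 0L) next
            cd <- commonDEGs(sets[hyb])
            groupCommon[[g]] <- cd
            writeTableTSV(data.frame(gene = cd$common),
                          out(paste0("common_degs_", g, ".tsv")))
            writeTableTSV(cd$venn, out(paste0("venn_", g, ".tsv")))
            if (!is.null(annotation) && length(cd$common)) {
                enr <- hypergeometricEnrichment(
                    cd$common, annotation,
                    universe = rownames(se), alpha = alpha)
                writeTableTSV(enr, out(paste0("enrichment_", g, ".tsv")))
                groupCommon[[paste0(g, "Enrichment")]] <- enr
            }
        }
    }

    lm <- lineMeans(se)
    if (moduleMode == "mpv") {
        mexpr <- mpvTransform(lm, design)
        mtrait <- if (!is.null(het)) setNames(het$MPV, het$hybrid)[colnames(mexpr)]
                  else NULL
    } else {
        an <- SummarizedExperiment::assayNames(se)
        mexpr <- log2(assay(se, "fpkm") + 1)
        mtrait <- if (!is.null(traits))
            setNames(traits$trait, traits$line)[colData(se)$line] else NULL
    }
    modules <- runCoexpressionModules(mexpr, mtrait, beta = beta,
                                      minModuleSize = minModuleSize,
                                      cutHeight = cutHeight, alpha = alpha)
    writeTableTSV(data.frame(gene = names(moduleLabels(modules)),
                             module = unname(moduleLabels(modules))),
                  out("modules.tsv"))
    if (nrow(eigengenes(modules)))
        writeExpressionTSV(eigengenes(modules), out("eigengenes.tsv"))
    if (nrow(moduleTrait(modules)))
        writeTableTSV(moduleTrait(modules), out("module_trait.tsv"))

    cfg <- S4Vectors::metadata(se)$config
    manifest <- list(
        package = "heterosisTx",
        version = as.character(utils::packageVersion("heterosisTx")),
        seed = if (!is.null(cfg)) cfg@seed else NA,
        thresholds = list(fdr = fdr, strongCut = strongCut,
                          weakCut = weakCut, alpha = alpha),
        network = list(beta = beta, minModuleSize = minModuleSize,
                       cutHeight = cutHeight, mode = moduleMode),
        deMethod = deMethod,
        files = list.files(outDir))
    write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
               pretty = TRUE)

    invisible(list(se = se, qc = qc, trioDE = trioDE, deSummary = summary1,
                   patterns = patternsAll, patternCounts = countsTab,
                   categoryPct = pctTab, patternSummary = summaryRows,
                   heterosis = het, groupCommon = groupCommon,
                   modules = modules, manifest = manifest))
}
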