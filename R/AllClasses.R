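#' @import methods
#' @importFrom S4Vectors DataFrame metadata
NULL

PATTERN_LEVELS <- c(paste0("P", 1:12), "unclassified")

PATTERN_CATEGORY <- c(
    P1 = "additive", P2 = "additive",
    P3 = "dominant", P4 = "dominant", P5 = "dominant", P6 = "dominant",
    P7 = "over-dominant", P8 = "over-dominant", P9 = "over-dominant",
    P10 = "over-dominant", P11 = "over-dominant", P12 = "over-dominant",
    unclassified = "none"
)

#' Simulation configuration for synthetic hybrid-parent trio data
#'
#' Holds every knob of the negative-binomial trio simulator: the diallel
#' layout (female x male inbred lines, each hybrid forming a trio with its
#' two parents), per-gene noise, planted effect sizes, the mixture of
#' planted expression patterns, and the coexpression/trait settings.
#'
#' The defaults emulate the design of a 4 x 4 diallel Chinese cabbage
#' heterosis trial: 4 female lines, 4 male lines, 16 hybrids, 3 biological
#' replicates per material (72 libraries), negative-binomial counts with
#' variance mu + dispersion * mu^2, library sizes log-uniform between 5 and
#' 15 million reads, and gene lengths uniform between 500 and 5000 bp.
#'
#' @slot nGenes number of genes to simulate.
#' @slot nFemale,nMale numbers of female and male inbred lines; every
#'   female x male pair is a hybrid, so there are \code{nFemale * nMale}
#'   trios.
#' @slot replicates biological replicates per material (>= 2).
#' @slot dispersion negative-binomial dispersion alpha
#'   (variance = mu + alpha * mu^2); a single value, or a positive vector
#'   recycled over genes, or gene-wise values drawn once when
#'   \code{dispersionShape > 0}.
#' @slot dispersionShape if positive, per-gene dispersions are drawn from a
#'   gamma with this shape and mean \code{dispersion}; 0 means constant.
#' @slot baselineMean expected count of an unperturbed gene at the
#'   reference library size.
#' @slot parentLog2FC,hybridLog2FC planted log2 effect sizes used for the
#'   parent-parent split and for pushing the hybrid outside the parental
#'   range in over-dominant patterns.
#' @slot patternMix named proportions over \code{P1..P12} and \code{null};
#'   must sum to 1.
#' @slot libSizeRange sampling range (reads) for per-library sequencing
#'   depth, drawn log-uniformly.
#' @slot geneLengthRange sampling range (bp) for gene lengths.
#' @slot moduleSpec data.frame with columns \code{size}, \code{loading},
#'   \code{noiseSD} describing planted coexpression modules.
#' @slot traitModuleR target correlation between the simulated trait and
#'   the first module's latent factor.
#' @slot nSamples sample count for the standalone coexpression simulator.
#' @slot seed integer seed; identical configs reproduce identical data.
#' @export
setClass("SimulationConfig",
    representation(
        nGenes = "integer",
        nFemale = "integer",
        nMale = "integer",
        replicates = "integer",
        dispersion = "numeric",
        dispersionShape = "numeric",
        baselineMean = "numeric",
        parentLog2FC = "numeric",
        hybridLog2FC = "numeric",
        patternMix = "numeric",
        libSizeRange = "numeric",
        geneLengthRange = "numeric",
        moduleSpec = "data.frame",
        traitModuleR = "numeric",
        nSamples = "integer",
        seed = "integer"
    )
)

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (object@nGenes < 1L) msg <- c(msg, "nGenes must be positive")
    if (object@nFemale < 1L || object@nMale < 1L)
        msg <- c(msg, "line counts must be positive")
    if (object@replicates < 2L)
        msg <- c(msg, "replicates must be >= 2")
    if (any(object@dispersion < 0))
        msg <- c(msg, "dispersion must be nonnegative")
    if (object@baselineMean <= 0)
        msg <- c(msg, "baselineMean must be positive")
    pm <- object@patternMix
    allowed <- c(paste0("P", 1:12), "null")
    if (!all(names(pm) %in% allowed))
        msg <- c(msg, "patternMix names must be P1..P12 or null")
    if (any(pm < 0) || abs(sum(pm) - 1) > 1e-8)
        msg <- c(msg, "patternMix proportions must be nonnegative and sum to 1")
    if (length(object@libSizeRange) != 2L || any(object@libSizeRange <= 0))
        msg <- c(msg, "libSizeRange must be two positive values")
    if (length(object@geneLengthRange) != 2L || any(object@geneLengthRange <= 0))
        msg <- c(msg, "geneLengthRange must be two positive values")
    if (nrow(object@moduleSpec) > 0) {
        need <- c("size", "loading", "noiseSD")
        if (!all(need %in% names(object@moduleSpec)))
            msg <- c(msg, "moduleSpec needs columns size, loading, noiseSD")
        else if (sum(object@moduleSpec$size) > object@nGenes)
            msg <- c(msg, "module sizes exceed nGenes")
    }
    if (abs(object@traitModuleR) > 1)
        msg <- c(msg, "traitModuleR must be in [-1, 1]")
    if (object@nSamples < 3L) msg <- c(msg, "nSamples must be >= 3")
    if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' @param nGenes number of genes.
#' @param nFemale,nMale numbers of female / male parental lines (the trio
#'   design crosses every pair).
#' @param replicates biological replicates per material.
#' @param dispersion NB dispersion alpha (variance = mu + alpha mu^2).
#' @param dispersionShape gamma shape for gene-wise dispersion draws
#'   (0 = constant dispersion).
#' @param baselineMean expected count for a null gene.
#' @param parentLog2FC,hybridLog2FC planted log2 fold changes.
#' @param patternMix named numeric proportions over P1..P12 and "null".
#' @param libSizeRange log-uniform sampling range for library sizes (reads).
#' @param geneLengthRange uniform sampling range for gene lengths (bp).
#' @param moduleSpec data.frame(size, loading, noiseSD) of planted modules.
#' @param traitModuleR target trait correlation with module 1's factor.
#' @param nSamples samples for [simulateCoexpression()].
#' @param seed integer seed.
#' @return a validated [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(nGenes = 500, seed = 1)
#' cfg
#' @export
simulationConfig <- function(nGenes = 2000L,
                             nFemale = 4L, nMale = 4L,
                             replicates = 3L,
                             dispersion = 0.05,
                             dispersionShape = 0,
                             baselineMean = 200,
                             parentLog2FC = 2,
                             hybridLog2FC = 2,
                             patternMix = c(null = 1),
                             libSizeRange = c(5e6, 15e6),
                             geneLengthRange = c(500, 5000),
                             moduleSpec = data.frame(),
                             traitModuleR = 0.8,
                             nSamples = 24L,
                             seed = 1L) {
    pm <- patternMix / 1  # force plain numeric
    new("SimulationConfig",
        nGenes = as.integer(nGenes),
        nFemale = as.integer(nFemale), nMale = as.integer(nMale),
        replicates = as.integer(replicates),
        dispersion = dispersion,
        dispersionShape = dispersionShape,
        baselineMean = baselineMean,
        parentLog2FC = parentLog2FC,
        hybridLog2FC = hybridLog2FC,
        patternMix = pm,
        libSizeRange = as.numeric(libSizeRange),
        geneLengthRange = as.numeric(geneLengthRange),
        moduleSpec = moduleSpec,
        traitModuleR = traitModuleR,
        nSamples = as.integer(nSamples),
        seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig\n")
    cat("  genes:", object@nGenes,
        " lines:", object@nFemale, "female x", object@nMale, "male",
        " replicates:", object@replicates, "\n")
    cat("  baseline mean:", object@baselineMean,
        " dispersion:", paste(signif(unique(object@dispersion), 3),
                              collapse = ","), "\n")
    cat("  planted log2FC parent/hybrid:", object@parentLog2FC, "/",
        object@hybridLog2FC, "\n")
    mix <- object@patternMix[object@patternMix > 0]
    cat("  pattern mix:",
        paste(names(mix), signif(mix, 3), sep = "=", collapse = " "), "\n")
    cat("  seed:", object@seed, "\n")
})

#' Per-gene trio calls for one hybrid
#'
#' The evidence the pattern classifier consumes for a single hybrid-parent
#' trio: group mean FPKM of the female parent (F), male parent (M) and
#' hybrid (H), and for each of the three pairwise comparisons
#' (female-vs-male FM, female-vs-hybrid FH, male-vs-hybrid MH) a
#' significance flag plus the sign of the mean difference.
#'
#' Directions are stored as +1/-1 and only interpreted for significant
#' comparisons: \code{dirFM = sign(F - M)}, \code{dirFH = sign(H - F)},
#' \code{dirMH = sign(H - M)}.
#'
#' @slot hybrid hybrid identifier.
#' @slot geneIds character vector of gene ids.
#' @slot meanF,meanM,meanH group mean FPKM per gene (nonnegative).
#' @slot sigFM,sigFH,sigMH logical significance of each comparison.
#' @slot dirFM,dirFH,dirMH integer signs of the mean differences.
#' @export
setClass("TrioCallSet",
    representation(
        hybrid = "character",
        geneIds = "character",
        meanF = "numeric", meanM = "numeric", meanH = "numeric",
        sigFM = "logical", sigFH = "logical", sigMH = "logical",
        dirFM = "integer", dirFH = "integer", dirMH = "integer"
    )
)

setValidity("TrioCallSet", function(object) {
    n <- length(object@geneIds)
    lens <- c(length(object@meanF), length(object@meanM),
              length(object@meanH), length(object@sigFM),
              length(object@sigFH), length(object@sigMH),
              length(object@dirFM), length(object@dirFH),
              length(object@dirMH))
    msg <- character()
    if (!all(lens == n)) msg <- c(msg, "all per-gene slots must match geneIds length")
    if (anyDuplicated(object@geneIds)) msg <- c(msg, "duplicated gene ids")
    if (any(object@meanF < 0, object@meanM < 0, object@meanH < 0))
        msg <- c(msg, "mean FPKMs must be nonnegative")
    if (!all(object@dirFM %in% c(-1L, 0L, 1L)) ||
        !all(object@dirFH %in% c(-1L, 0L, 1L)) ||
        !all(object@dirMH %in% c(-1L, 0L, 1L)))
        msg <- c(msg, "directions must be -1, 0 or 1")
    if (length(msg)) msg else TRUE
})

setMethod("show", "TrioCallSet", function(object) {
    cat("TrioCallSet for hybrid", object@hybrid, "\n")
    cat(" ", length(object@geneIds), "genes;",
        sum(object@sigFM), "FM,", sum(object@sigFH), "FH,",
        sum(object@sigMH), "MH significant calls\n")
})

#' @describeIn TrioCallSet-class number of genes
#' @param x a \code{TrioCallSet}
#' @export
setMethod("length", "TrioCallSet", function(x) length(x@geneIds))

#' Coexpression module detection result
#'
#' @slot labels named character vector, gene -> module label; "unassigned"
#'   marks genes in clusters below the minimum module size.
#' @slot eigengenes modules x samples matrix of unit-norm eigengenes.
#' @slot varianceExplained per-module fraction of module variance carried
#'   by the eigengene.
#' @slot moduleTrait data.frame of per-module trait correlation (r, p,
#'   significant), empty until [moduleTraitCor()] is run.
#' @slot beta soft-threshold power used.
#' @slot minModuleSize minimum module size used.
#' @export
setClass("ModuleResult",
    representation(
        labels = "character",
        eigengenes = "matrix",
        varianceExplained = "numeric",
        moduleTrait = "data.frame",
        beta = "numeric",
        minModuleSize = "integer"
    )
)

setValidity("ModuleResult", function(object) {
    msg <- character()
    mods <- setdiff(unique(object@labels), "unassigned")
    if (length(mods) && nrow(object@eigengenes) > 0) {
        if (!all(rownames(object@eigengenes) %in% mods))
            msg <- c(msg, "eigengene rows must be module labels")
        sizes <- table(object@labels[object@labels != "unassigned"])
        if (length(sizes) && any(sizes < object@minModuleSize))
            msg <- c(msg, "assigned module below minModuleSize")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "ModuleResult", function(object) {
    mods <- setdiff(unique(object@labels), "unassigned")
    cat("ModuleResult:", length(object@labels), "genes,",
        length(mods), "modules (beta =", object@beta,
        ", min size =", object@minModuleSize, ")\n")
    if (length(mods)) {
        sizes <- sort(table(object@labels[object@labels != "unassigned"]),
                      decreasing = TRUE)
        cat("  sizes:", paste(names(sizes), sizes, sep = "=",
                              collapse = " "), "\n")
    }
    cat("  unassigned:", sum(object@labels == "unassigned"), "\n")
    if (nrow(object@moduleTrait))
        cat("  trait-correlated modules (p <",
            attr(object@moduleTrait, "alpha") %||% 0.05, "):",
            sum(object@moduleTrait$significant), "\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn ModuleResult-class gene -> module label vector
#' @param object a \code{ModuleResult}
#' @export
setGeneric("moduleLabels", function(object) standardGeneric("moduleLabels"))

#' @rdname ModuleResult-class
#' @export
setMethod("moduleLabels", "ModuleResult", function(object) object@labels)

#' @describeIn ModuleResult-class modules x samples eigengene matrix
#' @export
setGeneric("eigengenes", function(object) standardGeneric("eigengenes"))

#' @rdname ModuleResult-class
#' @export
setMethod("eigengenes", "ModuleResult", function(object) object@eigengenes)

#' @describeIn ModuleResult-class module-trait correlation table
#' @export
setGeneric("moduleTrait", function(object) standardGeneric("moduleTrait"))

#' @rdname ModuleResult-class
#' @export
setMethod("moduleTrait", "ModuleResult", function(object) object@moduleTrait)
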