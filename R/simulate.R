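#' @importFrom stats rnbinom rnorm runif rgamma setNames
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
NULL

# Evaluate expr with a private RNG stream; the caller's .Random.seed is
# untouched.
withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

# Planted group-mean FPKM-scale expression (F, M, H) for one pattern.
# "=" relations are exact equalities; "<" uses the configured log2 effects.
# In-between hybrids (P1/P2) sit at the geometric midpoint of the parents.
patternMeans <- function(pattern, base, parentFC, hybridFC) {
    hi <- base * 2^parentFC
    mid <- base * 2^(parentFC / 2)
    up <- function(x) x * 2^hybridFC
    dn <- function(x) x / 2^hybridFC
    switch(pattern,
        P1  = c(F = hi,   M = base, H = mid),
        P2  = c(F = base, M = hi,   H = mid),
        P3  = c(F = base, M = hi,   H = hi),
        P4  = c(F = hi,   M = base, H = base),
        P5  = c(F = hi,   M = base, H = hi),
        P6  = c(F = base, M = hi,   H = base),
        P7  = c(F = base, M = base, H = dn(base)),
        P8  = c(F = hi,   M = base, H = dn(base)),
        P9  = c(F = base, M = hi,   H = dn(base)),
        P10 = c(F = base, M = base, H = up(base)),
        P11 = c(F = hi,   M = base, H = up(hi)),
        P12 = c(F = base, M = hi,   H = up(hi)),
        null = c(F = base, M = base, H = base))
}

# Which of the three comparisons a planted pattern makes truly differential.
patternTruthDEG <- function(pattern) {
    rel <- patternMeans(pattern, 1, 1, 1)
    c(FM = rel[["F"]] != rel[["M"]],
      FH = rel[["H"]] != rel[["F"]],
      MH = rel[["H"]] != rel[["M"]])
}

#' Simulate negative-binomial counts for a diallel of hybrid-parent trios
#'
#' Generates a seeded count matrix for every parental line and hybrid of a
#' female x male diallel, with genes planted into the twelve trio expression
#' patterns (or left null) according to \code{patternMix}. Counts are
#' negative binomial with variance \code{mu + dispersion * mu^2}; expected
#' counts scale with a per-library depth drawn log-uniformly, so FPKM
#' normalisation recovers the planted group means. A per-line trait
#' ("plant gross weight") is planted with hybrid mid-parent heterosis
#' values spanning the weak-to-strong range.
#'
#' The same configuration (including seed) always reproduces the identical
#' output.
#'
#' @param config a [SimulationConfig-class].
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   \code{counts} (genes x samples), \code{colData} columns
#'   \code{sample, line, role, replicate}, \code{rowData} column
#'   \code{length}, and \code{metadata()} entries:
#'   \describe{
#'     \item{trioDesign}{data.frame(hybrid, female, male), one row per trio}
#'     \item{truth}{data.frame(gene, pattern, degFM, degFH, degMH) of
#'       planted labels and truly differential comparisons}
#'     \item{traits}{data.frame(line, role, trait) of planted trait values,
#'       plus the planted per-hybrid MPV in \code{plantedMPV}}
#'     \item{libSizes}{named per-sample sequencing depths}
#'     \item{config}{the configuration used}
#'   }
#' @examples
#' cfg <- simulationConfig(nGenes = 100, patternMix = c(P4 = 0.2, null = 0.8),
#'                         seed = 7)
#' se <- simulateTrioCounts(cfg)
#' se
#' table(S4Vectors::metadata(se)$truth$pattern)
#' @export
simulateTrioCounts <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    withSeed(config@seed, {
        females <- paste0("F", seq_len(config@nFemale))
        males <- paste0("M", seq_len(config@nMale))
        design <- expand.grid(female = females, male = males,
                              KEEP.OUT.ATTRS = FALSE,
                              stringsAsFactors = FALSE)
        design <- design[order(design$female, design$male), , drop = FALSE]
        design$hybrid <- paste0(design$female, "x", design$male)
        design <- design[, c("hybrid", "female", "male")]
        rownames(design) <- NULL

        materials <- data.frame(
            line = c(females, males, design$hybrid),
            role = rep(c("female-parent", "male-parent", "hybrid"),
                       c(length(females), length(males), nrow(design))),
            stringsAsFactors = FALSE)

        genes <- sprintf("gene%05d", seq_len(config@nGenes))
        mix <- config@patternMix
        patterns <- sample(names(mix), config@nGenes, replace = TRUE,
                           prob = mix)

        lens <- round(runif(config@nGenes, config@geneLengthRange[1],
                            config@geneLengthRange[2]))
        disp <- if (config@dispersionShape > 0) {
            rgamma(config@nGenes, shape = config@dispersionShape,
                   rate = config@dispersionShape / config@dispersion[1])
        } else rep_len(config@dispersion, config@nGenes)

        # genes x materials matrix of planted mean expression
        mu <- matrix(config@baselineMean, config@nGenes, nrow(materials),
                     dimnames = list(genes, materials$line))
        roleOf <- setNames(materials$role, materials$line)
        for (g in which(patterns != "null")) {
            pm <- patternMeans(patterns[g], config@baselineMean,
                               config@parentLog2FC, config@hybridLog2FC)
            mu[g, ] <- ifelse(roleOf == "female-parent", pm[["F"]],
                       ifelse(roleOf == "male-parent", pm[["M"]], pm[["H"]]))
        }

        samples <- data.frame(
            sample = paste(rep(materials$line, each = config@replicates),
                           seq_len(config@replicates), sep = "_r"),
            line = rep(materials$line, each = config@replicates),
            role = rep(materials$role, each = config@replicates),
            replicate = rep(seq_len(config@replicates), nrow(materials)),
            stringsAsFactors = FALSE)

        refLib <- mean(config@libSizeRange)
        libs <- exp(runif(nrow(samples), log(config@libSizeRange[1]),
                          log(config@libSizeRange[2])))
        names(libs) <- samples$sample

        counts <- matrix(0L, config@nGenes, nrow(samples),
                         dimnames = list(genes, samples$sample))
        for (j in seq_len(nrow(samples))) {
            m <- mu[, samples$line[j]] * (libs[j] / refLib)
            counts[, j] <- rnbinom(config@nGenes, mu = m, size = 1 / pmax(disp, 1e-8))
        }

        deg <- t(vapply(patterns, patternTruthDEG, logical(3)))
        truth <- data.frame(gene = genes, pattern = patterns,
                            degFM = deg[, "FM"], degFH = deg[, "FH"],
                            degMH = deg[, "MH"],
                            stringsAsFactors = FALSE)

        # planted trait: parental lines around 2 (arbitrary kg-scale unit),
        # hybrids set to hit a planted MPV spread evenly from weak to strong
        parentTrait <- runif(length(c(females, males)), 1.5, 2.5)
        names(parentTrait) <- c(females, males)
        # planted MPVs span weak (<40), middle and strong (>140) heterosis
        # in a 1:2:1 split, the usual shape of a diallel heterosis panel
        nh <- nrow(design)
        qs <- ceiling(nh / 4)
        plantedMPV <- c(seq(15, 32, length.out = qs),
                        seq(55, 130, length.out = nh - 2 * qs),
                        seq(150, 240, length.out = qs))[seq_len(nh)]
        mp <- (parentTrait[design$female] + parentTrait[design$male]) / 2
        hybridTrait <- mp * (1 + plantedMPV / 100)
        traits <- data.frame(
            line = c(names(parentTrait), design$hybrid),
            role = c(roleOf[names(parentTrait)], rep("hybrid", nrow(design))),
            trait = c(parentTrait, hybridTrait),
            plantedMPV = c(rep(NA_real_, length(parentTrait)), plantedMPV),
            stringsAsFactors = FALSE)
        rownames(traits) <- NULL

        SummarizedExperiment(
            assays = list(counts = counts),
            colData = S4Vectors::DataFrame(samples, row.names = samples$sample),
            rowData = S4Vectors::DataFrame(length = lens, row.names = genes),
            metadata = list(trioDesign = design, truth = truth,
                            traits = traits, libSizes = libs,
                            config = config))
    })
}

#' Convert counts to FPKM
#'
#' FPKM = counts * 1e9 / (gene length in bp * mapped reads in the library).
#' Zero counts map to zero FPKM.
#'
#' @param counts a genes x samples count matrix, or a
#'   \code{SummarizedExperiment} with a \code{counts} assay and a
#'   \code{length} rowData column.
#' @param geneLengths per-gene lengths in bp; taken from rowData when
#'   \code{counts} is a SummarizedExperiment.
#' @param librarySizes per-sample mapped-read totals; defaults to the
#'   column sums of the count matrix, except for a SummarizedExperiment
#'   that carries known sequencing depths in
#'   \code{metadata()$libSizes} (as the simulator's output does), which
#'   take precedence — column-sum totals are biased when expression
#'   composition differs strongly between materials.
#' @return same shape as the input: a numeric FPKM matrix, or the
#'   SummarizedExperiment with an added \code{fpkm} assay.
#' @examples
#' countsToFPKM(matrix(10, 1, 1), geneLengths = 1000, librarySizes = 1e6)
#' @export
countsToFPKM <- function(counts, geneLengths = NULL, librarySizes = NULL) {
    if (is(counts, "SummarizedExperiment")) {
        se <- counts
        m <- assay(se, "counts")
        if (is.null(geneLengths))
            geneLengths <- SummarizedExperiment::rowData(se)$length
        if (is.null(librarySizes))
            librarySizes <- S4Vectors::metadata(se)$libSizes
        fp <- countsToFPKM(m, geneLengths, librarySizes)
        SummarizedExperiment::assays(se)$fpkm <- fp
        return(se)
    }
    counts <- as.matrix(counts)
    if (is.null(geneLengths))
        stop("geneLengths required for matrix input")
    if (length(geneLengths) != nrow(counts))
        stop("geneLengths must match the number of genes")
    if (is.null(librarySizes)) librarySizes <- colSums(counts)
    if (length(librarySizes) != ncol(counts))
        stop("librarySizes must match the number of samples")
    if (any(geneLengths <= 0) || any(librarySizes <= 0))
        stop("gene lengths and library sizes must be positive")
    sweep(counts / geneLengths, 2, librarySizes, "/") * 1e9
}

#' Simulate coexpressed gene modules and a correlated trait
#'
#' Genes of each planted module share a standard-normal latent factor:
#' expression = loading * factor + N(0, noiseSD). Remaining genes are
#' independent noise. The simulated trait is built to correlate with the
#' FIRST module's latent factor at approximately \code{traitModuleR}.
#'
#' @param config a [SimulationConfig-class] with a non-empty
#'   \code{moduleSpec}; \code{nSamples} sets the sample count.
#' @return list with \code{expr} (genes x samples matrix), \code{trait}
#'   (per-sample numeric), \code{truth} (data.frame gene -> module;
#'   "background" for unplanted genes) and \code{factors} (modules x
#'   samples latent factors).
#' @examples
#' cfg <- simulationConfig(nGenes = 60, nSamples = 24,
#'     moduleSpec = data.frame(size = c(20, 20), loading = 1,
#'                             noiseSD = 0.2),
#'     traitModuleR = 0.8, seed = 3)
#' sim <- simulateCoexpression(cfg)
#' cor(sim$trait, sim$factors[1, ])
#' @export
simulateCoexpression <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    spec <- config@moduleSpec
    if (nrow(spec) == 0) stop("moduleSpec must be non-empty")
    withSeed(config@seed + 1L, {
        n <- config@nSamples
        genes <- sprintf("gene%05d", seq_len(config@nGenes))
        expr <- matrix(rnorm(config@nGenes * n), config@nGenes, n,
                       dimnames = list(genes,
                                       paste0("s", seq_len(n))))
        truth <- rep("background", config@nGenes)
        factors <- matrix(rnorm(nrow(spec) * n), nrow(spec), n,
                          dimnames = list(paste0("module", seq_len(nrow(spec))),
                                          colnames(expr)))
        at <- 0L
        for (m in seq_len(nrow(spec))) {
            idx <- at + seq_len(spec$size[m])
            at <- at + spec$size[m]
            noise <- matrix(rnorm(length(idx) * n, sd = spec$noiseSD[m]),
                            length(idx), n)
            expr[idx, ] <- spec$loading[m] * rep(factors[m, ], each = length(idx)) + noise
            truth[idx] <- rownames(factors)[m]
        }
        r <- config@traitModuleR
        z <- as.numeric(scale(factors[1, ]))
        trait <- r * z + sqrt(max(0, 1 - r^2)) * rnorm(n)
        list(expr = expr, trait = setNames(trait, colnames(expr)),
             truth = data.frame(gene = genes, module = truth,
                                stringsAsFactors = FALSE),
             factors = factors)
    })
}
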