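---
title: "Methods: trio expression patterns, heterosis grouping and coexpression modules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trio expression patterns, heterosis grouping and coexpression modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heterosisTx)
```

# The analysis model

`heterosisTx` analyses *trios*: an F1 hybrid H together with its female
parent F and male parent M, replicated, in a diallel of several parents.
The chain is

1. FPKM normalisation and replicate-correlation QC,
2. three pairwise differential-expression tests per trio (F–M, F–H, M–H),
3. classification of each trio DEG into twelve expression patterns,
4. mid-parent heterosis grouping of the hybrids by a measured trait,
5. intersection of DEG sets within a heterosis group, with term
   enrichment,
6. weighted coexpression modules correlated with the trait.

## Differential expression

Each comparison is a two-group test on replicate expression. The default
is a Welch two-sample t-test on log2(FPKM + 1). The log transform
stabilises the strong mean–variance relation of expression data; the
pseudo-expression ε = 1 keeps zeros finite and is also used in the
reported fold change log2((mean_B + ε)/(mean_A + ε)). Welch's form was
chosen over a count model as the default because it is closed-form,
assumption-light and exactly testable against hand calculations; a
negative-binomial Wald GLM (DESeq2) is available via `method = "nb"` for
raw counts. Genes with zero variance and equal means get p = 1; zero
variance with unequal means is treated as perfect separation (p = 0).
P-values are Benjamini–Hochberg adjusted per comparison, and a gene is a
DEG when its adjusted p is at most the `fdr` threshold. The default is
`fdr = 0.05`; it is a single knob everywhere because reasonable published
practice varies between 0.05 and 0.01 and the choice materially changes
DEG counts — the package takes no position beyond the default.

## The twelve patterns

A trio DEG's behaviour is summarised by a relational triple over the
three comparisons, in which "X = Y" means *that comparison is not
significant* and "X < Y" / "X > Y" means *significant, with the group
mean FPKMs in that order*:

* **P1, P2 (additive)** — parents differ and the hybrid sits strictly
  between them; all three comparisons significant.
* **P3–P6 (dominant)** — parents differ and the hybrid equals one parent
  (that parent–hybrid comparison not significant) while differing from
  the other.
* **P7–P12 (over-dominant)** — the hybrid is below or above *both*
  parents, with the parents either equal (P7, P10) or different.

The classifier (`classifyGene()`) operates on the full triple, including
the relation left implicit by the two-condition definitions of P3–P6
(e.g. P3's F < M with H = M implies H > F, which is enforced). This makes
the twelve patterns mutually exclusive: each of the 27 possible
(significance, direction) triples maps to exactly one of
{P1..P12, unclassified}. Triples that match no pattern — for example a
significant parental split with *both* parent–hybrid comparisons
non-significant (H cannot equal both of two unequal parents), or a hybrid
significantly outside the range on one side only — are reported as
`unclassified` rather than force-fit. The unit suite checks the
classifier against an independently coded truth-table oracle over all 27
triples.

The DEG universe classified per trio is the **union** of the three
comparisons' DEG sets. Classifying only parent–parent DEGs would make
P7 and P10 unreachable (they require a non-significant F–M), so the union
is the only self-consistent choice.

### Summaries

Per hybrid, genes are counted per pattern and the three category
percentages are reported over classified genes (they sum to 100 by
construction). Across hybrids, per-pattern summary rows use the
arithmetic mean rounded half-away-from-zero to an integer and a standard
error computed as the population standard deviation (n divisor) divided
by √n, printed to two decimals. These slightly unusual conventions are
exactly the ones under which the bundled diallel table's printed
"Average" and "Standard error" rows recompute from its sixteen count
rows, which the acceptance suite verifies for all twelve patterns.

## Mid-parent heterosis

For a trait value F1 and mid-parent mean MP = (F + M)/2,
MPV = 100 × (F1 − MP)/MP. Hybrids group as **strong** when MPV > 140,
**weak** when MPV < 40, **middle** otherwise. The thresholds are
exclusive — "higher than" / "lower than" — so the boundary values 140 and
40 fall in *middle*; both cuts are arguments. Within a group, common DEGs
are the intersection of one DEG set per hybrid; the default set is the
union of the two parent–hybrid comparisons (FH ∪ MH), since those are the
genes whose hybrid behaviour differs from a parent, but
`selectDegSets()` exposes `fh`, `mh` and `fm` alternatives because the
choice is not canonical.

## Enrichment

Over-representation of a study set (typically group-common DEGs) in flat
term annotations (GMT or two-column TSV) uses the one-sided
hypergeometric tail p = P(X ≥ k), BH-adjusted across terms, significant
at adjusted p < 0.05. The default universe is the set of genes tested for
differential expression, not the genome: enrichment should be judged
against what could have been called. No GO-graph propagation or
length-bias correction is attempted; annotations are taken as given.

## Coexpression modules

The network is unsigned: a_ij = |cor(x_i, x_j)|^β with β = 11 and
minimum module size 50 as defaults (the settings used with networks of
this kind at transcriptome scale; for the small simulated examples the
tests pass smaller minimum sizes). Topological overlap is the standard
unsigned TOM; modules come from average-linkage clustering of 1 − TOM cut
at a fixed height (default 0.98), followed by merging any modules whose
eigengenes correlate above 0.8. The fixed-height cut plus eigengene merge
is a deliberate simplification of dynamic tree cutting: it is
deterministic and easily testable, but it will split or absorb modules
differently from dynamic methods, so *module counts are not comparable*
across implementations and are not treated as reproducible quantities.

Module eigengenes are the first principal component across samples of the
gene-standardized module submatrix, unit-norm, with the sign oriented so
the mean correlation with member genes is positive — making eigengene
signs reproducible. Module–trait association is a Pearson correlation
with a two-sided t-test (df = n − 2), significant at p < 0.05. Two input
modes exist: per-sample expression against a per-sample trait, and the
mid-parent heterosis transform — per hybrid and gene,
100 × (FPKM_H − MP)/MP on line-mean FPKMs — against the trait's MPV, which
asks which modules track the *gain* of hybrids over their parental
expectation rather than expression itself. Genes with a zero mid-parent
mean are dropped with a warning (the transform is undefined there).

# The synthetic generator

`simulateTrioCounts()` emulates the diallel design: f female × m male
lines, every cross a hybrid, three replicates per material by default.
Counts are negative binomial with variance μ + αμ² — the standard RNA-seq
noise model — with dispersion α = 0.05 by default (typical for biological
replicates of inbred material), optionally gamma-distributed per gene.
Planted patterns fix the (F, M, H) mean triple: "=" relations are exact
mean equalities; "<" uses `parentLog2FC` (default 2) between parents and
`hybridLog2FC` (default 2, chosen equal to the parental effect so
over-dominant departures are as detectable as parental divergence) beyond
the parental range; additive hybrids sit at the parents' geometric
midpoint. Library sizes are drawn log-uniform over 5–15 million reads and
gene lengths uniform over 500–5000 bp; expected counts scale with depth,
so FPKM recovers the planted means. The planted trait gives the hybrids
mid-parent heterosis values spanning weak to strong in a 1:2:1 split,
mirroring a typical diallel panel. `simulateCoexpression()` plants
modules as shared latent factors plus independent noise and builds a
trait correlated with the first module's factor at a target r.

Because FPKM divides by a library total, using per-sample column sums as
that total is composition-biased whenever hybrids systematically
over-express planted genes; the simulator therefore records its true
sequencing depths and `countsToFPKM()` uses them when present. Real
datasets should supply mapped-read totals the same way.

What passing tests on this generator do **not** show: the simulator has
no batch effects, no length- or GC-dependent biases, no outlier samples,
no correlated genes outside planted modules, and patterns planted
consistently across all hybrids — real trios disagree across crosses.
Recovery rates measured on it are upper bounds for real data.

# Numerical and degenerate-input choices

* BH adjustment is the exact step-up (via `stats::p.adjust`), checked
  against a brute-force min-over-suffix oracle up to n = 1000.
* The hypergeometric tail uses `stats::phyper`, checked against
  combinatorial enumeration for all universe sizes ≤ 20; k = 0 gives the
  vacuous tail p = 1, and terms with no study overlap are still reported.
* `topTerms()` breaks adjusted-p ties lexicographically by term id so
  output is deterministic.
* Constant expression vectors: replicate correlation reports NA;
  adjacency and module detection exclude zero-variance genes with a
  warning; the heatmap export flags constant genes and emits zeros; an
  all-constant module raises an error (its eigengene is undefined).
* Module labels are ranked by size (M1 largest) and the dendrogram cut is
  deterministic, so reruns reproduce labels exactly.
* All simulation entry points take an integer seed and restore the
  caller's RNG state; identical configurations are bit-reproducible.

# Known limitations

* **Additive-pattern power.** P1/P2 require all three comparisons
  significant, with the hybrid only half the parental divergence away
  from each parent; at moderate effect sizes their recovery is
  intrinsically lower than the dominant/over-dominant patterns', which
  the frozen end-to-end regression test documents.
* **FDR and "=" relations.** Under BH at FDR q, genes whose true relation
  is an equality are falsely called significant at a rate of roughly
  q × (rejections/m) in that comparison, *independently of effect size*.
  Patterns containing an "=" (P3–P7, P10) therefore cannot reach exactly
  100% recovery however strong the planted signal; the property test
  asserts exact recovery only for the six all-inequality patterns.
* The Welch default tests log-FPKM, not counts; very low counts are
  better served by `method = "nb"`.
* Fixed-height tree cutting is not dynamic tree cut; module counts are
  implementation-specific.
* Enrichment treats annotations as flat sets; no DAG structure.
* The test-suite problem sizes (hundreds to a few thousand genes, 72
  samples) are chosen so the whole suite runs in minutes; they are ample
  for the statistical properties checked but are not a performance
  benchmark for transcriptome-scale networks, where >20k-gene TOMs
  require blockwise computation this package does not provide.
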