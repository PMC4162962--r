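# stagenet

Staged-embryo transcriptome analysis in R: consecutive-stage differential
expression, expression-pattern clustering, weighted gene co-expression
network modules, stage-specific module calling, hub genes, permutation
module-preservation Z statistics, and cross-species module overlap — with a
synthetic staged-transcriptome generator so the whole pipeline runs and is
testable with known ground truth.

## Who this is for

Developmental and reproductive biologists analyzing bulk RNA-seq time
courses over pre-implantation stages (oocyte, 2-cell, ..., blastocyst), and
method developers who want a compact, fully tested reference implementation
of the staged co-expression workflow on data with planted truth.

## The methods at the core

**Detection and differential expression.** A gene is detected at a stage
when its mean FPKM there is strictly above 0.1. For each pair of consecutive
stages, genes whose expression sum across the compared samples exceeds the
25th percentile of those sums are tested with a conditioned exact-style
negative-binomial test: with group count sums `K_A`, `K_B` and size factors
from median-of-ratios normalization, the test conditions on `T = K_A + K_B`,
models each group sum as NB with dispersion `max(gene-wise MoM estimate,
mean–dispersion trend)`, and sums the probabilities of all splits of `T` no
more likely than the observed one. Genes with `p < 0.05` are called
differentially expressed.

**Co-expression network.** Connection weights are
`a(i,j) = |corr(i,j)|^beta` (Pearson on `log2(FPKM+1)`; beta from the
scale-free topology criterion). The topological overlap matrix is

```
W(i,j) = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij),
l_ij = sum_d a_id a_dj,   k_i = sum_d a_id
```

and `D = 1 - W` is clustered with average linkage. Branches are cut
adaptively (merge-height profile, minimum module size 30), each module is
summarized by its eigengene (first principal component of the standardized
module expression), modules with eigengene correlation strictly above 0.7
are merged iteratively with recomputation, and membership is refined by kME
(the gene–eigengene correlation).

**Stage-specific modules, hubs, preservation, overlap.** A module is
stage-specific when its eigengene correlates positively (`p < 0.05`, t test
with `n - 2` df) with a stage's unit indicator vector. Hub genes have
`kME > 0.9` (strict); the top-200 connections of the top-150 hubs export as
a VisANT-compatible edge list. Module preservation between datasets is the
permutation Z statistic (`Zsummary`; strong if `Z >= 10`, weak-to-moderate
if `2 <= Z < 10`, none below 2) over ortholog-mapped genes, and
cross-species module overlap is tested with the one-sided
Fisher/hypergeometric enrichment test over the commonly expressed ortholog
background.

## Worked example

```r
library(stagenet)

sim <- simulate_dataset(sim_config(seed = 1))
sim$counts
#> expression_matrix [counts]: 2000 genes x 16 samples
sim$design
#> stage_design: 16 samples, 8 stages (oocyte < 2-cell < 4-cell < 8-cell <
#>   16-cell < early_morula < compact_morula < blastocyst)

net  <- expressed_subset(sim$fpkm, sim$design)
mods <- detect_modules(net)
mods
#> module_set: 15 modules, 945 genes assigned, 366 grey
#>   ME2: 122 genes (VE 0.46)
#>   ME4: 101 genes (VE 0.48)
#>   ME1: 82 genes (VE 0.58)
#>   ...

calls <- stage_specific_modules(mods, sim$design)
head(calls[!is.na(calls$stage), ], 5)
#>   module_id        stage         r            p
#> 1       ME2 early_morula 0.5974338 1.453181e-02
#> 2       ME4       8-cell 0.8438814 3.969503e-05
#> 3       ME1       2-cell 0.8636349 1.627018e-05
#> 5       ME5       oocyte 0.7930585 2.471884e-04
#> 6       ME3   blastocyst 0.8404841 4.571397e-05

truth   <- sim$truth$assignment
planted <- names(truth)[!is.na(truth)]
adjusted_rand_index(truth[planted], mods$labels[planted])
#> [1] 0.98

ht <- hub_genes(mods, net, names(mods$modules)[1])
sum(ht$is_hub)
#> [1] 6
```

The five planted stage-peaked modules are each recovered as a detected
module (adjusted Rand index 0.98 against the planted membership) and each is
called stage-specific for its true peak stage; the remaining detected
modules are small background clusters with weaker eigengenes. The full
walkthrough — simulation through differential expression, patterns, network,
preservation and cross-species overlap, with TSV outputs and a checksum
manifest — is one call:

```r
run_pipeline(pipeline_config(seed = 1), out_dir = "run1")
```

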