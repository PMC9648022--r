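---
title: "Methods: stage-wise expression meta-analysis and biomarker evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stage-wise expression meta-analysis and biomarker evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

cervstage re-implements, as a tested pipeline over synthetic data, a
sequential gene-expression analysis of cervical malignant transformation.
The disease is modeled as an ordinal progression Normal (0) → LSIL (1) →
HSIL (2) → SCC (3), using the two-tier squamous intraepithelial lesion
terminology (CIN1 → LSIL, CIN2/CIN3 → HSIL); CIN sub-grades are kept as an
auxiliary label for IHC stratification. This vignette documents the models,
the tunable parameters and their defaults, the numerical choices, and what
the synthetic data do and do not establish.

## Heterogeneity assessment

Samples are embedded by PCA of the 1000 most variable genes, computed on
gene-centered but *unscaled* log2 values — variance-based gene selection on
a common log2 scale is standard microarray practice, and scaling would
re-weight exactly the high-variance genes the selection favors. Variance
fractions come from the singular values. Intralesional heterogeneity is the
distribution of pairwise Pearson correlations between samples of the same
stage, computed over **all** genes by default (a configuration flag
restricts to the top-variable subset; which choice the original analysis
made is not documented, and on our generator the qualitative ordering is
unchanged). Stage distributions are compared by Kruskal–Wallis followed by
all pairwise two-sided Wilcoxon rank-sum tests with Bonferroni correction
(p × number of pairs, capped at 1). Wilcoxon p-values use exact enumeration
when both groups have ≤ 50 observations and no ties, and the tie-corrected
normal approximation otherwise.

## Differential expression and gene-set logic

Per dataset, each lesion stage is contrasted with normal by a per-gene
Welch two-sample t-test on log2 values. The test is deliberately a plain
unpooled-variance t rather than an empirical-Bayes moderated statistic: the
contribution being reproduced is the *set logic* downstream of the test,
and moderation moves only borderline calls. The fold change is the
difference of log2 group means; a gene is `up` when log2FC > 1 (fold
change > 2) *and* the Benjamini–Hochberg adjusted p is < 0.05, `down`
symmetrically. Degenerate genes: both groups constant and equal gives
p = 1; constant but unequal gives p = 0 (the unpooled denominator is 0).

**Sets1** (cross-study): per comparison (LN/HN/CN), the union of up-calls
and the union of down-calls across datasets, removing genes called up in
one dataset and down in another. The wording of the source protocol is
ambiguous about whether this consistency filter acts per comparison or
globally; the default is per comparison (the literal reading of "per
comparison" unions), with `scope = "global"` available.

**Stepwise genes**: Spearman correlation (average ranks for ties) of each
gene with the stage code, two-sided p by the t approximation, switching to
an *exact permutation* p when the total sample count is ≤ 10, where the
approximation is unreliable. Because the stage vector has at most four
distinct levels, the permutation null is enumerated over assignments of
rank indices to stage groups (a multinomial enumeration, ≤ 25,200 cases at
n = 10) rather than over all n! permutations — exact and fast in pure R.

**Sets2** (cross-stage): per dataset, genes that are DEGs in at least one
comparison *and* stepwise in the same direction. Whether the original
required the carcinoma comparison specifically is not stated; the default
accepts any comparison, and a `comparison =` argument restricts.

## Over-representation

Flat gene-set collections (cytoband blocks, GO/KEGG exported as GMT) are
tested by the hypergeometric upper tail `P(X >= k)` with BH q-values across
the collection (q < 0.05 for cytobands, q < 0.1 for GO/KEGG in the original
workflow). The universe is the set of genes measured on the platform — the
defensible choice for array data — and can be overridden. DAG-aware GO
simplification and semantic-similarity clustering are out of scope.

## Network centrality and consensus hubs

Nine node-ranking methods are implemented from their definitions on an
undirected simple graph with hop distances: Degree, Betweenness, Stress,
harmonic Closeness (sum of reciprocal distances, well-defined on
disconnected graphs), Radiality (within-component, diameter-shifted mean
closeness), MNC (size of the largest connected component of the open
neighborhood), DMNC (edge count of that component divided by its node count
to the power ε = 1.7, the original method constant), Bottleneck, and EPC.
No installed package provides the cytoHubba-style family, so these are
authored here and verified against brute-force shortest-path enumeration
oracles in the tests.

Two methods need extra determinism decisions. *Bottleneck* counts, over
deterministic BFS shortest-path trees rooted at every node, the roots for
which a node's subtree holds at least a fraction (default 0.25) of the
tree; the underlying method is tree-ambiguous, so the canonical rule
"parent = smallest-named already-visited neighbor" makes scores
reproducible and relabeling-invariant. *EPC* averages a node's cluster size
over random edge-percolation realizations (threshold ~ U(0,1) per
realization, edge variables ~ U(0,1)); the realization count (default 5000,
the original plug-in's convention) and seed are exposed. Analyses in this
repository that loop over many replicate networks use 100–1000
realizations; the Monte-Carlo standard error of EPC scales as
`0.5/sqrt(R)`, which at R = 100 is still an order of magnitude below the
score gaps that decide the top-10 on our networks.

Per network, the candidate set is the union over the nine methods of the
top-k nodes (k = 10), **including every node tied with the k-th score**, so
candidate sets may exceed 9k. Consensus hubs are candidates appearing in at
least `consensus_min` networks. The source protocol states both "any
overlap in three sub-networks" and "occurring in at least two datasets";
the contradiction is preserved as configuration, default 2.

A known consequence of tie expansion worth stating plainly: on sparse
random networks the Bottleneck score is ≥ 1 for every node (each root's
own subtree is its whole tree) and MNC/Stress/Degree take small integer
values, so per-method top-10 sets routinely expand and the nine-method
union covers a large fraction of a desk-scale network. Consensus calling
therefore recovers planted hubs essentially always, but also admits many
background nodes; the hub list should be read as a *screen*, not a
high-precision call. The test suite asserts the recovery property; a
precision bound of ≤ 1 false hub is asserted in the acceptance suite and
documents this limitation when it fails.

## IHC scoring and diagnostic evaluation

H-score = 1·(%1+) + 2·(%2+) + 3·(%3+), range 0–300. Layer scores map the
stained fraction of the epithelial height to 0/1+/2+/3+ by thirds, with the
TOP2A 3+ collapsed into 2+. SCC sections are positive at strictly > 10%
positive cancer cells for every marker. Noninvasive positivity thresholds
are explicit reconstructions (the original scoring table is not published
in full): Ki-67/TOP2A layer ≥ 2, AURKA/CEP55 intensity ≥ 2, RFC4 intensity
≥ 2 with staining beyond the basal layer, p16 by a supplied
block-positivity flag (its criteria are visual, not computable from the
modeled fields). All are configurable.

Diagnostic metrics use exact Clopper–Pearson 95% CIs (these reproduce the
published intervals under integer-count reconstruction, which is how the
published table was pinned down); the binary-test AUC is
(sensitivity + specificity)/2 with a Hanley–McNeil variance CI — the
original interval method is unstated, so this is an assumption. Percentages
are rounded half-up to one decimal and AUC to two, matching the published
formatting. Paired markers are compared by the exact two-sided McNemar
binomial test on the discordant counts; agreement by Cohen's kappa;
combinations by serial (both positive) and parallel (either positive)
interpretation.

**Published-table reconstruction.** A printed proportion with its exact CI
at one decimal almost always pins down the integer counts uniquely below a
size bound (300 here): `match_proportion()` searches all (x, n) whose
percentage and CP interval round (half-up) to the printed values, and
`reconstruct_confusion()` demands uniqueness. The recovered HSIL rows share
68 diseased / 101 controls and the HSIL+ rows 129/101 — consistent with the
"evaluated simultaneously" design — and re-evaluating the metrics on the
recovered counts reproduces the published PPV/NPV/AUC exactly. The
Ki-67/TOP2A agreement table in HSIL follows from the reconstructed
marginals (62 and 60 positives of 68) plus the printed 97.1% agreement,
giving κ = 0.84.

## Survival analysis

Subjects are administratively censored at 60 months (records beyond the
horizon truncated with event = 0; exactly 60 is kept). Kaplan–Meier,
log-rank and Cox fits delegate to the survival package (Efron tie handling
— the modern default, the original is silent; convergence and
|β| > 15 separation guards added). Markers are dichotomized at the cutoff
maximizing the absolute standardized log-rank statistic over splits leaving
≥ 10% of subjects on each side (the conventional minimum-proportion default
of the maximally-selected-rank approach; ties go to the smallest cutoff).
A log-rank p re-computed at the selected cutoff on the same data is
selection-inflated; the result object carries a `selection_biased` flag and
an optional permutation p for the maximal statistic.

Time-dependent discrimination uses the IPCW cumulative-case/dynamic-control
AUC at 12, 24, 36, 48, 60 months: cases (event by t) are weighted by the
inverse Kaplan–Meier censoring survival just before their event time; the
common control weight 1/G(t) cancels. With no censoring this reduces
exactly to the empirical case/control AUC, which the tests assert. Nested
models are compared at each time by a paired bootstrap (default 1000
resamples; the analysis driver uses 500) with Holm adjustment across the
five times — the original "adjusted p-values" method is unnamed, so a
method-agnostic, testable choice was made.

## Synthetic-data generator

The generator emits the statistical structure the analysis assumes, with
defaults fixed once to the emulated study conditions: three discovery
datasets sharing 500 gene symbols; 8 samples per stage; stepwise genes at
+1 log2 per stage step (half up, half down) over a 0.5-SD noise floor;
20 direction-inconsistent genes (sign flipping between odd and even
datasets); SCC noise inflated 1.5× so the carcinoma stage shows the lowest
within-stage correlations without tuning; a 60-node network with 4 hubs
wired to 40% of nodes over an Erdős–Rényi background at p = 0.05; a paired
IHC cohort of 68 diseased / 101 control sections at operating point
(0.882, 0.901) with a Gaussian-copula shared factor (loading 0.5)
controlling inter-marker agreement — a single parameter spanning
conditional independence (κ ≈ 0 within class) to identical calls (κ = 1);
and an exponential survival cohort of n = 252 with a protective marker
(log HR = −0.7), small clinical-covariate effects, uniform censoring
calibrated to a 20% target and the 5-year horizon.

What passing tests on these data show: the pipeline's operations implement
their definitions (oracle equivalence), are calibrated under their nulls,
and recover planted structure at the stated effect sizes. What they do not
show: robustness to probe-level artifacts, batch effects, non-normal noise,
annotation drift between platforms, or real PPI topology — none of which
the generator emulates.

## Problem sizes and numerical notes

Simulation-based tests use 30–200 replicates at the sizes above; the
centrality oracle runs 100 random graphs of ≤ 10 nodes; Cox recovery uses
100 cohorts of n = 1000. Probe collapse breaks mean ties by file order.
Variance ties in gene selection break lexicographically. All file IO is
UTF-8, tab- or comma-separated by extension, decimal points only.
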