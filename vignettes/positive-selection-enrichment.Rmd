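---
title: "Post-processing and gene-set enrichment for genome-wide positive-selection scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-processing and gene-set enrichment for genome-wide positive-selection scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(possel)
```

## The problem

A genome-wide scan for episodic positive selection runs a branch-site
likelihood-ratio test on every branch of every single-copy ortholog
family: the alternative codon model allows a class of sites with
$\omega = d_N/d_S > 1$ on the tested (foreground) branch, the null
constrains that class to $\omega = 1$. The statistic $2\Delta\ln L$ is
referred to a $\chi^2_1$ distribution. At the scale of thousands of
families times a dozen branches, three practical problems dominate, and
this package implements the statistical layer that addresses them:

1. codon-model optimisation does not always converge, so each hypothesis
   is optimised in triplicate and the replicates must be reconciled and
   filtered;
2. tens of thousands of dependent tests need multiple-testing control
   and per-branch/per-lineage accounting, including gene trees whose
   branches merge when taxa are missing;
3. asking *which functions* are targeted needs a gene-set statistic that
   uses the full score distribution rather than a significance cutoff,
   decorrelated across the ontology graph, with an honest FDR.

## Reconciliation and the convergence filter

For each family x branch, the best of three runs per hypothesis is kept:
$\Delta\ln L = \max_r \ln L^{alt}_r - \max_r \ln L^{null}_r$. Negative
values (about 8% of tests in real scans, almost all near 0) are an
artifact of incomplete optimisation, not evidence; they are clamped to
0 and map to $p = 1$. The within-hypothesis spread
$d = \max_h(\max_r \ln L^h_r - \min_r \ln L^h_r)$ diagnoses replicate
disagreement. Its distribution is bimodal — a major mode at 0 and a minor
mode near 1 nat — and a strict cutoff between the modes ($d > 0.004$,
boundary retained) excludes tests with convergence problems from the
p-value series. `d` is computed as the max-of-ranges over the two
hypotheses; the qualitative description ("largest differences ... in both
models") does not pin down a formula, and max-of-ranges is the natural
conservative reading.

Benjamini–Hochberg adjustment is applied over one pooled series — all
converged tests of a data set, branches times families — matching how the
genome scan treats its 10% FDR threshold. Clamped tests stay in the
series with $p = 1$: they are valid, maximally non-significant tests, and
removing them would make the correction anti-conservative. A `groups`
argument allows separate series per data set (e.g. ants, flies, bees).

## Lineage scores and the fourth-root transform

Per-branch results are heterogeneous in power, so the enrichment layer
works on one score per family: the mean LRT over the converged tests on
the lineage's branches (by default the 13 ant branches: 7 terminal + 6
internal). Families missing some branches are averaged over their
*available* branches; how the original analysis handled missing branches
is not documented, so the fixed-denominator alternative (missing = 0) is
provided as an option and `n_branches_used` is always recorded so
sensitivity analyses can filter. Merged branches lying entirely inside
the lineage contribute to the mean, consistent with lineage-level
accounting of merged-branch hits.

Scores follow roughly a $\chi^2_1$ mixture spanning orders of magnitude;
the fourth root is applied **after** averaging as a variance-stabilising,
rank-preserving transform (the two orders differ; a regression test
asserts the implementation transforms the mean). Scores are kept on the
$2\Delta\ln L$ scale by default since that is the $\chi^2$-distributed
quantity; a `statistic = "delta_lnl"` switch exists for comparison.

## The SUMSTAT test and its normal null

For a set $g$ of $n$ genes, $\mathrm{SUMSTAT} = \sum_{i \in g} s_i$ over
transformed scores $s_i$. Under the null that $g$ is a random draw from
the background of $N$ scored genes, the CLT gives
$\mathrm{SUMSTAT} \sim \mathcal{N}(n\mu_G,\; \sigma^2)$ with
$\mu_G$ the background mean. The displayed variance formula in the
source material is not machine-readable, so the package adjudicates it
empirically: random sets are drawn *without replacement* from the gene
list, which implies the finite-population variance
$\sigma^2 = n\,\sigma^2_G\,(N-n)/(N-1)$ with $\sigma^2_G$ the population
(divide-by-$N$) background variance. An exhaustive-enumeration oracle on
toy backgrounds (all $\binom{N}{n}$ subsets) confirms this choice
exactly — e.g. background $\{0,1,2,3\}$, $n=2$: mean 3, variance $5/3$ —
and `empirical_null()` (10,000 random same-size sets) confirms it at
genome scale; the uncorrected i.i.d. variance $n\sigma^2_G$ remains
available as `mode = "iid"`. Both one-sided p-values are computed
(enrichment and depletion); depletion reflects purifying selection and is
reported separately.

The normal approximation is accurate even for small sets: on a
5,000-family synthetic background the Kolmogorov–Smirnov distance
between the empirical null and the fitted normal stays below 0.02 for
$n \in \{11, 25, 100\}$ (the acceptance suite recomputes this).

## elim decorrelation and the permutation FDR

Propagated ontology annotation makes parent sets supersets of their
children, so a single enriched child makes every ancestor "enriched".
The elim procedure tests terms deepest-first (longest-path depth, so a
term always precedes its ancestors; ties broken lexicographically for
determinism) and, when a term is enriched at `elim_alpha`, removes its
current member genes from all ancestor sets before those are tested.
`elim_alpha` is not documented in the original analysis; the package
uses 0.01, the conventional default of the procedure, and records the
value used. Terms falling below the minimum set size after removals are
reported untested rather than silently tested on remnants. Flat
collections (KEGG-style pathways) run with elim disabled.

Because elim-processed tests have an awkward dependence structure, the
reporting criterion is an empirical FDR: gene scores are permuted
(labels reshuffled), the full elim enrichment rerun — permutations must
traverse the same pipeline as the observed data — and at each observed
p-value threshold $t$, $\mathrm{FDR}(t) = N_0(t)/N_t(t)$ with $N_0$ the
mean permutation positive count and $N_t$ the observed count. Thresholds
are exactly the observed p-values; $N_t = 0$ gives FDR 0 by convention
and values above 1 are clamped. Per-term values apply the q-value
convention — the minimum of the FDR curve at or above the term's own p,
the same step-up monotonisation Benjamini–Hochberg performs. Without it
the raw ratio is non-monotone in $t$ and an isolated small p sitting
just below a cluster of larger ps gets an arbitrarily noisy FDR; the
raw per-threshold ratios are still reported in the calibration table. 100 permutations is the default;
on null data this empirical FDR tracks Benjamini–Hochberg closely (the
acceptance suite checks agreement within 0.1 at every observed p). Sets
below 20% empirical FDR are flagged `reported`, and each reported set
gets an outlier diagnostic: the enrichment p recomputed after dropping
its single highest-scoring gene, to distinguish a distributional shift
from one extreme member.

Minimum set sizes: 11 genes for genome-wide functional annotation
(categories mapped to 10 or fewer genes are discarded), 6 for the much
sparser phenotype-ontology annotation.

## Composition and targeted set tests

`composition_test()` asks a different question — whether a *subset* of
genes (e.g. the analyzable data set vs all annotated genes) is biased
across ontology terms — with per-term 2x2 Fisher's exact tests under the
same deepest-first elim removal, both directions reported and BH
adjustment across terms. `fisher_exact()` uses probability-mass
summation for the two-sided p (the convention of common
implementations) and reports the sample odds ratio $ad/bc$.

`targeted_set_test()` handles a-priori sets (caste-biased expression,
ageing contrasts): the SUMSTAT sum is compared to 10,000 randomisations
of gene scores, with the add-one convention
$p = (1 + \#\{S^{perm} \ge S\})/(1 + B)$ so p is never 0, and a
Bonferroni level $0.05/k$ attached for families of $k$ related sets
($k=4$ ageing sets $\to$ 0.0125, $k=6$ caste sets $\to$ 0.0083). The
"effect size" is reported as the observed-over-expected ratio
$S/(n\mu_G)$; this is an interpretation (no formal definition exists for
the published values) and should not be compared numerically to them.

## Tree utilities

`map_branches()` labels each branch of a single-copy family tree by its
canonical species-tree branch: the branch's leaf bipartition must match
exactly one species branch restricted to the species present. When taxa
are missing, chains of species branches collapse onto one family branch;
such branches are labelled `merged:<b>` with `<b>` the branch subtending
the smallest canonical clade containing them, are excluded from
per-branch tallies, and count toward any lineage containing that clade.

`split_tree()` partitions an oversized gene tree (e.g. a several-hundred
leaf receptor family) into testable subtrees of fewer than `max_leaves`
leaves, greedily cutting the branch with the highest bootstrap support
among cuts leaving at least `min_component = 5` leaves on each side,
with ties broken by balance then by smallest tip label. The original
16-subtree partition of the receptor tree cannot be reproduced exactly —
its tie-breaking and size floor were never stated — so the subtree count
is not a validated quantity; the guaranteed properties are the size
bound and that components partition the leaf set.

`gc3_shifts()` computes per-branch shifts in third-codon-position GC
content as the child-minus-parent difference of node values (inputs are
externally estimated ancestral GC3 values); shifts telescope along
root-to-leaf paths by construction.

## The synthetic-data generator

`simulate_dataset()` emulates exactly the statistical structure the
analysis assumes, with ground truth:

* **Null LRTs**: the boundary mixture $\pi_0\delta_0 + (1-\pi_0)\chi^2_1$
  with $\pi_0 = 0.5$, the standard asymptotic result for testing one
  parameter on a boundary. Real branch-site nulls are if anything more
  conservative; $\pi_0$ is configurable.
* **Alternatives**: noncentral $\chi^2_1(\lambda)$. Nothing in the
  original analysis models alternatives; this is the simplest family
  with a tunable effect size, and any power figure must be read together
  with the $\lambda$ used.
* **Replicates**: each run falls short of its hypothesis optimum by
  $|\mathcal{N}(0, \texttt{jitter\_sd})|$; with probability
  `blowup_prob` (default 0.02) one run of one random hypothesis is
  additionally depressed by
  $\mathcal{N}(\texttt{blowup\_scale}, \texttt{blowup\_scale}/10)$
  truncated at 0, recreating the minor mode of $d$ near 1 nat.
* **Trees**: each family loses each ant species independently with
  probability `missing_taxon_prob` (default 0.05; outgroups are always
  kept, and a family keeps all ants if fewer than two would remain), and
  the pruned topology is mapped back to canonical/merged branch labels.
* **Ontology**: a layered random DAG (default 150 terms, 4 layers, 1–2
  parents per term) with genes annotated at leaf terms only; upward
  propagation is left to the ontology module, so the generator cannot
  mask propagation bugs.
* **Planted enrichment**: a planted term draws a fraction of its member
  families under selection ($\lambda$ on every tested branch). All
  randomness flows through deterministic per-family sub-streams, so
  non-member families are byte-identical between a planted and an
  unplanted run of the same seed — planted/background comparisons are
  exactly paired.

What the generator does **not** emulate: sequence evolution, alignment
error, dS saturation, GC-biased gene conversion, correlated scores among
paralogs, or realistic GO topology. Passing tests therefore validate the
*inference layer* — calibration, FDR control, decorrelation, power under
a stated effect size — not robustness to upstream artifacts of real
scans.

## Numerical and design choices

* p-values at $\Delta\ln L = 0$ are exactly 1; the p mapping matches the
  closed-form $2\Phi(-\sqrt{2\Delta\ln L})$ to 10 significant digits.
* The convergence filter keeps the boundary ($d \le$ cutoff retained).
* $\sigma^2_G$ uses the divide-by-$N$ convention so the enumeration
  oracle matches exactly.
* A set spanning the whole background has zero finite-population
  variance and is reported untested.
* Deterministic orderings everywhere (depth then id; bootstrap then
  balance then tip label) make reruns byte-identical under a fixed seed.
* Problem sizes used by the validation suites — 5,000-family backgrounds
  for the normal-approximation and power checks, 3,000 families for the
  FDR-agreement check, 20–25 replicates for the rate estimates, 100
  permutations, 10,000-draw empirical nulls — were chosen as the
  smallest sizes at which the Monte-Carlo error is well below the
  tolerances being asserted.

## Known limitations

* The elim significance level and the exact handling of families with
  missing branches in the published lineage score are undocumented
  upstream; both are explicit, configurable choices here.
* The empirical FDR is a plug-in ratio estimate; with few observed
  positives it is noisy and is clamped rather than smoothed.
* `map_branches()` assumes family trees follow the species topology
  (true by construction for the single-copy pipeline that produced
  them); it does not attempt reconciliation of discordant topologies.
* The permutation FDR assumes exchangeability of scores across families,
  which ignores, e.g., correlated selection pressures within genomic
  neighbourhoods.
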