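# File formats

All tabular files are tab-separated with a header line; lines starting
with `#` are comments. Floating-point values are written with 10
significant digits, so reruns under a fixed seed are byte-identical.

## replicate_runs.tsv
One row per likelihood optimisation run.

| column      | type    | meaning                                   |
|-------------|---------|-------------------------------------------|
| family_id   | string  | gene-family id                             |
| branch_id   | string  | canonical branch label or `merged:<b>`     |
| hypothesis  | string  | `null` or `alt`                            |
| run         | int     | replicate index (1, 2, 3)                  |
| lnl         | float   | maximised log-likelihood (nats)            |

## test_records.tsv
One row per family x branch test after reconciliation/processing:
`family_id`, `branch_id`, `delta_lnl` (reconciled, clamped at 0), `lrt`
(= 2 x delta_lnl), `d` (largest within-hypothesis run spread, nats),
`clamped`, `converged`, `p` (chi-square(1) upper tail; NA if not
converged), `q` (Benjamini-Hochberg over the pooled converged series),
`significant` (q <= threshold).

## family_scores.tsv
`family_id`, `n_branches_used`, `mean_lrt` (mean LRT over usable lineage
branches), `transformed` (fourth root of the mean).

## associations.tsv
Two columns, `gene` and `term`: direct (unpropagated) annotations.

## ontology.obo
OBO subset: `[Term]` stanzas with `id`, `name`, `namespace`, `is_a`,
`relationship: part_of`, `is_obsolete`.

## family_trees.tsv
`family_id`, `newick`: the pruned per-family species topology.

## gene sets (settest input)
One set per line: `name` TAB comma-separated gene ids.

## enrichment.tsv
One row per term: `term_id`, `set_size`, `S` (SUMSTAT sum of transformed
scores), `z`, `p_enrich`, `p_deplete`, `genes_removed_by_elim`, `tested`,
`fdr_bh`, `fdr_bh_deplete`, `fdr_empirical`, `fdr_empirical_deplete`,
`reported` (empirical FDR < reporting threshold), `p_drop_top` (outlier
diagnostic: enrichment p after removing the top-scoring member).

## fdr_table.tsv
Empirical FDR calibration: `threshold` (observed p-value), `N_t`
(observed positives at the threshold), `N_0` (mean permutation
positives), `fdr` (= N_0 / N_t, clamped to [0, 1]).

## truth_tests.tsv / truth_terms.tsv (simulator only)
Ground truth: per-test selection labels (`family_id`, `branch_id`,
`selected`, `lambda`) and per-term planting labels (`term`, `planted`,
`member_sel_fraction`, `noncentrality`).

## branch_counts.tsv
Per canonical branch: `branch`, `n_significant`, `fraction` (of all
families in the record set).
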