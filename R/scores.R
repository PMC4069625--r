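## Lineage-level selection scores per gene family.

#' Fourth-root variance-stabilising transform
#'
#' Branch-site likelihood-ratio scores follow (approximately) a chi-square
#' distribution with one degree of freedom and span several orders of
#' magnitude; the fourth root stabilises their variance while conserving
#' ranks, which makes the sum statistic of [sumstat_test()] well behaved.
#'
#' @param scores non-negative numeric vector.
#' @return `scores^(1/4)`.
#' @export
transform_scores <- function(scores) {
  if (any(!is.finite(scores)) || any(scores < 0))
    stop("scores must be finite and >= 0")
  scores^0.25
}

#' Collapse per-branch tests into one lineage-level score per family
#'
#' For each gene family, the selection score is the arithmetic mean of the
#' LRT statistic (2 * delta_lnl) over the converged tests on branches of the
#' focal lineage, fourth-root transformed afterwards (the transform is
#' applied to the mean, not the mean of transforms). Merged branches are
#' included when their containing canonical clade lies inside the lineage.
#' Families with no usable branch are dropped with a message.
#'
#' @param records processed `test_records` (needs `converged`, `lrt`).
#' @param branch_set canonical branch labels defining the lineage (e.g. the
#'   13 ant branches: 7 terminal + 6 internal).
#' @param include_merged include `"merged:<b>"` records with `b` in
#'   `branch_set` (default TRUE).
#' @param denominator `"available"` divides by the number of usable branches
#'   of that family; `"fixed"` divides by `length(branch_set)`, treating
#'   missing branches as zeros.
#' @param statistic score scale: `"lrt"` (2 * delta_lnl, default) or
#'   `"delta_lnl"`.
#' @return data frame `family_scores`: `family_id`, `n_branches_used`,
#'   `mean_lrt`, `transformed`.
#' @export
lineage_scores <- function(records, branch_set, include_merged = TRUE,
                           denominator = c("available", "fixed"),
                           statistic = c("lrt", "delta_lnl")) {
  denominator <- match.arg(denominator)
  statistic <- match.arg(statistic)
  if (is.null(records$converged))
    stop("records must carry a 'converged' column (run process_tests first)")
  lab <- records$branch_id
  in_set <- lab %in% branch_set
  if (include_merged) {
    cont <- merged_container(lab)
    in_set <- in_set | (!is.na(cont) & cont %in% branch_set)
  }
  use <- records$converged & in_set
  kept <- records[use, , drop = FALSE]
  dropped <- setdiff(unique(records$family_id), unique(kept$family_id))
  if (length(dropped))
    message(length(dropped), " families without a usable lineage branch dropped")
  if (!nrow(kept))
    return(data.frame(family_id = character(), n_branches_used = integer(),
                      mean_lrt = numeric(), transformed = numeric()))
  score <- if (statistic == "lrt") kept$lrt else kept$delta_lnl
  sums <- tapply(score, kept$family_id, sum)
  ns <- tapply(score, kept$family_id, length)
  denom <- if (denominator == "available") as.numeric(ns)
           else rep(length(branch_set), length(ns))
  out <- data.frame(
    family_id = names(sums),
    n_branches_used = as.integer(ns),
    mean_lrt = as.numeric(sums) / denom,
    stringsAsFactors = FALSE
  )
  out$transformed <- transform_scores(out$mean_lrt)
  rownames(out) <- NULL
  out
}

#' Named vector of transformed family scores
#'
#' Convenience accessor: the enrichment layer works on a named numeric
#' vector (names = family ids, values = transformed scores).
#'
#' @param family_scores output of [lineage_scores()].
#' @return named numeric vector.
#' @export
score_vector <- function(family_scores) {
  setNames(family_scores$transformed, family_scores$family_id)
}
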