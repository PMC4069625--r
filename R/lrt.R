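## Reconciliation, convergence filtering, p-values and FDR for replicated
## branch-site (and site) likelihood-ratio tests.

#' Reconcile triplicate likelihood runs into one test record per branch
#'
#' Codon-model likelihood optimisation is prone to convergence failures, so
#' each hypothesis (null and alternative) is optimised three times and the
#' best run kept. `reconcile()` collapses the replicated log-likelihoods into
#' one record per family x branch:
#' `delta_lnl = max(lnL_alt) - max(lnL_null)`, clamped at zero when negative
#' (a negative log-likelihood ratio means non-significance, not evidence);
#' `lrt = 2 * delta_lnl`; and `d`, the largest within-hypothesis spread
#' (`max - min` over the three runs, maximised over the two hypotheses),
#' which diagnoses runs that did not converge to the same optimum.
#'
#' @param runs data frame of replicated runs with columns `family_id`,
#'   `branch_id`, `hypothesis` (`"null"` or `"alt"`), `run` (1, 2, 3) and
#'   `lnl` (log-likelihood, nats). Every family x branch must have exactly
#'   three runs per hypothesis.
#' @return A `test_records` data frame with one row per family x branch and
#'   columns `family_id`, `branch_id`, `delta_lnl`, `lrt`, `d`, `clamped`.
#'   Row order follows the sorted (family, branch) keys; the result is
#'   invariant to the order of the input rows.
#' @examples
#' runs <- data.frame(
#'   family_id = "F1", branch_id = "Sinv",
#'   hypothesis = rep(c("null", "alt"), each = 3), run = rep(1:3, 2),
#'   lnl = c(-103, -103, -103, -100.2, -100.25, -100.21))
#' reconcile(runs)
#' @seealso [convergence_filter()], [lrt_pvalue()], [process_tests()]
#' @export
reconcile <- function(runs) {
  req <- c("family_id", "branch_id", "hypothesis", "run", "lnl")
  miss <- setdiff(req, names(runs))
  if (length(miss))
    stop("replicate-run table lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(runs$hypothesis %in% c("null", "alt")))
    stop("hypothesis must be 'null' or 'alt'")
  bad <- !is.finite(runs$lnl)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("non-finite log-likelihood for family %s, branch %s",
                 runs$family_id[i], runs$branch_id[i]))
  }

  key <- paste(runs$family_id, runs$branch_id, sep = "\r")
  ord <- order(key, runs$hypothesis, runs$run)  # "alt" sorts before "null"
  key <- key[ord]
  lnl <- runs$lnl[ord]
  hyp <- runs$hypothesis[ord]

  r <- rle(key)
  if (any(r$lengths != 6L)) {
    i <- which(r$lengths != 6L)[1L]
    stop("expected exactly 3 runs per hypothesis for ",
         gsub("\r", " / ", r$values[i]))
  }
  n <- length(r$values)
  if (!all(hyp == rep(rep(c("alt", "null"), each = 3L), n)))
    stop("expected exactly 3 'null' and 3 'alt' runs per family x branch")

  base <- seq(1L, length(lnl), by = 6L)
  a1 <- lnl[base]; a2 <- lnl[base + 1L]; a3 <- lnl[base + 2L]
  n1 <- lnl[base + 3L]; n2 <- lnl[base + 4L]; n3 <- lnl[base + 5L]
  max_alt <- pmax(a1, a2, a3); min_alt <- pmin(a1, a2, a3)
  max_null <- pmax(n1, n2, n3); min_null <- pmin(n1, n2, n3)

  delta <- max_alt - max_null
  clamped <- delta < 0
  delta[clamped] <- 0
  d <- pmax(max_alt - min_alt, max_null - min_null)

  fb <- strsplit(r$values, "\r", fixed = TRUE)
  out <- data.frame(
    family_id = vapply(fb, `[`, "", 1L),
    branch_id = vapply(fb, `[`, "", 2L),
    delta_lnl = delta,
    lrt = 2 * delta,
    d = d,
    clamped = clamped,
    stringsAsFactors = FALSE
  )
  class(out) <- c("test_records", "data.frame")
  out
}

#' Flag tests with likelihood-convergence problems
#'
#' The distribution of the within-hypothesis run spread `d` is bimodal: a
#' major mode at 0 (replicates agree) and a minor mode near 1 (at least one
#' replicate stuck at a worse optimum). A strict cutoff between the modes
#' removes unreliable tests; records with `d > cutoff` are marked
#' `converged = FALSE` and are excluded from the p-value/FDR series by
#' [process_tests()]. The boundary `d == cutoff` is retained.
#'
#' @param records output of [reconcile()].
#' @param cutoff spread threshold in nats (default 0.004).
#' @return `records` with a logical `converged` column.
#' @export
convergence_filter <- function(records, cutoff = 0.004) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff >= 0)
  records$converged <- records$d <= cutoff
  n_excl <- sum(!records$converged)
  if (n_excl > 0)
    message(n_excl, " of ", nrow(records),
            " tests excluded for convergence problems (d > ", cutoff, ")")
  records
}

#' Chi-square(1) p-value of a (clamped) log-likelihood ratio
#'
#' The test statistic 2 * `delta_lnl` is compared to a chi-square
#' distribution with one degree of freedom. A clamped ratio of 0 maps to
#' p = 1 exactly.
#'
#' @param delta_lnl non-negative reconciled log-likelihood ratio(s), nats.
#' @return upper-tail probabilities, same length as the input.
#' @examples
#' lrt_pvalue(16.1)  # 1.4e-08
#' lrt_pvalue(0)     # 1
#' @export
lrt_pvalue <- function(delta_lnl) {
  if (!is.numeric(delta_lnl) || any(!is.finite(delta_lnl)))
    stop("delta_lnl must be finite numeric")
  if (any(delta_lnl < 0))
    stop("delta_lnl must be >= 0: clamp negative log-likelihood ratios to 0 upstream")
  pchisq(2 * delta_lnl, df = 1, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment over one series of p-values. In the genome-wide scan
#' the series pools every converged test (number of branches tested x number
#' of gene families tested) of one data set.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Run the full test post-processing chain
#'
#' Reconciles replicated runs (if raw runs are given), applies the
#' convergence filter, computes chi-square(1) p-values for converged tests,
#' adjusts them by Benjamini-Hochberg over one pooled series (or within
#' groups), and flags significance at the q-value threshold. Non-converged
#' tests carry `NA` p/q and are never significant.
#'
#' @param x replicate-run data frame (see [reconcile()]) or a `test_records`
#'   data frame already reconciled.
#' @param d_cutoff convergence cutoff in nats, see [convergence_filter()].
#' @param fdr_threshold q-value threshold for the `significant` flag
#'   (default 0.10, i.e. 10% FDR).
#' @param groups optional factor (one value per record) splitting the FDR
#'   series, e.g. one level per data set; default: one pooled series.
#' @return `test_records` data frame with added columns `converged`, `p`,
#'   `q`, `significant`.
#' @export
process_tests <- function(x, d_cutoff = 0.004, fdr_threshold = 0.10,
                          groups = NULL) {
  records <- if (inherits(x, "test_records")) x else reconcile(x)
  records <- convergence_filter(records, cutoff = d_cutoff)
  records$p <- NA_real_
  records$q <- NA_real_
  conv <- records$converged
  records$p[conv] <- lrt_pvalue(records$delta_lnl[conv])
  if (is.null(groups)) {
    records$q[conv] <- bh_fdr(records$p[conv])
  } else {
    stopifnot(length(groups) == nrow(records))
    for (g in split(which(conv), groups[conv]))
      records$q[g] <- bh_fdr(records$p[g])
  }
  records$significant <- !is.na(records$q) & records$q <= fdr_threshold
  message(sum(conv), " converged tests (", sum(records$clamped), " clamped), ",
          sum(records$significant), " significant at q <= ", fdr_threshold)
  records
}

merged_container <- function(label) {
  ifelse(startsWith(label, "merged:"), sub("^merged:", "", label), NA_character_)
}

#' Tally significant families per branch and per lineage
#'
#' Per-branch counts use canonical branch labels only. A gene-family branch
#' produced by merging several canonical branches (missing taxa) is labelled
#' `"merged:<branch>"`, where `<branch>` subtends the smallest canonical
#' clade containing it; such tests are not counted for any single branch but
#' do count for a lineage that contains that clade.
#'
#' @param records processed `test_records` (with `significant`).
#' @param lineages named list of character vectors; each vector lists the
#'   canonical branch labels making up one lineage.
#' @param branch_labels canonical labels to tabulate; default: all
#'   non-merged labels present in `records`.
#' @return list with `branches` (label, n_significant, fraction),
#'   `lineages` (name, n_significant, fraction) and `n_families`.
#'   Fractions are relative to the number of distinct families in `records`.
#' @export
tabulate_selection <- function(records, lineages = list(),
                               branch_labels = NULL) {
  if (is.null(records$significant))
    stop("records must be processed first (no 'significant' column)")
  fams <- unique(records$family_id)
  n_fam <- length(fams)
  lab <- records$branch_id
  is_merged <- startsWith(lab, "merged:")
  if (is.null(branch_labels)) {
    branch_labels <- sort(unique(lab[!is_merged]))
  } else {
    unknown <- setdiff(lab[!is_merged], branch_labels)
    if (length(unknown))
      stop("unknown branch label(s): ", paste(unknown, collapse = ", "))
  }

  sig <- records[records$significant, , drop = FALSE]
  sig_lab <- sig$branch_id
  sig_merged_in <- merged_container(sig_lab)

  n_per_branch <- vapply(branch_labels, function(b)
    length(unique(sig$family_id[sig_lab == b])), 0L)
  branches <- data.frame(
    branch = branch_labels,
    n_significant = as.integer(n_per_branch),
    fraction = if (n_fam) n_per_branch / n_fam else rep(0, length(branch_labels)),
    stringsAsFactors = FALSE
  )

  lin <- lapply(names(lineages), function(nm) {
    set <- lineages[[nm]]
    hit <- sig_lab %in% set | (!is.na(sig_merged_in) & sig_merged_in %in% set)
    k <- length(unique(sig$family_id[hit]))
    data.frame(lineage = nm, n_significant = k,
               fraction = if (n_fam) k / n_fam else 0,
               stringsAsFactors = FALSE)
  })
  lineage_df <- if (length(lin)) do.call(rbind, lin) else
    data.frame(lineage = character(), n_significant = integer(),
               fraction = numeric())

  list(branches = branches, lineages = lineage_df, n_families = n_fam)
}

#' Filter test records to top-hit reporting criteria
#'
#' Composable predicate filter used to produce curated top-hit tables:
#' keep internal branches only, require a synonymous rate below a maximum
#' (saturation guard) and a minimum Bayes-Empirical-Bayes site support.
#' Criteria whose column is absent are skipped with a warning.
#'
#' @param records processed `test_records`, optionally carrying the
#'   pass-through columns `ds_foreground`, `beb_max`.
#' @param internal_branches character vector of internal branch labels, or
#'   `NULL` to skip the branch criterion.
#' @param max_ds maximum foreground dS (default 1).
#' @param min_beb minimum max-BEB posterior (default 0.9).
#' @return filtered records, ordered by decreasing `delta_lnl`.
#' @export
top_hits <- function(records, internal_branches = NULL, max_ds = 1,
                     min_beb = 0.9) {
  keep <- rep(TRUE, nrow(records))
  if (!is.null(internal_branches))
    keep <- keep & records$branch_id %in% internal_branches
  for (crit in list(c("ds_foreground", "max"), c("beb_max", "min"))) {
    col <- crit[1L]
    if (is.null(records[[col]])) {
      warning("column '", col, "' absent; criterion skipped")
    } else if (crit[2L] == "max") {
      keep <- keep & !is.na(records[[col]]) & records[[col]] < max_ds
    } else {
      keep <- keep & !is.na(records[[col]]) & records[[col]] > min_beb
    }
  }
  out <- records[keep, , drop = FALSE]
  out[order(-out$delta_lnl), , drop = FALSE]
}

#' @export
print.test_records <- function(x, ...) {
  cat("Branch-site test records: ", nrow(x), " tests, ",
      length(unique(x$family_id)), " families\n", sep = "")
  if (!is.null(x$converged))
    cat("  converged: ", sum(x$converged), "; clamped: ", sum(x$clamped),
        if (!is.null(x$significant))
          paste0("; significant: ", sum(x$significant)), "\n", sep = "")
  print(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat("  ... ", nrow(x) - 6L, " more rows\n", sep = "")
  invisible(x)
}
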