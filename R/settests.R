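## Fisher's-exact composition tests and targeted permutation SUMSTAT tests
## on externally defined gene sets.

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact test on the conditional hypergeometric distribution,
#' summing the probabilities of all tables as or less probable than the
#' observed one. The odds ratio is the sample cross-product `ad / bc`
#' (infinite when `bc = 0` and `ad > 0`), not the conditional MLE.
#'
#' @param table 2x2 matrix (or length-4 vector, row-wise `a, b, c, d`) of
#'   non-negative integer counts.
#' @return list with `odds_ratio` and `p` (two-sided).
#' @examples
#' fisher_exact(matrix(c(1, 9, 11, 3), 2, byrow = TRUE))
#' @export
fisher_exact <- function(table) {
  if (is.vector(table) && length(table) == 4L)
    table <- matrix(table, 2L, byrow = TRUE)
  if (!is.matrix(table) || !all(dim(table) == 2L))
    stop("table must be 2x2")
  if (any(table < 0) || any(table != round(table)))
    stop("cells must be non-negative integers")
  if (sum(table) == 0)
    stop("table is all zero (no positive margin)")
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  p <- stats::fisher.test(table)$p.value
  list(odds_ratio = or, p = min(p, 1))
}

#' Over/under-representation of a gene subset across ontology terms
#'
#' For each term of the collection, a 2x2 Fisher's exact test contrasts
#' membership in the subset of interest against membership in the term,
#' within the reference universe. Terms are processed deepest first with
#' the same elim decorrelation as the score-based enrichment: genes of a
#' term significantly over-represented (one-sided `p_over < elim_alpha`)
#' are removed from all ancestor terms before these are tested.
#'
#' @param collection size-filtered [gene_set_collection][filter_sets()]
#'   whose background is the reference universe.
#' @param graph [ontology_graph()] or `NULL` (no elim).
#' @param subset character vector of gene ids of interest (must be a
#'   subset of the reference).
#' @param reference character vector, the universe; defaults to the
#'   collection background.
#' @param elim_alpha removal level for elim (default 0.01).
#' @return data frame per term: `term_id`, `set_size`, `n_in_subset`,
#'   `expected`, `odds_ratio`, `p_over`, `p_under`, `p_two_sided`,
#'   `direction`, `fdr_bh` (BH over the two-sided series),
#'   `genes_removed_by_elim`, `tested`.
#' @export
composition_test <- function(collection, graph = NULL, subset,
                             reference = collection$background,
                             elim_alpha = 0.01) {
  if (!length(subset)) stop("subset must be non-empty")
  reference <- unique(reference)
  subset <- unique(subset)
  if (length(setdiff(subset, reference)))
    stop("subset contains genes outside the reference universe")
  min_size <- if (is.null(collection$min_size)) 1L else collection$min_size
  ids <- names(collection$members)
  order_ids <- if (is.null(graph)) sort(ids) else depth_order(graph, ids)
  removed <- new.env(parent = emptyenv())
  n_ref <- length(reference)
  n_sub <- length(subset)

  rows <- vector("list", length(order_ids))
  for (k in seq_along(order_ids)) {
    t <- order_ids[k]
    mem <- intersect(collection$members[[t]], reference)
    rem <- if (!is.null(graph)) removed[[t]] else NULL
    cur <- if (length(rem)) setdiff(mem, rem) else mem
    n_removed <- length(mem) - length(cur)
    m <- length(cur)
    if (m < min_size || m == 0L) {
      rows[[k]] <- data.frame(term_id = t, set_size = m,
                              n_in_subset = NA_integer_, expected = NA_real_,
                              odds_ratio = NA_real_, p_over = NA_real_,
                              p_under = NA_real_, p_two_sided = NA_real_,
                              direction = NA_character_,
                              genes_removed_by_elim = n_removed,
                              tested = FALSE, stringsAsFactors = FALSE)
      next
    }
    a <- length(intersect(cur, subset))        # in term & in subset
    # hypergeometric tails: white balls = subset, draws = term members
    p_over <- stats::phyper(a - 1L, n_sub, n_ref - n_sub, m,
                            lower.tail = FALSE)
    p_under <- stats::phyper(a, n_sub, n_ref - n_sub, m, lower.tail = TRUE)
    tab <- matrix(c(a, m - a, n_sub - a, n_ref - n_sub - (m - a)), 2L)
    fe <- fisher_exact(tab)
    expected <- m * n_sub / n_ref
    rows[[k]] <- data.frame(term_id = t, set_size = m, n_in_subset = a,
                            expected = expected, odds_ratio = fe$odds_ratio,
                            p_over = p_over, p_under = p_under,
                            p_two_sided = fe$p,
                            direction = if (a >= expected) "over" else "under",
                            genes_removed_by_elim = n_removed,
                            tested = TRUE, stringsAsFactors = FALSE)
    if (!is.null(graph) && elim_alpha > 0 && p_over < elim_alpha) {
      for (anc in term_ancestors(graph, t))
        removed[[anc]] <- union(removed[[anc]], cur)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$fdr_bh <- NA_real_
  out$fdr_bh[out$tested] <- bh_fdr(out$p_two_sided[out$tested])
  out
}

#' Targeted SUMSTAT test of one externally defined gene set
#'
#' Tests whether the summed transformed scores of an a-priori gene set
#' (e.g. genes over-expressed in one caste, or an ageing-regulated set)
#' differ from random sets of the same size drawn from the scored
#' background. The p-value is empirical, from `B` randomisations of gene
#' scores, with the add-one convention `p = (1 + #extreme) / (1 + B)` so
#' it is never exactly 0. A Bonferroni level `0.05 / k_tests` is attached
#' for families of related tests (e.g. `k_tests = 4` ageing sets gives
#' 0.0125; 6 caste sets give 0.0083). The effect size is the
#' observed-over-expected SUMSTAT ratio `S / (n * mu_G)`.
#'
#' @param gene_set character vector of gene ids; members absent from the
#'   scored background are dropped.
#' @param scores named numeric vector of transformed scores.
#' @param B number of randomisations (default 10000).
#' @param k_tests number of tests in the Bonferroni family (default 1).
#' @param direction `"enrich"` (sum at least as high as observed) or
#'   `"deplete"`.
#' @param name label carried through to the result.
#' @return object of class `targeted_set_result`: list with `name`, `n`,
#'   `S`, `expected`, `effect_size`, `p`, `direction`, `B`,
#'   `bonferroni_alpha`, `significant`.
#' @export
targeted_set_test <- function(gene_set, scores, B = 10000L, k_tests = 1L,
                              direction = c("enrich", "deplete"),
                              name = deparse(substitute(gene_set))) {
  direction <- match.arg(direction)
  force(name)
  if (B < 100L) warning("B < 100 gives a very coarse p-value resolution")
  genes <- intersect(unique(gene_set), names(scores))
  if (!length(genes)) stop("gene set has no overlap with the scored background")
  n <- length(genes)
  S <- sum(scores[genes])
  N <- length(scores)
  perm <- vapply(seq_len(B), function(i) sum(scores[sample.int(N, n)]), 0)
  extreme <- if (direction == "enrich") sum(perm >= S) else sum(perm <= S)
  p <- (1 + extreme) / (1 + B)
  expected <- n * mean(scores)
  structure(list(name = name, n = n, S = S, expected = expected,
                 effect_size = S / expected, p = p, direction = direction,
                 B = as.integer(B),
                 bonferroni_alpha = 0.05 / k_tests,
                 significant = p < 0.05 / k_tests),
            class = "targeted_set_result")
}

#' @export
print.targeted_set_result <- function(x, ...) {
  cat("Targeted SUMSTAT set test: ", x$name, "\n", sep = "")
  cat(sprintf("  n = %d, S = %.4g (expected %.4g, effect size %.3g)\n",
              x$n, x$S, x$expected, x$effect_size))
  cat(sprintf("  empirical p (%s, B = %d) = %.4g; Bonferroni alpha = %.4g%s\n",
              x$direction, x$B, x$p, x$bonferroni_alpha,
              if (x$significant) " *" else ""))
  invisible(x)
}
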