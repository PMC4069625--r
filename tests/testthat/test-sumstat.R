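# Exhaustive enumeration over all C(N, n) subsets: the independent oracle
# for the SUMSTAT null mean and (without-replacement) variance.
enumerate_null <- function(scores, n) {
  sums <- combn(scores, n, sum)
  list(mean = mean(sums), var = mean((sums - mean(sums))^2))
}

test_that("null parameters match exhaustive enumeration on toy backgrounds", {
  bg <- setNames(c(0, 1, 2, 3), letters[1:4])
  np <- sumstat_null_params(2, bg)
  expect_equal(np$mean, 3)
  expect_equal(np$var, 5 / 3)
  # all subset sums {1,2,3,3,4,5}: mean 3, variance 5/3
  oracle <- enumerate_null(bg, 2)
  expect_equal(np$mean, oracle$mean)
  expect_equal(np$var, oracle$var)

  set.seed(9)
  for (N in c(5, 7, 8)) {
    sc <- setNames(rchisq(N, 1)^0.25, paste0("g", 1:N))
    for (n in 1:(N - 1)) {
      np <- sumstat_null_params(n, sc)
      oracle <- enumerate_null(sc, n)
      expect_equal(np$mean, oracle$mean)
      expect_equal(np$var, oracle$var)
    }
  }
})

test_that("iid mode drops the finite-population correction", {
  sc <- setNames(c(0, 1, 2, 3), letters[1:4])
  expect_equal(sumstat_null_params(2, sc, mode = "iid")$var, 2 * 1.25)
  expect_equal(sumstat_null_params(4, sc)$var, 0)  # n = N degenerate
})

test_that("sumstat test is symmetric at the null mean and errors when degenerate", {
  bg <- setNames(c(0, 1, 2, 3), letters[1:4])
  res <- sumstat_test(c("b", "c"), bg)  # S = 3 = null mean
  expect_equal(res$p_enrich, 0.5)
  expect_equal(res$p_enrich + res$p_deplete, 1)
  expect_error(sumstat_test(letters[1:4], bg), "whole background")
  expect_error(sumstat_test(character(0), bg), "empty")
  expect_error(sumstat_test(c("a", "b"), setNames(rep(2, 6), letters[1:6])),
               "all scores equal")
  expect_error(sumstat_test("zz", bg), "unscored")
})

test_that("empirical null matches the analytic parameters", {
  sc <- skewed_scores(400)
  set.seed(21)
  samp <- empirical_null(25, sc, B = 4000)
  np <- sumstat_null_params(25, sc)
  expect_lt(abs(mean(samp) - np$mean), 4 * sqrt(np$var / 4000))
  expect_lt(abs(var(samp) / np$var - 1), 0.12)
  # toy background: sample variance against the enumeration oracle
  toy <- setNames(c(0, 1, 2, 3), letters[1:4])
  set.seed(22)
  s2 <- empirical_null(2, toy, B = 20000)
  expect_lt(abs(var(s2) - 5 / 3), 0.05)
  # n = 1 reduces to resampling single scores
  set.seed(23)
  s1 <- empirical_null(1, sc, B = 5000)
  ks <- suppressWarnings(ks.test(s1, sc)$statistic)
  expect_lt(unname(ks), 0.03)
  expect_error(empirical_null(400, sc), "smaller")
})

test_that("elim with alpha 0 reduces to independent per-term tests", {
  sc <- skewed_scores(120)
  g <- diamond_graph()
  members <- list(leaf = names(sc)[1:15], m1 = names(sc)[1:25],
                  m2 = names(sc)[c(1:15, 40:50)], root = names(sc)[1:60])
  coll <- make_collection(members, names(sc), min_size = 5)
  res0 <- elim_enrichment(coll, g, sc, elim_alpha = 0)
  for (t in names(members)) {
    plain <- sumstat_test(members[[t]], sc)
    i <- match(t, res0$term_id)
    expect_equal(res0$p_enrich[i], plain$p_enrich)
    expect_equal(res0$genes_removed_by_elim[i], 0L)
  }
})

test_that("significant siblings strip the union of their genes from the parent", {
  set.seed(31)
  sc <- skewed_scores(300)
  hot <- names(sc)[1:30]
  sc[hot] <- sc[hot] + 3  # strong planted signal in both siblings
  g <- ontology_graph(
    data.frame(id = c("root", "s1", "s2"), name = c("r", "s1", "s2"),
               namespace = "bp"),
    data.frame(child = c("s1", "s2"), parent = "root"))
  shared <- hot[11:20]
  members <- list(s1 = c(hot[1:10], shared), s2 = c(shared, hot[21:30]),
                  root = c(hot, names(sc)[31:80]))
  coll <- make_collection(members, names(sc), min_size = 5)
  res <- elim_enrichment(coll, g, sc, elim_alpha = 0.01)
  expect_true(all(res$p_enrich[res$term_id %in% c("s1", "s2")] < 0.01))
  # union of sibling genes (30 distinct, shared counted once) removed
  expect_equal(res$genes_removed_by_elim[res$term_id == "root"], 30L)
})

test_that("a parent enriched only through its child is suppressed by elim", {
  set.seed(41)
  hits <- 0L
  for (rep in 1:20) {
    sc <- setNames(rchisq(1000, 1)^0.25, sprintf("G%04d", 1:1000))
    child_genes <- names(sc)[1:30]
    sel <- sample(child_genes, 15)
    sc[sel] <- rchisq(15, 1, ncp = 10)^0.25
    g <- chain_graph()
    members <- list(leaf = child_genes,
                    mid = c(child_genes, names(sc)[31:60]),
                    root = names(sc)[1:200])
    coll <- make_collection(members, names(sc), min_size = 5)
    res <- elim_enrichment(coll, g, sc, elim_alpha = 0.01)
    child_sig <- res$p_enrich[res$term_id == "leaf"] < 0.01
    parent_ok <- res$p_enrich[res$term_id == "mid"] > 0.05
    if (child_sig && parent_ok) hits <- hits + 1L
  }
  expect_gte(hits, 16L)  # >= 80% of replicates
})

test_that("permutation FDR follows the N0/Nt definition and is deterministic", {
  set.seed(51)
  sc <- skewed_scores(500)
  members <- lapply(1:40, function(i) sample(names(sc), 20))
  names(members) <- sprintf("T%02d", 1:40)
  coll <- make_collection(members, names(sc), min_size = 5)
  obs <- elim_enrichment(coll, NULL, sc)
  set.seed(99)
  pf <- permutation_fdr(obs, coll, NULL, sc, B = 30)
  tab <- pf$table
  expect_equal(tab$N_t,
               vapply(tab$threshold, function(t) sum(obs$p_enrich <= t), 0L))
  expect_equal(tab$fdr, ifelse(tab$N_t == 0, 0, pmin(1, tab$N_0 / tab$N_t)))
  expect_true(all(tab$fdr >= 0 & tab$fdr <= 1))
  # per-term FDR is the table value at the term's own p
  i <- which.min(obs$p_enrich)
  expect_equal(unname(pf$fdr[obs$term_id[i]]), tab$fdr[1])
  set.seed(99)
  pf2 <- permutation_fdr(obs, coll, NULL, sc, B = 30)
  expect_identical(pf, pf2)
  expect_error(permutation_fdr(obs, coll, NULL, sc, B = 0), "B")
})

test_that("null calibration: about 5% of random sets reach p < 0.05", {
  set.seed(61)
  sc <- skewed_scores(1500, seed = 61)
  p <- replicate(2500, sumstat_test(sample(names(sc), 20), sc)$p_enrich)
  se <- sqrt(0.05 * 0.95 / 2500)
  expect_lt(abs(mean(p < 0.05) - 0.05), 3 * se + 0.01)
})

test_that("the enrichment driver assembles FDR columns and diagnostics", {
  set.seed(71)
  sc <- skewed_scores(400, seed = 71)
  hot <- names(sc)[1:25]
  sc[hot] <- rchisq(25, 1, ncp = 8)^0.25
  g <- chain_graph()
  members <- list(leaf = hot, mid = c(hot, names(sc)[26:55]),
                  root = names(sc)[1:150])
  coll <- make_collection(members, names(sc), min_size = 5)
  fit <- sumstat_enrich(sc, coll, g, fdr_perms = 25)
  r <- fit$results
  expect_s3_class(fit, "sumstat_enrichment")
  expect_true(r$reported[r$term_id == "leaf"])
  expect_false(is.na(r$p_drop_top[r$term_id == "leaf"]))
  # dropping one gene from a 25-gene planted set must not kill the signal
  expect_lt(r$p_drop_top[r$term_id == "leaf"], 0.01)
  expect_equal(r$fdr_bh[r$tested], bh_oracle(r$p_enrich[r$tested]))
  expect_output(print(fit), "SUMSTAT")
  expect_output(print(summary(fit)), "reported")
})
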