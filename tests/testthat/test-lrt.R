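test_that("reconciliation takes best runs, computes d, clamps negatives", {
  rec <- reconcile(make_runs(c(-103, -103, -103), c(-100.2, -100.25, -100.21)))
  expect_equal(rec$delta_lnl, 2.8)
  expect_equal(rec$d, 0.05)
  expect_false(rec$clamped)
  expect_equal(rec$lrt, 5.6)

  rec <- reconcile(make_runs(rep(-100, 3), rep(-100.5, 3)))
  expect_equal(rec$delta_lnl, 0)
  expect_true(rec$clamped)

  rec <- reconcile(make_runs(rep(-50, 3), rep(-50, 3)))
  expect_equal(rec$d, 0)
  expect_true(convergence_filter(rec, 1e-9)$converged)
})

test_that("reconciliation is invariant to run order and input row order", {
  set.seed(7)
  for (i in 1:10) {
    runs <- make_runs(rnorm(3, -1000), rnorm(3, -998))
    perm <- runs
    perm$lnl[1:3] <- runs$lnl[sample(1:3)]       # permute runs within null
    perm$lnl[4:6] <- runs$lnl[3 + sample(1:3)]   # ... and within alt
    perm <- perm[sample.int(6L), ]               # and shuffle row order
    expect_equal(reconcile(runs)[c("delta_lnl", "d", "clamped")],
                 reconcile(perm)[c("delta_lnl", "d", "clamped")])
  }
})

test_that("malformed replicate input is rejected with a pointed message", {
  runs <- make_runs(rep(-10, 3), rep(-9, 3))
  expect_error(reconcile(runs[-1, ]), "3 runs")
  runs$lnl[2] <- NA
  expect_error(reconcile(runs), "non-finite.*F1.*b1")
  runs2 <- make_runs(rep(-10, 3), rep(-9, 3))
  runs2$hypothesis[1] <- "alternative"
  expect_error(reconcile(runs2), "hypothesis")
})

test_that("convergence filter excludes d above cutoff, keeps the boundary", {
  rec <- rbind(reconcile(make_runs(c(-10, -10.05, -10), c(-9, -9, -9), "F1")),
               reconcile(make_runs(c(-10, -10.004, -10), c(-9, -9, -9), "F2")),
               reconcile(make_runs(rep(-10, 3), rep(-9, 3), "F3")))
  class(rec) <- c("test_records", "data.frame")
  out <- suppressMessages(convergence_filter(rec))
  expect_equal(out$converged, c(FALSE, TRUE, TRUE))
  expect_true(all(convergence_filter(rec, Inf)$converged))
})

test_that("chi-square p-values reproduce published test statistics", {
  # top branch-site and site-test families, printed to 2 significant figures
  expect_equal(signif(lrt_pvalue(16.1), 2), 1.4e-8)
  expect_equal(signif(lrt_pvalue(10.9), 2), 3.0e-6)
  expect_equal(signif(lrt_pvalue(8.3), 2), 4.6e-5)
  expect_equal(lrt_pvalue(0), 1)
  expect_error(lrt_pvalue(-0.1), "clamp")
})

test_that("p-value mapping matches the closed-form normal-tail oracle", {
  grid <- seq(0, 50, by = 0.37)
  oracle <- 2 * pnorm(-sqrt(2 * grid))  # chisq(1) survival in closed form
  expect_equal(lrt_pvalue(grid), oracle, tolerance = 1e-10)
  expect_true(all(diff(lrt_pvalue(seq(0, 30, 0.5))) < 0))
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_fdr(c(1e-4, 0.01, 0.03, 0.04)), c(4e-4, 0.02, 0.04, 0.04))
  expect_equal(bh_fdr(rep(0.07, 5)), rep(0.07, 5))
  expect_equal(bh_fdr(0.42), 0.42)
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  set.seed(11)
  for (i in 1:5) {
    p <- runif(200)^2
    expect_equal(bh_fdr(p), bh_oracle(p))
  }
})

test_that("processing conserves records and ties significance to convergence", {
  set.seed(5)
  runs <- do.call(rbind, lapply(1:40, function(i) {
    base <- -1000 - i
    blow <- if (i %% 7 == 0) 1 else 0
    make_runs(base - c(0, blow, 0), base + 2 + c(0, 0, 0),
              family = paste0("F", i))
  }))
  rec <- suppressMessages(process_tests(runs))
  expect_equal(sum(rec$converged) + sum(!rec$converged), nrow(rec))
  expect_true(all(rec$converged[rec$significant]))
  expect_true(all(is.na(rec$p[!rec$converged])))
  expect_equal(rec$p[rec$clamped & rec$converged],
               rep(1, sum(rec$clamped & rec$converged)))
})

test_that("realized false-discovery proportion respects the BH level", {
  # 20 replicates of a mixed series: 10% of tests truly selected
  set.seed(101)
  fdp <- replicate(20, {
    truth <- runif(3000) < 0.10
    lrt <- numeric(3000)
    lrt[truth] <- sample_lrt(sum(truth), pi0 = 0, noncentrality = 15)
    lrt[!truth] <- sample_lrt(sum(!truth), pi0 = 0.5)
    q <- bh_fdr(lrt_pvalue(lrt / 2))
    disc <- q <= 0.10
    if (any(disc)) sum(disc & !truth) / sum(disc) else 0
  })
  expect_lt(mean(fdp), 0.10 + 0.03)
})

test_that("tabulation separates branch-specific and lineage counts", {
  rec <- data.frame(
    family_id = c("F1", "F1", "F2", "F3", "F4"),
    branch_id = c("Sinv", "b1", "merged:b2", "Sinv", "b7"),
    significant = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  tab <- tabulate_selection(rec, lineages = list(
    ant = c("Sinv", "b1", "b2"), all = c("Sinv", "b1", "b2", "b7")))
  b <- tab$branches
  expect_equal(b$n_significant[b$branch == "Sinv"], 1L)
  expect_equal(b$n_significant[b$branch == "b1"], 1L)
  # merged branch not tabulated per branch, but counted in its lineage
  expect_false("merged:b2" %in% b$branch)
  expect_equal(tab$lineages$n_significant[tab$lineages$lineage == "ant"], 2L)
  expect_equal(tab$lineages$n_significant[tab$lineages$lineage == "all"], 3L)
  expect_equal(tab$n_families, 4L)

  rec$significant <- FALSE
  tab0 <- tabulate_selection(rec)
  expect_true(all(tab0$branches$fraction == 0))
  expect_error(tabulate_selection(rec, branch_labels = c("Sinv", "b1")),
               "unknown branch")
})

test_that("top-hit filtering applies branch, dS and BEB predicates", {
  rec <- data.frame(
    family_id = paste0("F", 1:4), branch_id = c("b1", "Sinv", "b2", "b3"),
    delta_lnl = c(5, 9, 7, 8), ds_foreground = c(0.2, 0.1, 1.4, 0.3),
    beb_max = c(0.95, 0.99, 0.95, 0.5), stringsAsFactors = FALSE)
  out <- top_hits(rec, internal_branches = c("b1", "b2", "b3"))
  expect_equal(out$family_id, "F1")  # F2 terminal, F3 dS>=1, F4 low BEB
  w <- capture_warnings(top_hits(rec[, 1:3], internal_branches = "b1"))
  expect_length(w, 2L)  # both optional criteria skipped
  expect_match(w, "skipped", all = TRUE)
})
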