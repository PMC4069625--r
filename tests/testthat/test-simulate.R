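test_that("LRT sampler reproduces the boundary mixture and noncentral moments", {
  n <- 1e5
  x <- sample_lrt(n, pi0 = 0.5, seed = 1)
  expect_lt(abs(mean(x == 0) - 0.5), 3 * sqrt(0.25 / n))

  x <- sample_lrt(n, pi0 = 0, seed = 2)
  expect_lt(abs(mean(x) - 1), 4 * sqrt(2 / n))  # chisq(1): mean 1, var 2

  # noncentral chisq(1, lambda): mean 1 + lambda, var 2(1 + 2 lambda)
  x <- sample_lrt(n, pi0 = 0, noncentrality = 5, seed = 3)
  expect_lt(abs(mean(x) - 6), 4 * sqrt(2 * 11 / n))
  expect_equal(sum(x == 0), 0L)

  expect_error(sample_lrt(10, pi0 = 1.3), "pi0")
  expect_error(sample_lrt(10, 0.5, noncentrality = -1), "noncentrality")
  expect_error(sample_lrt(0, 0.5), "n must be")
})

test_that("replicate-run emulator honours the noiseless and blow-up contracts", {
  runs <- synthesize_runs(4, -1000, jitter_sd = 0, blowup_prob = 0)
  expect_equal(runs$lnl[runs$hypothesis == "null"], rep(-1000, 3))
  expect_equal(runs$lnl[runs$hypothesis == "alt"], rep(-998, 3))
  rec <- reconcile(cbind(family_id = "F1", branch_id = "b1", runs))
  expect_equal(rec$delta_lnl, 2)
  expect_equal(rec$d, 0)

  runs <- synthesize_runs(4, -1000, jitter_sd = 0, blowup_prob = 1,
                          blowup_scale = 1, seed = 4)
  spread <- tapply(runs$lnl, runs$hypothesis, function(v) max(v) - min(v))
  expect_gt(max(spread), 0.004)  # flagged downstream
  expect_identical(synthesize_runs(4, -1000, 0.01, 0.5, 1, seed = 9),
                   synthesize_runs(4, -1000, 0.01, 0.5, 1, seed = 9))
  expect_error(synthesize_runs(4, -1000, jitter_sd = -1), "jitter_sd")
})

test_that("reconciled null LRTs follow the boundary mixture at scale", {
  n <- 1e5
  lrt <- sample_lrt(n, pi0 = 0.5, seed = 10)
  # noiseless triplicates around the sampled statistic, then reconcile
  runs <- data.frame(
    family_id = rep(sprintf("F%06d", seq_len(n)), each = 6L),
    branch_id = "b1",
    hypothesis = rep(rep(c("null", "alt"), each = 3L), n),
    run = rep(1:3, 2L * n),
    lnl = as.vector(rbind(matrix(-1000, 3, n),
                          matrix(rep(-1000 + lrt / 2, each = 3), 3, n))))
  rec <- reconcile(runs)
  mix_cdf <- function(q) 0.5 + 0.5 * pchisq(q, 1)
  grid <- c(0, seq(0.01, 12, length.out = 200))
  ecdf_v <- ecdf(rec$lrt)(grid)
  expect_lt(max(abs(ecdf_v - mix_cdf(grid))), 0.01)
})

test_that("configuration validation names the offending parameter", {
  expect_error(simulation_config(pi0 = -0.1), "pi0")
  expect_error(simulation_config(blowup_prob = 2), "blowup_prob")
  expect_error(simulation_config(n_families = 0), "n_families")
  expect_error(simulation_config(
    planted_terms = list(list(term = NULL, member_sel_fraction = 2,
                              noncentrality = 5))), "member_sel_fraction")
})

test_that("datasets are reproducible byte-for-byte under a fixed seed", {
  cfg <- simulation_config(n_families = 40, n_terms = 30, seed = 77)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1, d2)
  d3 <- simulate_dataset(simulation_config(n_families = 40, n_terms = 30,
                                           seed = 78))
  expect_false(identical(d1$replicate_runs, d3$replicate_runs))
})

test_that("every test has 3+3 runs and truth labels cover tests and terms", {
  d <- simulate_dataset(simulation_config(
    n_families = 60, n_terms = 30, seed = 5, sel_fraction = 0.1,
    planted_terms = list(list(term = NULL, member_sel_fraction = 0.4,
                              noncentrality = 8))))
  counts <- table(d$replicate_runs$family_id, d$replicate_runs$branch_id,
                  d$replicate_runs$hypothesis)
  expect_true(all(counts %in% c(0L, 3L)))
  tests <- unique(d$replicate_runs[c("family_id", "branch_id")])
  expect_equal(nrow(merge(tests, d$truth$tests)), nrow(tests))
  expect_equal(sort(d$truth$terms$term), sort(d$ontology$terms$id))
  expect_equal(sum(d$truth$terms$planted), 1L)
  planted_id <- d$truth$terms$term[d$truth$terms$planted]
  members <- unique(d$annotations$gene[d$annotations$term == planted_id])
  sel_fams <- unique(d$truth$tests$family_id[d$truth$tests$lambda == 8])
  expect_true(all(sel_fams %in% members))
  expect_equal(length(sel_fams), round(0.4 * length(members)))
})

test_that("without taxon loss every family tree is the species topology", {
  d <- simulate_dataset(simulation_config(n_families = 25, n_terms = 20,
                                          missing_taxon_prob = 0, seed = 6))
  expect_false(any(startsWith(d$replicate_runs$branch_id, "merged:")))
  expect_equal(length(unique(d$replicate_runs$branch_id)), 15L)
  expect_equal(length(unique(d$family_trees)), 1L)

  d2 <- simulate_dataset(simulation_config(n_families = 120, n_terms = 20,
                                           missing_taxon_prob = 0.25,
                                           seed = 7))
  expect_true(any(startsWith(d2$replicate_runs$branch_id, "merged:")))
})

test_that("planting leaves non-member families untouched (paired streams)", {
  base_cfg <- function(planted) simulation_config(
    n_families = 80, n_terms = 30, seed = 11, planted_terms = planted)
  d0 <- simulate_dataset(base_cfg(list()))
  d1 <- simulate_dataset(base_cfg(list(list(
    term = NULL, member_sel_fraction = 0.5, noncentrality = 10))))
  planted_id <- d1$truth$terms$term[d1$truth$terms$planted]
  members <- unique(d1$annotations$gene[d1$annotations$term == planted_id])
  r0 <- d0$replicate_runs[!d0$replicate_runs$family_id %in% members, ]
  r1 <- d1$replicate_runs[!d1$replicate_runs$family_id %in% members, ]
  expect_identical(r0, r1)
  # and the planted members' scores are stochastically larger
  s0 <- mean(d0$replicate_runs$lnl[d0$replicate_runs$family_id %in% members &
                                   d0$replicate_runs$hypothesis == "alt"])
  s1 <- mean(d1$replicate_runs$lnl[d1$replicate_runs$family_id %in% members &
                                   d1$replicate_runs$hypothesis == "alt"])
  expect_gt(s1, s0)
})

test_that("a too-shallow term budget degrades the DAG with a warning", {
  expect_warning(simulate_dataset(simulation_config(
    n_families = 10, n_terms = 3, dag_depth = 5, seed = 1)), "shallower")
})
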