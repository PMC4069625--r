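## Synthetic data with the statistical structure the analysis assumes:
## chi-square-mixture null LRTs, noncentral alternatives for planted
## positively selected families, triplicate-run likelihood jitter with a
## rare large-discrepancy mode, per-family trees with missing taxa, and a
## layered random ontology with planted enriched terms.

#' Simulation configuration
#'
#' Houses the free parameters of the generator. The null LRT is the
#' boundary mixture `pi0 * delta_0 + (1 - pi0) * chisq(1)` (default
#' `pi0 = 0.5`, the standard result for a one-parameter boundary
#' constraint); true positives draw from a noncentral chisq(1) with
#' noncentrality `noncentrality`. Replicate log-likelihoods jitter below
#' the optimum with sd `jitter_sd`, and with probability `blowup_prob` one
#' run of one hypothesis is depressed by about `blowup_scale` nats,
#' recreating the minor mode of the run-discrepancy distribution near 1.
#'
#' @param n_families number of single-copy gene families.
#' @param branch_labels tested branch labels (default: the 15 branches of
#'   [ant_branch_labels()]: 7 terminal ant branches + b1-b8).
#' @param pi0 probability that a null LRT is exactly 0.
#' @param sel_fraction fraction of family x branch tests under positive
#'   selection in the background (outside planted terms).
#' @param noncentrality noncentrality of the alternative LRT distribution.
#' @param jitter_sd sd (nats) of the small run-to-run likelihood jitter.
#' @param blowup_prob,blowup_scale probability and magnitude (nats) of the
#'   rare large-discrepancy mode.
#' @param missing_taxon_prob per-family, per-ant-species gene-loss
#'   probability (outgroups always present).
#' @param n_terms,n_genes_per_term,dag_depth ontology shape: total terms,
#'   genes annotated per leaf term, layers below the root.
#' @param planted_terms list of lists with elements `term` (id, or `NULL`
#'   to auto-assign leaf terms), `member_sel_fraction`, `noncentrality`.
#' @param seed integer random seed; a fixed seed makes the whole dataset
#'   reproducible.
#' @return object of class `sim_config`.
#' @export
simulation_config <- function(n_families = 1000L,
                              branch_labels = ant_branch_labels("tested"),
                              pi0 = 0.5,
                              sel_fraction = 0.05,
                              noncentrality = 5,
                              jitter_sd = 1e-4,
                              blowup_prob = 0.02,
                              blowup_scale = 1,
                              missing_taxon_prob = 0.05,
                              n_terms = 150L,
                              n_genes_per_term = 25L,
                              dag_depth = 4L,
                              planted_terms = list(),
                              seed = 1L) {
  chk_prob <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
      stop(nm, " must be a probability in [0, 1]")
  }
  chk_prob(pi0, "pi0"); chk_prob(sel_fraction, "sel_fraction")
  chk_prob(blowup_prob, "blowup_prob")
  chk_prob(missing_taxon_prob, "missing_taxon_prob")
  if (n_families < 1L) stop("n_families must be >= 1")
  if (noncentrality < 0) stop("noncentrality must be >= 0")
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  for (pt in planted_terms) {
    chk_prob(pt$member_sel_fraction, "member_sel_fraction")
    if (is.null(pt$noncentrality) || pt$noncentrality < 0)
      stop("planted term noncentrality must be >= 0")
  }
  structure(list(n_families = as.integer(n_families),
                 branch_labels = branch_labels, pi0 = pi0,
                 sel_fraction = sel_fraction, noncentrality = noncentrality,
                 jitter_sd = jitter_sd, blowup_prob = blowup_prob,
                 blowup_scale = blowup_scale,
                 missing_taxon_prob = missing_taxon_prob,
                 n_terms = as.integer(n_terms),
                 n_genes_per_term = as.integer(n_genes_per_term),
                 dag_depth = as.integer(dag_depth),
                 planted_terms = planted_terms, seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config: ", x$n_families, " families x ",
      length(x$branch_labels), " branches, pi0 = ", x$pi0,
      ", sel_fraction = ", x$sel_fraction, ", seed = ", x$seed, "\n",
      sep = "")
  if (length(x$planted_terms))
    cat("  ", length(x$planted_terms), " planted enriched term(s)\n", sep = "")
  invisible(x)
}

#' Sample likelihood-ratio test statistics
#'
#' Null draws come from the boundary mixture `pi0 * delta_0 +
#' (1 - pi0) * chisq(1)`; with `noncentrality > 0` draws come from the
#' noncentral chisq(1) alternative instead (no point mass).
#'
#' @param n number of draws.
#' @param pi0 point mass at 0 under the null.
#' @param noncentrality noncentrality parameter lambda (0 = null).
#' @param seed optional seed set before drawing.
#' @return numeric vector of `n` values on the 2*delta_lnl scale.
#' @export
sample_lrt <- function(n, pi0, noncentrality = 0, seed = NULL) {
  if (n < 1L) stop("n must be >= 1")
  if (!is.numeric(pi0) || length(pi0) != 1L || is.na(pi0) || pi0 < 0 || pi0 > 1)
    stop("pi0 must be a probability in [0, 1]")
  if (noncentrality < 0) stop("noncentrality must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (noncentrality > 0) return(rchisq(n, df = 1, ncp = noncentrality))
  x <- rchisq(n, df = 1)
  x[runif(n) < pi0] <- 0
  x
}

## truncated-at-zero normal draw
rtnorm_pos <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  for (i in seq_len(20L)) {
    neg <- x < 0
    if (!any(neg)) break
    x[neg] <- rnorm(sum(neg), mean, sd)
  }
  pmax(x, 0)
}

#' Emulate triplicate likelihood optimisations for one test
#'
#' Emits three null and three alternative log-likelihoods whose best-run
#' difference equals `true_lrt / 2` up to jitter: each run falls short of
#' its hypothesis optimum by `|N(0, jitter_sd)|` nats. With probability
#' `blowup_prob`, one run of one randomly chosen hypothesis is depressed
#' by a Normal(`blowup_scale`, `blowup_scale/10`) amount truncated at 0 —
#' the convergence failure mode the d-filter is designed to catch.
#'
#' @param true_lrt true test statistic (2*delta_lnl scale).
#' @param base_lnl null-hypothesis optimum log-likelihood.
#' @param jitter_sd,blowup_prob,blowup_scale see [simulation_config()].
#' @param seed optional seed.
#' @return data frame with columns `hypothesis`, `run`, `lnl` (6 rows).
#' @export
synthesize_runs <- function(true_lrt, base_lnl, jitter_sd = 0,
                            blowup_prob = 0, blowup_scale = 1, seed = NULL) {
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  if (blowup_prob < 0 || blowup_prob > 1)
    stop("blowup_prob must be a probability in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  target <- c(rep(base_lnl, 3L), rep(base_lnl + true_lrt / 2, 3L))
  lnl <- target - abs(rnorm(6L, 0, jitter_sd))
  if (runif(1L) < blowup_prob) {
    slot <- sample.int(6L, 1L)  # one run of one hypothesis
    lnl[slot] <- lnl[slot] - rtnorm_pos(1L, blowup_scale, blowup_scale / 10)
  }
  data.frame(hypothesis = rep(c("null", "alt"), each = 3L),
             run = rep(1:3, 2L), lnl = lnl, stringsAsFactors = FALSE)
}

#' Generate a layered random ontology DAG
#'
#' One root plus `dag_depth` layers; every non-root term gets 1-2 parents
#' in the layer above, giving a DAG with diamond motifs like real
#' ontologies. Uses the current RNG stream.
#'
#' @param n_terms total number of terms including the root.
#' @param dag_depth layers below the root; shallower (with a warning) when
#'   `n_terms` is too small.
#' @param namespace namespace string for all terms.
#' @return [ontology_graph()] object.
#' @export
generate_ontology <- function(n_terms, dag_depth, namespace = "biological_process") {
  if (n_terms < 2L) stop("n_terms must be >= 2")
  n_rest <- n_terms - 1L
  depth_eff <- dag_depth
  if (n_rest < dag_depth) {
    warning("too few terms for requested depth; DAG will be shallower")
    depth_eff <- n_rest
  }
  per_layer <- rep(n_rest %/% depth_eff, depth_eff)
  if (n_rest %% depth_eff)
    per_layer[depth_eff] <- per_layer[depth_eff] + n_rest %% depth_eff
  ids <- sprintf("T%04d", seq_len(n_terms) - 1L)  # T0000 = root
  layers <- split(ids[-1L], rep(seq_len(depth_eff), per_layer))
  edges <- list()
  above <- ids[1L]
  for (k in seq_len(depth_eff)) {
    for (t in layers[[k]]) {
      n_par <- if (length(above) > 1L) sample(1:2, 1L) else 1L
      par <- if (length(above) == 1L) above else sample(above, n_par)
      edges[[length(edges) + 1L]] <- data.frame(child = t, parent = par,
                                                stringsAsFactors = FALSE)
    }
    above <- layers[[k]]
  }
  terms <- data.frame(id = ids,
                      name = c("root", paste("term", seq_len(n_rest))),
                      namespace = namespace, stringsAsFactors = FALSE)
  ontology_graph(terms, do.call(rbind, edges))
}

#' Serialise an ontology graph as OBO-subset text
#'
#' @param graph [ontology_graph()].
#' @return character vector of OBO lines.
#' @export
obo_text <- function(graph) {
  out <- c("format-version: 1.2", "")
  for (i in seq_len(nrow(graph$terms))) {
    id <- graph$terms$id[i]
    par <- graph$parents[[id]]
    out <- c(out, "[Term]",
             paste0("id: ", id),
             paste0("name: ", graph$terms$name[i]),
             paste0("namespace: ", graph$terms$namespace[i]),
             if (length(par)) paste0("is_a: ", par),
             "")
  }
  out
}

per_family_seed <- function(seed, i) {
  (as.double(seed) + 100003 * as.double(i)) %% 2147483629
}

#' Generate a complete synthetic dataset with ground truth
#'
#' Composes the LRT samplers, replicate-run emulator, per-family trees
#' with missing taxa, and a layered random ontology with planted enriched
#' terms. Planted terms have `member_sel_fraction` of their member
#' families drawn under positive selection (noncentral chisq(1) LRTs on
#' every tested branch), making the members' lineage scores stochastically
#' larger than background while non-member families are untouched:
#' randomness is drawn from deterministic per-family sub-streams, so a
#' background family's data is identical with and without planting.
#'
#' @param config [simulation_config()].
#' @return object of class `sim_dataset`: list with `replicate_runs`
#'   (data frame `family_id`, `branch_id`, `hypothesis`, `run`, `lnl`),
#'   `family_trees` (named character vector of newick strings),
#'   `annotations` (`gene`, `term`), `ontology` ([ontology_graph()]),
#'   `obo` (OBO text lines), `truth` (list: `tests` with per-test
#'   selection labels, `terms` with per-term planting labels), `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sptree <- ant_species_tree()
  ants <- ant_branch_labels("terminal_ant")
  outgroups <- setdiff(sptree$tip.label, ants)
  fam_ids <- sprintf("F%05d", seq_len(config$n_families))

  ## --- ontology + annotations (global stream; independent of planting) ---
  graph <- generate_ontology(config$n_terms, config$dag_depth)
  has_children <- vapply(graph$children, length, 0L) > 0L
  leaves <- sort(graph$terms$id[!has_children[graph$terms$id]])
  ann <- lapply(leaves, function(t)
    data.frame(gene = sample(fam_ids, min(config$n_genes_per_term,
                                          config$n_families)),
               term = t, stringsAsFactors = FALSE))
  annotations <- do.call(rbind, ann)

  ## --- plant enriched terms (own sub-streams) ---
  planted <- config$planted_terms
  term_truth <- data.frame(term = graph$terms$id, planted = FALSE,
                           member_sel_fraction = 0, noncentrality = 0,
                           stringsAsFactors = FALSE)
  fam_lambda <- setNames(rep(NA_real_, config$n_families), fam_ids)
  if (length(planted)) {
    auto <- leaves[!leaves %in% vapply(planted, function(p)
      if (is.null(p$term)) "" else p$term, "")]
    ai <- 1L
    for (j in seq_along(planted)) {
      pt <- planted[[j]]
      term <- pt$term
      if (is.null(term)) { term <- auto[ai]; ai <- ai + 1L }
      if (!term %in% graph$terms$id) stop("planted term not in ontology: ", term)
      members <- unique(annotations$gene[annotations$term == term])
      set.seed(per_family_seed(config$seed, 7000000 + j))
      k <- round(pt$member_sel_fraction * length(members))
      sel_members <- if (k > 0L) sample(members, k) else character(0)
      fam_lambda[sel_members] <- pt$noncentrality
      i <- match(term, term_truth$term)
      term_truth$planted[i] <- TRUE
      term_truth$member_sel_fraction[i] <- pt$member_sel_fraction
      term_truth$noncentrality[i] <- pt$noncentrality
    }
  }

  ## --- branch-label cache per missing-taxon pattern ---
  label_cache <- new.env(parent = emptyenv())
  labels_for <- function(present_ants) {
    key <- paste(present_ants, collapse = ",")
    hit <- label_cache[[key]]
    if (!is.null(hit)) return(hit)
    keep <- c(present_ants, outgroups)
    fam_tree <- ape::keep.tip(sptree, keep)
    mp <- map_branches(fam_tree, sptree)
    cont <- merged_container(mp$label)
    tested <- mp$label[mp$label %in% config$branch_labels |
                       (!is.na(cont) & cont %in% config$branch_labels)]
    res <- list(newick = ape::write.tree(fam_tree), tested = tested)
    label_cache[[key]] <- res
    res
  }

  ## --- per-family replicate runs (per-family sub-streams) ---
  runs_fam <- vector("list", config$n_families)
  truth_fam <- vector("list", config$n_families)
  trees <- character(config$n_families)
  for (i in seq_len(config$n_families)) {
    set.seed(per_family_seed(config$seed, i))
    miss <- runif(length(ants)) < config$missing_taxon_prob
    present <- if (sum(!miss) < 2L) ants else ants[!miss]
    lf <- labels_for(present)
    trees[i] <- lf$newick
    branches <- lf$tested
    nb <- length(branches)
    base_lnl <- round(-1500 + rnorm(1L, 0, 200), 4)

    lam <- fam_lambda[[i]]
    if (!is.na(lam)) {
      sel <- rep(TRUE, nb)
      lrt <- rchisq(nb, 1, ncp = lam)
      lambda <- rep(lam, nb)
    } else {
      sel <- runif(nb) < config$sel_fraction & config$noncentrality > 0
      lrt <- numeric(nb)
      lrt[sel] <- rchisq(sum(sel), 1, ncp = config$noncentrality)
      lrt[!sel] <- sample_lrt(max(sum(!sel), 1L), config$pi0)[seq_len(sum(!sel))]
      lambda <- ifelse(sel, config$noncentrality, 0)
    }

    target <- rbind(matrix(base_lnl, 3L, nb),
                    matrix(rep(base_lnl + lrt / 2, each = 3L), 3L, nb))
    lnl <- target - abs(matrix(rnorm(6L * nb, 0, config$jitter_sd), 6L, nb))
    blow <- runif(nb) < config$blowup_prob
    if (any(blow)) {
      for (b in which(blow)) {
        slot <- sample.int(6L, 1L)
        lnl[slot, b] <- lnl[slot, b] -
          rtnorm_pos(1L, config$blowup_scale, config$blowup_scale / 10)
      }
    }
    ## column-wise flatten: per branch, rows 1-3 are null runs, 4-6 alt runs
    runs_fam[[i]] <- data.frame(
      family_id = fam_ids[i],
      branch_id = rep(branches, each = 6L),
      hypothesis = rep(rep(c("null", "alt"), each = 3L), nb),
      run = rep(1:3, 2L * nb),
      lnl = as.vector(lnl),
      stringsAsFactors = FALSE)
    truth_fam[[i]] <- data.frame(family_id = fam_ids[i], branch_id = branches,
                                 selected = sel, lambda = lambda,
                                 stringsAsFactors = FALSE)
  }
  replicate_runs <- do.call(rbind, runs_fam)
  rownames(replicate_runs) <- NULL

  structure(list(replicate_runs = replicate_runs,
                 family_trees = setNames(trees, fam_ids),
                 annotations = annotations,
                 ontology = graph,
                 obo = obo_text(graph),
                 truth = list(tests = do.call(rbind, truth_fam),
                              terms = term_truth),
                 config = config),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Synthetic branch-site scan dataset\n")
  cat("  ", x$config$n_families, " families, ",
      nrow(x$replicate_runs) / 6L, " tests (x6 replicate runs)\n", sep = "")
  cat("  ontology: ", nrow(x$ontology$terms), " terms; annotations: ",
      nrow(x$annotations), " gene-term pairs; ",
      sum(x$truth$terms$planted), " planted term(s)\n", sep = "")
  invisible(x)
}
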