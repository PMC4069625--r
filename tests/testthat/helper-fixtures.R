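# Shared fixtures: all built in code, no files.

make_runs <- function(lnl_null, lnl_alt, family = "F1", branch = "b1") {
  data.frame(family_id = family, branch_id = branch,
             hypothesis = rep(c("null", "alt"), each = 3L),
             run = rep(1:3, 2L),
             lnl = c(lnl_null, lnl_alt),
             stringsAsFactors = FALSE)
}

# leaf -> mid -> root chain
chain_graph <- function() {
  ontology_graph(
    data.frame(id = c("root", "mid", "leaf"), name = c("r", "m", "l"),
               namespace = "bp", stringsAsFactors = FALSE),
    data.frame(child = c("leaf", "mid"), parent = c("mid", "root"),
               stringsAsFactors = FALSE))
}

# diamond: leaf reaches root via two mid nodes
diamond_graph <- function() {
  ontology_graph(
    data.frame(id = c("root", "m1", "m2", "leaf"),
               name = c("r", "m1", "m2", "l"), namespace = "bp",
               stringsAsFactors = FALSE),
    data.frame(child = c("leaf", "leaf", "m1", "m2"),
               parent = c("m1", "m2", "root", "root"),
               stringsAsFactors = FALSE))
}

# independent step-up BH oracle (direct from the definition)
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# exhaustive hypergeometric two-sided Fisher oracle
fisher_oracle <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  k <- a + c          # col 1 total
  n <- a + b + c + d
  lo <- max(0L, k - (n - m)); hi <- min(k, m)
  x <- lo:hi
  pr <- dhyper(x, m, n - m, k)
  sum(pr[pr <= pr[x == a] * (1 + 1e-7)])
}

# collection from explicit member lists
make_collection <- function(members, background, min_size = 1L) {
  structure(list(members = members, background = background,
                 min_size = as.integer(min_size)),
            class = "gene_set_collection")
}

skewed_scores <- function(n, seed = 42) {
  set.seed(seed)
  setNames(rchisq(n, df = 1)^0.25, sprintf("G%05d", seq_len(n)))
}
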