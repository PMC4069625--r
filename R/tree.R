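## Newick utilities: canonical-branch mapping for gene trees with missing
## taxa, bootstrap-guided partitioning of oversized trees, and per-branch
## GC3 shifts.

#' Default hymenopteran species tree and tested branches
#'
#' A rooted 10-species topology used by the synthetic-data generator:
#' seven ant species (Acep, Aech, Sinv, Pbar, Cflo, Lhum, Hsal) and three
#' outgroups (Amel, Nvit, Dmel). Internal node labels name the branch
#' subtending that node: `b1` (Attini) through `b6` (Formicidae) are the
#' internal ant branches, `b7` (Aculeata) and `b8` (Hymenoptera/Apocrita)
#' the basal hymenopteran branches. The 15 tested branches are the 7
#' terminal ant branches plus `b1`-`b8`; the 13 ant-lineage branches drop
#' `b7` and `b8`.
#'
#' @return `ape::phylo` object with node labels.
#' @export
ant_species_tree <- function() {
  ape::read.tree(text = paste0(
    "(((((((((Acep,Aech)b1,Sinv)b2,Pbar)b3,Cflo)b4,Lhum)b5,Hsal)b6,",
    "Amel)b7,Nvit)b8,Dmel)root;"))
}

#' @rdname ant_species_tree
#' @param lineage `"tested"` (all 15), `"ant"` (the 13 ant branches) or
#'   `"terminal_ant"` (7 species branches).
#' @export
ant_branch_labels <- function(lineage = c("tested", "ant", "terminal_ant")) {
  lineage <- match.arg(lineage)
  ants <- c("Acep", "Aech", "Sinv", "Pbar", "Cflo", "Lhum", "Hsal")
  switch(lineage,
         tested = c(ants, paste0("b", 1:8)),
         ant = c(ants, paste0("b", 1:6)),
         terminal_ant = ants)
}

## tip set below each non-root node, as a list indexed by node number
node_clades <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  clades <- vector("list", n_all)
  for (i in seq_len(n_tip)) clades[[i]] <- tree$tip.label[i]
  edge <- ape::reorder.phylo(tree, "postorder")$edge  # children before parents
  for (k in seq_len(nrow(edge)))
    clades[[edge[k, 1L]]] <- c(clades[[edge[k, 1L]]], clades[[edge[k, 2L]]])
  lapply(clades, sort)
}

## label of the branch above each non-root node: tip label for tips,
## node label for internal nodes
branch_labels_by_node <- function(tree) {
  n_tip <- length(tree$tip.label)
  lab <- c(tree$tip.label,
           if (is.null(tree$node.label)) rep(NA_character_, tree$Nnode)
           else tree$node.label)
  lab[lab == ""] <- NA_character_
  lab
}

#' Map gene-family tree branches to canonical species-tree branches
#'
#' In a single-copy gene family with missing taxa, pruning collapses
#' species-tree branches: a family branch spanning two or more canonical
#' branches no longer corresponds to any single branch of the species
#' topology. Each non-root family branch is labelled with its canonical
#' branch when its leaf bipartition matches exactly one species branch
#' (restricted to the species present), and `"merged:<b>"` otherwise,
#' where `<b>` is the branch subtending the smallest canonical clade
#' containing the merged branch.
#'
#' @param family_tree rooted `phylo`; tip labels are species ids (one gene
#'   per species).
#' @param species_tree rooted `phylo` with node labels naming internal
#'   branches (see [ant_species_tree()]).
#' @return data frame with one row per non-root family branch: `node`
#'   (family-tree node number below the branch), `label`, `type`
#'   (`"canonical"` or `"merged"`).
#' @export
map_branches <- function(family_tree, species_tree) {
  if (anyDuplicated(family_tree$tip.label))
    stop("duplicate species in family tree: single-copy contract violated")
  absent <- setdiff(family_tree$tip.label, species_tree$tip.label)
  if (length(absent))
    stop("family tip(s) not in species tree: ", paste(absent, collapse = ", "))
  present <- family_tree$tip.label

  sp_clades <- node_clades(species_tree)
  sp_labels <- branch_labels_by_node(species_tree)
  sp_root <- length(species_tree$tip.label) + 1L
  sp_nodes <- setdiff(seq_along(sp_clades), sp_root)
  restricted <- lapply(sp_clades, function(cl) intersect(cl, present))

  fam_clades <- node_clades(family_tree)
  fam_root <- length(family_tree$tip.label) + 1L
  fam_nodes <- setdiff(seq_along(fam_clades), fam_root)

  rows <- lapply(fam_nodes, function(nd) {
    C <- fam_clades[[nd]]
    cand <- sp_nodes[vapply(sp_nodes, function(s)
      length(restricted[[s]]) == length(C) && all(restricted[[s]] == C),
      TRUE)]
    if (!length(cand))
      return(data.frame(node = nd, label = "unmapped", type = "unmapped",
                        stringsAsFactors = FALSE))
    if (length(cand) == 1L)
      return(data.frame(node = nd, label = sp_labels[cand], type = "canonical",
                        stringsAsFactors = FALSE))
    # chain of elided branches: container = topmost (largest full clade)
    top <- cand[which.max(vapply(cand, function(s) length(sp_clades[[s]]), 0L))]
    data.frame(node = nd, label = paste0("merged:", sp_labels[top]),
               type = "merged", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Split an oversized tree into subtrees at well-supported branches
#'
#' Codon-model tests become impractical on very large gene trees (e.g. a
#' multigene receptor family), so the tree is partitioned into subtrees
#' each smaller than `max_leaves`. While any component has `>= max_leaves`
#' leaves, the internal branch cut is the one that (i) leaves both sides
#' with at least `min_component` leaves and (ii) has maximal bootstrap
#' support (missing support counts as 0); ties are broken by the most
#' balanced split, then by the lexicographically smallest tip label of
#' the clade. If no branch satisfies the size floor the component is
#' returned as is, with a warning.
#'
#' @param tree rooted `phylo` with bootstrap values (0-100) as internal
#'   node labels.
#' @param max_leaves components must end up strictly below this size
#'   (default 100).
#' @param min_component minimum leaves on each side of a cut (default 5).
#' @return list of `phylo` objects whose tip sets partition the input tips.
#' @export
split_tree <- function(tree, max_leaves = 100L, min_component = 5L) {
  if (max_leaves < 2L * min_component)
    stop("max_leaves must be at least 2 * min_component")
  n_tip <- length(tree$tip.label)
  if (n_tip < max_leaves) return(list(tree))

  clades <- node_clades(tree)
  root <- n_tip + 1L
  boot <- suppressWarnings(as.numeric(branch_labels_by_node(tree)))
  boot[is.na(boot)] <- 0
  internal <- setdiff((n_tip + 1L):(n_tip + tree$Nnode), root)

  sizes <- vapply(clades, length, 0L)
  ok <- internal[sizes[internal] >= min_component &
                 (n_tip - sizes[internal]) >= min_component]
  if (!length(ok)) {
    warning("no admissible cut found for a component of ", n_tip,
            " leaves; returned unsplit")
    return(list(tree))
  }
  balance <- abs(2L * sizes[ok] - n_tip)
  first_tip <- vapply(ok, function(nd) clades[[nd]][1L], "")
  best <- ok[order(-boot[ok], balance, first_tip)][1L]

  part1 <- ape::extract.clade(tree, best)
  part2 <- ape::drop.tip(tree, clades[[best]])
  c(split_tree(part1, max_leaves, min_component),
    split_tree(part2, max_leaves, min_component))
}

#' Per-branch shift in GC content at third codon positions
#'
#' Given ancestral and terminal GC3 estimates at every node, the shift on
#' a branch is the difference between the GC3 at the two nodes delimiting
#' it: `GC3(child) - GC3(parent)`. Shifts telescope along paths: their sum
#' from root to a leaf equals `GC3(leaf) - GC3(root)`.
#'
#' @param tree rooted `phylo` with unique tip and node labels.
#' @param gc3 named numeric vector of GC3 fractions in [0, 1], named by
#'   tip/node labels. Branches missing a value at either end are skipped
#'   with a warning.
#' @return data frame: `parent`, `child` (labels), `shift`.
#' @export
gc3_shifts <- function(tree, gc3) {
  labels <- branch_labels_by_node(tree)
  root <- length(tree$tip.label) + 1L
  n_all <- length(tree$tip.label) + tree$Nnode
  # root has no branch above it, but its label is still a GC3 lookup key
  labels[root] <- if (is.null(tree$node.label)) NA_character_
                  else tree$node.label[1L]
  val <- gc3[labels]
  if (any(!is.na(val) & (val < 0 | val > 1)))
    stop("GC3 values must lie in [0, 1]")
  rows <- apply(tree$edge, 1L, function(e) {
    p <- labels[e[1L]]; ch <- labels[e[2L]]
    vp <- if (is.na(p)) NA_real_ else unname(gc3[p])
    vc <- if (is.na(ch)) NA_real_ else unname(gc3[ch])
    data.frame(parent = p, child = ch, shift = vc - vp,
               stringsAsFactors = FALSE)
  }, simplify = FALSE)
  out <- do.call(rbind, rows)
  if (anyNA(out$shift)) {
    warning(sum(is.na(out$shift)), " branch(es) skipped: missing GC3 at an endpoint")
    out <- out[!is.na(out$shift), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
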