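## Ontology DAG handling: OBO-subset parsing, annotation propagation,
## size-filtered testable gene sets, and the deepest-first order used by
## the elim decorrelation.

#' Construct an ontology graph
#'
#' Terms form a directed acyclic graph with child-to-parent edges (`is_a`
#' and, optionally, `part_of`). Term depth is the longest path from the
#' namespace root, so a term is always deeper than every one of its
#' ancestors — the property the elim procedure relies on to process a term
#' before all terms it can strip genes from.
#'
#' @param terms data frame with columns `id`, `name`, `namespace`.
#' @param edges data frame with columns `child`, `parent` (term ids).
#' @return object of class `ontology_graph` with elements `terms`,
#'   `parents` (named list), `children` (named list), `depth` (named
#'   integer, root = 0).
#' @export
ontology_graph <- function(terms, edges) {
  stopifnot(all(c("id", "name", "namespace") %in% names(terms)))
  ids <- terms$id
  if (anyDuplicated(ids)) stop("duplicated term ids")
  if (nrow(edges)) {
    unknown <- setdiff(c(edges$child, edges$parent), ids)
    if (length(unknown))
      stop("edge references unknown term(s): ", paste(unknown, collapse = ", "))
  }
  parents <- split(edges$parent, factor(edges$child, levels = ids))
  parents <- lapply(parents, unique)
  children <- split(edges$child, factor(edges$parent, levels = ids))
  children <- lapply(children, unique)

  # Kahn topological order (parents first) + cycle detection
  n_par <- vapply(parents, length, 0L)
  queue <- ids[n_par == 0L]
  topo <- character(0)
  remaining <- n_par
  while (length(queue)) {
    t <- queue[1L]; queue <- queue[-1L]
    topo <- c(topo, t)
    for (ch in children[[t]]) {
      remaining[ch] <- remaining[ch] - 1L
      if (remaining[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(topo) != length(ids)) {
    left <- setdiff(ids, topo)
    bad <- left[1L]
    stop(sprintf("cycle detected in ontology graph (e.g. involving edge %s -> %s)",
                 bad, parents[[bad]][1L]))
  }

  depth <- setNames(integer(length(ids)), ids)
  for (t in topo) {
    p <- parents[[t]]
    depth[t] <- if (length(p)) 1L + max(depth[p]) else 0L
  }

  structure(list(terms = terms, parents = parents, children = children,
                 depth = depth, topo = topo),
            class = "ontology_graph")
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("Ontology graph: ", nrow(x$terms), " terms, ",
      sum(vapply(x$parents, length, 0L)), " edges, max depth ",
      max(x$depth), "\n", sep = "")
  cat("  namespaces: ", paste(unique(x$terms$namespace), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Parse an OBO-format ontology subset
#'
#' Reads `[Term]` stanzas and the tags `id`, `name`, `namespace`, `is_a`,
#' `relationship: part_of` and `is_obsolete`. Obsolete terms are skipped
#' with a warning. Other stanza types and tags are ignored.
#'
#' @param path OBO file.
#' @param relations edge types to keep as child-to-parent edges.
#' @return [ontology_graph()] object.
#' @export
read_obo <- function(path, relations = c("is_a", "part_of")) {
  lines <- readLines(path, warn = FALSE)
  in_term <- FALSE
  cur <- NULL
  terms <- list()
  flush <- function(cur, terms) {
    if (!is.null(cur) && !is.null(cur$id)) terms[[length(terms) + 1L]] <- cur
    terms
  }
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)          # strip OBO comments
    ln <- trimws(ln)
    if (ln == "") next
    if (startsWith(ln, "[")) {
      terms <- flush(cur, terms)
      in_term <- identical(ln, "[Term]")
      cur <- if (in_term) list(is_a = character(0), part_of = character(0))
      next
    }
    if (!in_term) next
    kv <- regmatches(ln, regexpr(":", ln, fixed = TRUE), invert = TRUE)[[1L]]
    if (length(kv) != 2L) next
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "is_a") cur$is_a <- c(cur$is_a, strsplit(val, "\\s+")[[1L]][1L])
    else if (key == "is_obsolete" && tolower(val) == "true") cur$obsolete <- TRUE
    else if (key == "relationship") {
      parts <- strsplit(val, "\\s+")[[1L]]
      if (length(parts) >= 2L && parts[1L] == "part_of")
        cur$part_of <- c(cur$part_of, parts[2L])
    }
  }
  terms <- flush(cur, terms)

  obsolete <- vapply(terms, function(t) isTRUE(t$obsolete), TRUE)
  if (any(obsolete)) {
    warning(sum(obsolete), " obsolete term(s) skipped")
    terms <- terms[!obsolete]
  }
  if (!length(terms)) stop("no [Term] stanzas found in ", path)

  term_df <- data.frame(
    id = vapply(terms, function(t) t$id, ""),
    name = vapply(terms, function(t) if (is.null(t$name)) "" else t$name, ""),
    namespace = vapply(terms, function(t)
      if (is.null(t$namespace)) "default" else t$namespace, ""),
    stringsAsFactors = FALSE
  )
  edge_list <- lapply(terms, function(t) {
    par <- character(0)
    if ("is_a" %in% relations) par <- c(par, t$is_a)
    if ("part_of" %in% relations) par <- c(par, t$part_of)
    if (length(par)) data.frame(child = t$id, parent = par,
                                stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, edge_list)
  if (is.null(edges))
    edges <- data.frame(child = character(0), parent = character(0))
  # drop edges to terms not present in the subset (dangling references)
  keep <- edges$parent %in% term_df$id
  if (any(!keep))
    warning(sum(!keep), " edge(s) to terms outside the subset dropped")
  ontology_graph(term_df, edges[keep, , drop = FALSE])
}

#' All ancestors of a term
#'
#' @param graph [ontology_graph()].
#' @param id term id.
#' @return character vector of ancestor ids (excluding `id` itself).
#' @export
term_ancestors <- function(graph, id) {
  if (!id %in% names(graph$parents)) stop("unknown term: ", id)
  out <- character(0)
  frontier <- graph$parents[[id]]
  while (length(frontier)) {
    out <- union(out, frontier)
    frontier <- setdiff(unique(unlist(graph$parents[frontier], use.names = FALSE)),
                        out)
  }
  out
}

#' Propagate gene annotations up the ontology
#'
#' Annotation of child terms is propagated to all their ancestors: a gene
#' annotated to a term becomes a member of every ancestor of that term.
#' Membership is a set (a gene reached through several paths counts once);
#' the operation is idempotent.
#'
#' @param graph [ontology_graph()].
#' @param annotations data frame with columns `gene`, `term`.
#' @return object of class `gene_set_collection`: list with `members`
#'   (named list term -> sorted gene ids; terms with no genes omitted),
#'   `background` (`NULL` until [filter_sets()]), `min_size` (`NULL`).
#' @export
propagate <- function(graph, annotations) {
  stopifnot(all(c("gene", "term") %in% names(annotations)))
  known <- annotations$term %in% graph$terms$id
  if (any(!known)) {
    warning(sum(!known), " association(s) to unknown term(s) skipped: ",
            paste(unique(annotations$term[!known]), collapse = ", "))
    annotations <- annotations[known, , drop = FALSE]
  }
  members <- lapply(split(annotations$gene, annotations$term), unique)
  # children before parents: reverse topological order
  for (t in rev(graph$topo)) {
    g <- members[[t]]
    if (is.null(g)) next
    for (p in graph$parents[[t]])
      members[[p]] <- union(members[[p]], g)
  }
  members <- lapply(members, function(g) sort(g))
  members <- members[order(names(members))]
  structure(list(members = members, background = NULL, min_size = NULL),
            class = "gene_set_collection")
}

#' Restrict a collection to a background and drop small sets
#'
#' Membership is intersected with the background (the scored, annotated
#' genes); terms whose remaining set has fewer than `min_size` members are
#' discarded. The genome-wide functional analysis uses `min_size = 11`
#' (categories mapped to 10 genes or fewer are discarded); the sparser
#' phenotype annotation uses `min_size = 6`.
#'
#' @param collection [propagate()] output (or any `gene_set_collection`).
#' @param min_size minimum retained set size.
#' @param background character vector of gene ids.
#' @return filtered `gene_set_collection` with `background` and `min_size`
#'   recorded.
#' @export
filter_sets <- function(collection, min_size = 11L, background) {
  if (!length(background)) stop("background must be non-empty")
  background <- unique(background)
  members <- lapply(collection$members, function(g) intersect(g, background))
  members <- members[vapply(members, length, 0L) >= min_size]
  structure(list(members = members, background = background,
                 min_size = as.integer(min_size)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sz <- vapply(x$members, length, 0L)
  cat("Gene-set collection: ", length(x$members), " sets",
      if (!is.null(x$min_size)) paste0(" (min size ", x$min_size, ")"),
      "\n", sep = "")
  if (length(sz))
    cat("  set sizes: ", min(sz), "-", max(sz), ", background ",
        length(x$background), " genes\n", sep = "")
  invisible(x)
}

#' Deepest-first processing order for elim
#'
#' Orders terms by decreasing longest-path depth; ties broken
#' lexicographically by term id, so the order is deterministic.
#'
#' @param graph [ontology_graph()].
#' @param ids optional subset of term ids to order (default all).
#' @return character vector of term ids, deepest first.
#' @export
depth_order <- function(graph, ids = NULL) {
  if (is.null(ids)) ids <- graph$terms$id
  d <- graph$depth[ids]
  ids[order(-d, ids)]
}
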