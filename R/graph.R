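#' RNA 2D structure graphs
#'
#' An `rna_graph` is a directed edge-labelled graph: nodes are nucleotide
#' positions, edges carry [edge_label()] strings, and every interaction appears
#' as the two directed twins `(u, v, L)` and `(v, u, iota(L))`. The chemistry
#' of basepairing guarantees that the labels form a proper edge-coloring (PEC):
#' no node has two outgoing edges with the same label. That property is what
#' the matching algorithms in this package exploit.
#'
#' @param id chain/graph identifier string.
#' @param n number of nodes; nodes are the 0-based positions `0:(n-1)`.
#' @param nodes alternatively, an explicit integer vector of node ids
#'   (used for subgraphs that keep their source coordinates).
#' @param chain source chain identifier (defaults to `id`); graph versions
#'   produced by [duplicate_for_exceptions()] share a `chain` but get distinct
#'   `id`s.
#' @param seq optional residue string or character vector (metadata only).
#' @return an object of class `rna_graph`.
#' @seealso [add_interaction()], [validate_pec()], [build_graph()]
#' @export
rna_graph <- function(id, n = NULL, nodes = NULL, chain = id, seq = NULL) {
  if (is.null(nodes)) {
    stopifnot(is.numeric(n), n >= 0)
    nodes <- if (n == 0) integer(0) else 0:(n - 1)
  }
  nodes <- sort(unique(as.integer(nodes)))
  if (!is.null(seq) && length(seq) == 1 && nchar(seq) > 1) {
    seq <- strsplit(seq, "")[[1]]
  }
  structure(
    list(
      id = as.character(id),
      chain = as.character(chain),
      nodes = nodes,
      edges = tibble(from = integer(0), to = integer(0), label = character(0)),
      seq = seq,
      sse = NULL,       # named int vector: node id -> SSE index
      sse_kind = NULL   # chr vector indexed by SSE index
    ),
    class = "rna_graph"
  )
}

#' @export
print.rna_graph <- function(x, ...) {
  cat(sprintf("<rna_graph '%s'> %d nodes, %d directed edges (%d interactions)\n",
              x$id, length(x$nodes), nrow(x$edges), nrow(x$edges) / 2L))
  invisible(x)
}

graph_n_nodes <- function(g) length(g$nodes)

#' One row per interaction
#'
#' Collapses the two directed twin edges of each interaction onto a single row,
#' oriented from the smaller node id.
#'
#' @param g an `rna_graph`.
#' @return tibble with columns `from`, `to` (`from < to`) and `label` (the
#'   label on the `from -> to` direction).
#' @export
interactions <- function(g) {
  e <- g$edges
  keep <- e$from < e$to
  out <- e[keep, , drop = FALSE]
  out[order(out$from, out$to, out$label), , drop = FALSE]
}

#' Add an interaction to a graph
#'
#' Inserts the directed edge `(a, b, label)` and its twin `(b, a, iota(label))`
#' atomically, re-checking the proper edge-coloring at both endpoints. An
#' insertion that would give either endpoint two outgoing edges with the same
#' label is rejected with a condition of class `rinnet_pec_violation` carrying
#' the offending node, label and targets; callers building graphs from
#' annotation data may instead accumulate edges leniently and route conflicts
#' to [duplicate_for_exceptions()].
#'
#' @param g an `rna_graph`.
#' @param a,b node ids, `a != b`.
#' @param label edge label for the `a -> b` direction.
#' @param lenient if `TRUE`, insert without the PEC check.
#' @return the updated graph.
#' @export
add_interaction <- function(g, a, b, label, lenient = FALSE) {
  a <- as.integer(a); b <- as.integer(b)
  check_label(label)
  if (a == b) abort("self-interactions are not allowed")
  if (!(a %in% g$nodes) || !(b %in% g$nodes)) {
    abort(sprintf("node %d or %d not in graph '%s'", a, b, g$id))
  }
  lab_ab <- label
  lab_ba <- iota(label)
  if (!lenient) {
    e <- g$edges
    clash_a <- e$from == a & e$label == lab_ab
    clash_b <- e$from == b & e$label == lab_ba
    if (any(clash_a) || any(clash_b)) {
      node <- if (any(clash_a)) a else b
      lab <- if (any(clash_a)) lab_ab else lab_ba
      targets <- sort(c(e$to[e$from == node & e$label == lab],
                        if (any(clash_a)) b else a))
      abort(
        sprintf("PEC violation at node %d: two outgoing '%s' edges", node, lab),
        class = "rinnet_pec_violation",
        violation = list(node = node, label = lab, conflicting_targets = targets)
      )
    }
  }
  if (any(g$edges$from == a & g$edges$to == b & g$edges$label == lab_ab)) {
    return(g)  # idempotent: the interaction is already present
  }
  g$edges <- dplyr::bind_rows(
    g$edges,
    tibble(from = c(a, b), to = c(b, a), label = c(lab_ab, lab_ba))
  )
  g
}

#' Validate the proper edge-coloring
#'
#' @param g an `rna_graph` (possibly built leniently).
#' @return a list of violations, empty iff the graph satisfies the PEC. Each
#'   violation is a list with `node`, `label` and `conflicting_targets`
#'   (length >= 2), ordered by node id then label.
#' @export
validate_pec <- function(g) {
  e <- g$edges
  if (nrow(e) == 0) return(list())
  key <- paste(e$from, e$label, sep = "\r")
  dup_keys <- unique(key[duplicated(key)])
  if (length(dup_keys) == 0) return(list())
  out <- lapply(dup_keys, function(k) {
    rows <- which(key == k)
    list(node = e$from[rows[1]], label = e$label[rows[1]],
         conflicting_targets = sort(unique(e$to[rows])))
  })
  ord <- order(vapply(out, function(v) v$node, integer(1)),
               vapply(out, function(v) v$label, character(1)))
  out[ord]
}

# canonical (min-node-first) identity of the interaction a directed edge belongs to
interaction_key <- function(from, to, label) {
  lo <- pmin(from, to)
  hi <- pmax(from, to)
  lab_lo <- ifelse(from <= to, label, iota(label))
  paste(lo, hi, lab_lo, sep = "\r")
}

#' Split a conflicted graph into proper edge-colored versions
#'
#' Rarely, annotation data assigns one nucleotide two interactions on the same
#' Leontis-Westhof edge, which breaks the proper edge-coloring. Rather than
#' discarding such chains, the graph is duplicated into PEC-valid versions,
#' each keeping one of the conflicting interactions per violation (Cartesian
#' product over independent violations). Version ids get a `#k` suffix; all
#' versions share the source `chain` id.
#'
#' Beyond `cap` versions the product is truncated: a single version is kept
#' that retains, for each conflict, the interaction whose partner sits in the
#' largest stack of canonical cWW pairs (the same tie rule used when assigning
#' the secondary structure), and a warning is emitted.
#'
#' @param g an `rna_graph`, possibly violating the PEC.
#' @param cap maximum number of versions (default 16).
#' @return list of PEC-valid `rna_graph`s; `list(g)` unchanged when `g` is
#'   already valid.
#' @export
duplicate_for_exceptions <- function(g, cap = 16L) {
  viols <- validate_pec(g)
  if (length(viols) == 0) return(list(g))

  e <- g$edges
  ikey <- interaction_key(e$from, e$to, e$label)
  # per violation: the conflicting interactions (as canonical keys)
  groups <- lapply(viols, function(v) {
    unique(ikey[e$from == v$node & e$label == v$label])
  })
  # one violation is seen from both endpoints when both twins clash; merge
  groups <- unique(lapply(groups, sort))
  n_versions <- prod(vapply(groups, length, integer(1)))

  if (n_versions > cap) {
    warn(sprintf(
      "graph '%s': %d PEC interpretations exceed cap %d; keeping largest-stack version",
      g$id, n_versions, cap))
    choice <- vapply(groups, function(ks) ks[best_stack_choice(g, ks)], character(1))
    combos <- matrix(choice, nrow = 1)
  } else {
    combos <- as.matrix(expand.grid(groups, stringsAsFactors = FALSE))
  }

  all_conflicted <- unique(unlist(groups))
  versions <- list()
  seen <- character(0)
  for (r in seq_len(nrow(combos))) {
    kept <- unlist(combos[r, ])
    drop <- setdiff(all_conflicted, kept)
    gv <- g
    gv$edges <- e[!(ikey %in% drop), , drop = FALSE]
    if (length(validate_pec(gv)) > 0) next  # overlapping conflicts: skip inconsistent combo
    sig <- paste(sort(interaction_key(gv$edges$from, gv$edges$to, gv$edges$label)),
                 collapse = ";")
    if (sig %in% seen) next
    seen <- c(seen, sig)
    versions[[length(versions) + 1]] <- gv
  }
  if (length(versions) == 0) abort(sprintf(
    "graph '%s': no consistent PEC interpretation found", g$id))
  if (length(versions) > 1) {
    for (k in seq_along(versions)) versions[[k]]$id <- paste0(g$id, "#", k)
  }
  versions
}

# among conflicting interactions, index of the one whose partner lies in the
# longest run of stacked cWW pairs (0 when no cWW context); ties -> first
best_stack_choice <- function(g, keys) {
  cww <- interactions(g)
  cww <- cww[label_geometry(cww$label) == "cWW", , drop = FALSE]
  stack_len <- cww_stack_lengths(cww$from, cww$to)
  score <- vapply(keys, function(k) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    lo <- as.integer(parts[1]); hi <- as.integer(parts[2])
    hit <- which(cww$from == lo & cww$to == hi)
    if (length(hit)) stack_len[hit[1]] else 0L
  }, integer(1))
  which.max(score)
}

# length of the maximal run of consecutive nested cWW pairs each pair sits in
cww_stack_lengths <- function(i, j) {
  if (length(i) == 0) return(integer(0))
  key <- paste(i, j)
  len <- integer(length(i))
  for (k in seq_along(i)) {
    l <- 0L
    while (paste(i[k] - l - 1L, j[k] + l + 1L) %in% key) l <- l + 1L
    r <- 0L
    while (paste(i[k] + r + 1L, j[k] - r - 1L) %in% key) r <- r + 1L
    len[k] <- l + r + 1L
  }
  len
}

#' Induced subgraph on a node set
#'
#' Keeps the given nodes and every edge whose two endpoints are both kept.
#' Node ids are preserved (not renumbered).
#'
#' @param g an `rna_graph`.
#' @param nodes node ids to keep.
#' @return an `rna_graph`.
#' @export
subgraph_nodes <- function(g, nodes) {
  nodes <- sort(unique(as.integer(nodes)))
  g$nodes <- intersect(g$nodes, nodes)
  g$edges <- g$edges[g$edges$from %in% g$nodes & g$edges$to %in% g$nodes, , drop = FALSE]
  if (!is.null(g$sse)) g$sse <- g$sse[as.character(g$nodes)]
  g
}

drop_edges_by_key <- function(g, keys) {
  ikey <- interaction_key(g$edges$from, g$edges$to, g$edges$label)
  g$edges <- g$edges[!(ikey %in% keys), , drop = FALSE]
  g
}

#' Renumber a graph's nodes to 0..n-1
#'
#' Used to put canonical RIN graphs into chain-independent coordinates.
#'
#' @param g an `rna_graph`.
#' @return list with the renumbered `graph` and the `map` (old ids, in order,
#'   such that `map[k]` is the old id of new node `k - 1`).
#' @export
renumber_graph <- function(g) {
  map <- g$nodes
  idx <- stats::setNames(seq_along(map) - 1L, map)
  g2 <- g
  g2$nodes <- seq_along(map) - 1L
  g2$edges <- tibble(
    from = unname(idx[as.character(g$edges$from)]),
    to = unname(idx[as.character(g$edges$to)]),
    label = g$edges$label
  )
  g2$sse <- NULL
  g2$seq <- NULL
  list(graph = g2, map = map)
}

# undirected simple igraph over the merged twin edges (labels dropped);
# igraph vertex v corresponds to g$nodes[v]
to_igraph_undirected <- function(g) {
  n <- length(g$nodes)
  idx <- stats::setNames(seq_len(n), g$nodes)
  e <- g$edges[g$edges$from < g$edges$to, , drop = FALSE]
  pairs <- unique(cbind(unname(idx[as.character(e$from)]),
                        unname(idx[as.character(e$to)])))
  ig <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(pairs) > 0) ig <- igraph::add_edges(ig, as.vector(t(pairs)))
  ig
}

# connected components (weak, over merged edges) as a list of node-id vectors
graph_components <- function(g) {
  if (length(g$nodes) == 0) return(list())
  ig <- to_igraph_undirected(g)
  comp <- igraph::components(ig)$membership
  unname(split(g$nodes, comp))
}

#' Read and write the graph JSON dialect
#'
#' Graphs are serialised as
#' `{"id", "chain", "n_nodes", "nodes", "edges": [[u, v, "cWH", "local"], ...]}`
#' storing each interaction once (the `iota` twin is implicit); the reader
#' reconstructs both directed edges. `nodes` is omitted when they are simply
#' `0:(n_nodes-1)`.
#'
#' @param g an `rna_graph`.
#' @param path file path.
#' @return `read_graph_json()` returns an `rna_graph`;
#'   `write_graph_json()` returns `path` invisibly.
#' @export
write_graph_json <- function(g, path) {
  ia <- interactions(g)
  obj <- list(
    id = g$id,
    chain = g$chain,
    n_nodes = length(g$nodes),
    edges = purrr::pmap(ia, function(from, to, label) {
      list(from, to, label_geometry(label), label_range(label))
    })
  )
  if (!identical(g$nodes, seq_len(length(g$nodes)) - 1L)) obj$nodes <- g$nodes
  if (!is.null(g$seq)) obj$seq <- paste(g$seq, collapse = "")
  if (!is.null(g$sse)) {
    obj$sse <- unname(g$sse[as.character(g$nodes)])
    obj$sse_kind <- g$sse_kind
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_graph_json
#' @export
read_graph_json <- function(path) {
  obj <- jsonlite::read_json(path)
  nodes <- if (!is.null(obj$nodes)) unlist(obj$nodes) else NULL
  g <- rna_graph(obj$id,
                 n = if (is.null(nodes)) obj$n_nodes else NULL,
                 nodes = nodes,
                 chain = obj$chain %||% obj$id,
                 seq = obj$seq)
  if (length(obj$edges) > 0) {
    tab <- tibble(
      i = vapply(obj$edges, function(e) as.integer(e[[1]]), integer(1)),
      j = vapply(obj$edges, function(e) as.integer(e[[2]]), integer(1)),
      label = edge_label(vapply(obj$edges, function(e) e[[3]], character(1)),
                         vapply(obj$edges, function(e) e[[4]], character(1)))
    )
    g$edges <- tibble(from = c(tab$i, tab$j), to = c(tab$j, tab$i),
                      label = c(tab$label, iota(tab$label)))
    if (length(validate_pec(g)) > 0) {
      abort(sprintf("graph '%s' in %s violates the proper edge-coloring",
                    g$id, path))
    }
  }
  if (!is.null(obj$sse)) {
    g$sse <- stats::setNames(unlist(obj$sse), g$nodes)
    g$sse_kind <- unlist(obj$sse_kind)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
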