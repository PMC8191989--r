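# ---- inclusion network over a catalog ---------------------------------------

#' Build the inclusion network of a RIN catalog
#'
#' Nodes are catalog ids; a directed edge `r1 -> r2` states that the canonical
#' graph of r1 is a subgraph of the canonical graph of r2. Because the catalog
#' is non-redundant (no two canonical graphs isomorphic), the relation is a
#' strict partial order. Ordered pairs are pre-screened with an
#' invariant-vector dominance test (node count and per-label edge counts must
#' not decrease) before the exact subgraph-isomorphism call; each retained
#' edge keeps its certifying injection for audit.
#'
#' @param catalog a `rin_catalog`.
#' @return a `rin_network`: list with `nodes`, `edges` (tibble `from`, `to`),
#'   `injections` (named list keyed `"from->to"`), `reduced` flag.
#' @export
build_network <- function(catalog) {
  rins <- catalog$rins
  ids <- vapply(rins, function(r) r$catalog_id, integer(1))
  sizes <- vapply(rins, function(r) length(r$graph$nodes), integer(1))
  counts <- lapply(rins, function(r) table(r$graph$edges$label))

  dominates <- function(a, b) {
    # do b's per-label counts cover a's?
    all(names(counts[[a]]) %in% names(counts[[b]])) &&
      all(as.integer(counts[[a]]) <=
            as.integer(counts[[b]][names(counts[[a]])]))
  }

  from <- integer(0); to <- integer(0)
  injections <- list()
  for (a in seq_along(rins)) for (b in seq_along(rins)) {
    if (a == b || sizes[a] > sizes[b]) next
    if (!dominates(a, b)) next
    inj <- is_subgraph(rins[[a]]$graph, rins[[b]]$graph)
    if (is.null(inj)) next
    if (sizes[a] == sizes[b] &&
        nrow(rins[[a]]$graph$edges) == nrow(rins[[b]]$graph$edges)) {
      abort("catalog contains isomorphic canonical graphs; not non-redundant")
    }
    from <- c(from, ids[a]); to <- c(to, ids[b])
    injections[[paste0(ids[a], "->", ids[b])]] <- inj
  }
  structure(list(nodes = ids, edges = tibble(from = from, to = to),
                 injections = injections, reduced = FALSE),
            class = "rin_network")
}

#' @export
print.rin_network <- function(x, ...) {
  cat(sprintf("<rin_network%s> %d RINs, %d inclusion edges\n",
              if (x$reduced) " (reduced)" else "", length(x$nodes), nrow(x$edges)))
  invisible(x)
}

reachability_matrix <- function(nodes, edges) {
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  R <- matrix(FALSE, n, n)
  if (nrow(edges) > 0) R[cbind(idx[as.character(edges$from)],
                               idx[as.character(edges$to)])] <- TRUE
  # transitive closure (Floyd-Warshall style)
  for (k in seq_len(n)) R <- R | (outer(R[, k], R[k, ], `&`))
  R
}

#' Transitively reduce an inclusion network
#'
#' Removes every edge `r1 -> r3` for which a 2-step path `r1 -> r2 -> r3`
#' exists, leaving the minimal edge set with the same reachability (for
#' display, every removed edge is equivalent to a path). Requires an acyclic
#' network; a cycle signals a redundant catalog and is an error.
#'
#' @param network a `rin_network`.
#' @return the reduced `rin_network`.
#' @export
transitive_reduce <- function(network) {
  R <- reachability_matrix(network$nodes, network$edges)
  if (any(diag(R))) abort("inclusion network contains a cycle (catalog redundancy bug)")
  idx <- stats::setNames(seq_along(network$nodes), network$nodes)
  e <- network$edges
  if (nrow(e) > 0) {
    redundant <- vapply(seq_len(nrow(e)), function(k) {
      u <- idx[as.character(e$from[k])]
      v <- idx[as.character(e$to[k])]
      mid <- which(R[u, ] & R[, v])
      length(setdiff(mid, c(u, v))) > 0
    }, logical(1))
    network$edges <- e[!redundant, , drop = FALSE]
  }
  network$reduced <- TRUE
  network
}

#' Connected-component statistics of an inclusion network
#'
#' Summarises the weakly connected components: how fragmented the class
#' landscape is, how many isolated RINs there are, and what fraction of the
#' catalog the giant component gathers.
#'
#' @param network a `rin_network`.
#' @return one-row tibble: `n_nodes`, `n_edges`, `n_components`,
#'   `n_singletons`, `giant_size`, `giant_fraction`, plus a `component_sizes`
#'   list-column (sizes in decreasing order).
#' @export
component_stats <- function(network) {
  n <- length(network$nodes)
  idx <- stats::setNames(seq_len(n), network$nodes)
  ig <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(network$edges) > 0) {
    ig <- igraph::add_edges(ig, rbind(idx[as.character(network$edges$from)],
                                      idx[as.character(network$edges$to)]))
  }
  comp <- igraph::components(ig)
  sizes <- sort(as.integer(comp$csize), decreasing = TRUE)
  tibble(
    n_nodes = n,
    n_edges = nrow(network$edges),
    n_components = length(sizes),
    n_singletons = sum(sizes == 1),
    giant_size = if (length(sizes)) sizes[1] else 0L,
    giant_fraction = if (n > 0) sizes[1] / n else NA_real_,
    component_sizes = list(sizes)
  )
}

#' @rdname tidy.rin_catalog
#' @export
tidy.rin_network <- function(x, ...) x$edges

#' @rdname tidy.rin_catalog
#' @export
glance.rin_network <- function(x, ...) {
  component_stats(x)[, c("n_nodes", "n_edges", "n_components",
                         "n_singletons", "giant_fraction")]
}

#' Plot an inclusion network
#'
#' Simple ggplot rendering of the (preferably reduced) inclusion network with
#' a force-directed layout.
#'
#' @param object a `rin_network`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.rin_network <- function(object, ...) {
  n <- length(object$nodes)
  idx <- stats::setNames(seq_len(n), object$nodes)
  ig <- igraph::make_empty_graph(n, directed = TRUE)
  if (nrow(object$edges) > 0) {
    ig <- igraph::add_edges(ig, rbind(idx[as.character(object$edges$from)],
                                      idx[as.character(object$edges$to)]))
  }
  xy <- igraph::layout_with_fr(ig)
  pts <- tibble(id = object$nodes, x = xy[, 1], y = xy[, 2])
  seg <- dplyr::mutate(object$edges,
                       x = pts$x[idx[as.character(.data$from)]],
                       y = pts$y[idx[as.character(.data$from)]],
                       xend = pts$x[idx[as.character(.data$to)]],
                       yend = pts$y[idx[as.character(.data$to)]])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          color = "grey60",
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::geom_point(data = pts, ggplot2::aes(x = .data$x, y = .data$y), size = 2) +
    ggplot2::theme_void()
}

#' Export an inclusion network
#'
#' `write_network_json()` writes nodes and edge list;
#' `write_network_dot()` writes Graphviz DOT.
#'
#' @param network a `rin_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(network, path) {
  jsonlite::write_json(
    list(nodes = network$nodes,
         edges = purrr::map2(network$edges$from, network$edges$to, c),
         reduced = network$reduced),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network_json
#' @export
write_network_dot <- function(network, path) {
  lines <- c("digraph rin_inclusions {",
             paste0("  ", network$nodes, ";"),
             sprintf("  %d -> %d;", network$edges$from, network$edges$to),
             "}")
  writeLines(lines, path)
  invisible(path)
}
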