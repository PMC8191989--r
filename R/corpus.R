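# ---- pairwise corpus extraction and isomorphism clustering -------------------

# invariant vector used to bucket canonical graphs before exact isomorphism:
# node count, per-label edge counts, sorted out-degree multiset
graph_invariant <- function(g) {
  cnt <- table(g$edges$label)
  deg <- sort(as.integer(table(factor(g$edges$from, levels = g$nodes))))
  paste(length(g$nodes),
        paste(names(cnt), as.integer(cnt), sep = "=", collapse = ","),
        paste(deg, collapse = "."),
        sep = "|")
}

occurrence_key <- function(occ) {
  paste0(occ$graph_id, ":", paste(occ$nodes, collapse = ","))
}

#' Extract a non-redundant RIN catalog from a corpus of structure graphs
#'
#' The full pipeline: every chain graph is (optionally) pre-filtered with
#' f'_R; for each unordered pair of graphs from distinct chains all maximal
#' connected common subgraphs are enumerated and distilled into candidate RINs
#' with [extract_rins()]; candidates are clustered by exact graph isomorphism
#' (bucketed on an invariant vector first) and their occurrences merged, keyed
#' by (graph id, occupied node set) so that automorphic re-matchings collapse;
#' clusters whose occurrences touch fewer than two distinct chains are dropped
#' (a RIN must be recurrent across chains). Pairs are processed independently,
#' so the result does not depend on the corpus order; catalog ids are assigned
#' on a deterministic sort of the clusters.
#'
#' @param graphs list of PEC-valid `rna_graph`s (>= 2, distinct ids).
#' @param rules a [rin_rules()] rule set.
#' @param use_prefilter apply f'_R before matching (identical catalog, much
#'   faster; the equivalence is property-tested).
#' @param cap branch-safety cap forwarded to [all_maximal_common_subgraphs()].
#' @return a `rin_catalog`.
#' @export
run_corpus <- function(graphs, rules = rin_rules("abc"), use_prefilter = TRUE,
                       cap = 1e6) {
  if (length(graphs) < 2) abort("a corpus needs at least two graphs")
  ids <- vapply(graphs, function(g) g$id, character(1))
  if (anyDuplicated(ids)) abort("graph ids must be unique")
  chains <- vapply(graphs, function(g) g$chain, character(1))

  work <- if (use_prefilter) lapply(graphs, prefilter, rules = rules) else graphs

  clusters <- list()      # each: list(graph, invariant, occs = named list, lr)
  add_candidate <- function(cand) {
    inv <- graph_invariant(cand$graph)
    for (ci in seq_along(clusters)) {
      if (clusters[[ci]]$invariant != inv) next
      iso <- are_isomorphic(clusters[[ci]]$graph, cand$graph)
      if (is.null(iso)) next
      for (occ in cand$occurrences) {
        key <- occurrence_key(occ)
        if (is.null(clusters[[ci]]$occs[[key]])) {
          # remap the injection onto the cluster representative's node order
          occ$injection <- stats::setNames(
            unname(occ$injection[as.character(unname(iso))]), names(iso))
          clusters[[ci]]$occs[[key]] <<- occ
        }
      }
      return(invisible())
    }
    occs <- list()
    for (occ in cand$occurrences) occs[[occurrence_key(occ)]] <- occ
    clusters[[length(clusters) + 1]] <<- list(
      graph = cand$graph, invariant = inv, occs = occs, lr = cand$n_long_range)
    invisible()
  }

  idx <- seq_along(graphs)
  for (a in idx) for (b in idx) {
    if (a >= b || chains[a] == chains[b]) next
    mcss <- all_maximal_common_subgraphs(work[[a]], work[[b]], cap = cap)
    for (m in mcss) {
      for (cand in extract_rins(m, rules, graphs[[a]], graphs[[b]])) {
        add_candidate(cand)
      }
    }
  }

  # recurrence: occurrences must span >= 2 distinct chains
  chain_of <- stats::setNames(chains, ids)
  keep <- vapply(clusters, function(cl) {
    ch <- unique(vapply(cl$occs, function(o) o$chain, character(1)))
    length(ch) >= 2
  }, logical(1))
  clusters <- clusters[keep]

  # deterministic, corpus-order-independent catalog ids
  sort_key <- vapply(clusters, function(cl) {
    paste(sprintf("%06d", length(cl$graph$nodes)),
          sprintf("%06d", nrow(cl$graph$edges)),
          cl$invariant,
          paste(sort(names(cl$occs)), collapse = ";"))
  }, character(1))
  clusters <- clusters[order(sort_key)]

  rins <- lapply(seq_along(clusters), function(k) {
    cl <- clusters[[k]]
    occs <- cl$occs[order(names(cl$occs))]
    structure(list(
      catalog_id = k,
      graph = cl$graph,
      occurrences = occs,
      n_long_range = cl$lr
    ), class = "rin")
  })

  structure(list(
    rins = rins,
    rules = rules,
    manifest = tibble(graph_id = ids, chain = chains,
                      n_nodes = vapply(graphs, function(g) length(g$nodes), integer(1)))
  ), class = "rin_catalog")
}

#' @export
print.rin <- function(x, ...) {
  cat(sprintf("<rin #%d> %d nodes, %d interactions, %d long-range, %d occurrence(s) in %d chain(s)\n",
              x$catalog_id, length(x$graph$nodes), nrow(x$graph$edges) / 2,
              x$n_long_range, length(x$occurrences),
              length(unique(vapply(x$occurrences, function(o) o$chain, character(1))))))
  invisible(x)
}

#' @export
print.rin_catalog <- function(x, ...) {
  cat(sprintf("<rin_catalog> %d RINs, %d occurrences, rules '%s', %d graphs\n",
              length(x$rins),
              sum(vapply(x$rins, function(r) length(r$occurrences), integer(1))),
              x$rules$name, nrow(x$manifest)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a RIN catalog
#'
#' @param x a `rin_catalog`.
#' @param ... unused.
#' @return one row per RIN: catalog id, node/interaction counts, long-range
#'   interaction count, occurrence and chain counts, and the range of SSE
#'   spans observed across occurrences.
#' @export
tidy.rin_catalog <- function(x, ...) {
  purrr::map_dfr(x$rins, function(r) {
    spans <- vapply(r$occurrences, function(o) as.integer(o$sse_span), integer(1))
    tibble(
      catalog_id = r$catalog_id,
      n_nodes = length(r$graph$nodes),
      n_interactions = nrow(r$graph$edges) / 2,
      n_long_range = r$n_long_range,
      n_occurrences = length(r$occurrences),
      n_chains = length(unique(vapply(r$occurrences, function(o) o$chain, character(1)))),
      sse_span_min = if (all(is.na(spans))) NA_integer_ else min(spans, na.rm = TRUE),
      sse_span_max = if (all(is.na(spans))) NA_integer_ else max(spans, na.rm = TRUE)
    )
  })
}

#' @rdname tidy.rin_catalog
#' @export
glance.rin_catalog <- function(x, ...) {
  tb <- tidy(x)
  tibble(
    n_rins = nrow(tb),
    n_occurrences = sum(tb$n_occurrences),
    n_graphs = nrow(x$manifest),
    rules = x$rules$name,
    largest_rin_nodes = if (nrow(tb)) max(tb$n_nodes) else 0L
  )
}

#' Plot the composition of a RIN catalog
#'
#' Bar chart of RIN and occurrence counts by number of long-range
#' interactions (the catalog-level summary view).
#'
#' @param object a `rin_catalog`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.rin_catalog <- function(object, ...) {
  tb <- tidy(object)
  agg <- dplyr::summarise(
    dplyr::group_by(tb, .data$n_long_range),
    RINs = dplyr::n(), occurrences = sum(.data$n_occurrences), .groups = "drop")
  long <- tidyr_pivot(agg)
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$n_long_range),
                                     y = .data$count, fill = .data$what)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "long-range interactions", y = "count (log scale)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

# minimal long-format pivot (avoids a tidyr dependency for one reshape)
tidyr_pivot <- function(agg) {
  dplyr::bind_rows(
    tibble(n_long_range = agg$n_long_range, what = "RINs", count = agg$RINs),
    tibble(n_long_range = agg$n_long_range, what = "occurrences", count = agg$occurrences)
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# corpus-order-independent fingerprint of a catalog (used by the determinism
# and prefilter-equivalence tests): canonical-graph invariant + occurrence keys
catalog_signature <- function(catalog) {
  sort(vapply(catalog$rins, function(r) {
    paste(graph_invariant(r$graph),
          paste(sort(names(r$occurrences)), collapse = ";"),
          sep = " || ")
  }, character(1)))
}

#' Serialise a catalog to JSON
#'
#' Writes each RIN's canonical graph (graph JSON dialect), its long-range
#' interaction count, and its occurrences as chain id plus 1-based nucleotide
#' positions, together with the SSE-span histogram across occurrences.
#'
#' @param catalog a `rin_catalog`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_catalog_json <- function(catalog, path) {
  obj <- list(
    rules = catalog$rules[setdiff(names(catalog$rules), "name")],
    preset = catalog$rules$name,
    n_rins = length(catalog$rins),
    rins = lapply(catalog$rins, function(r) {
      ia <- interactions(r$graph)
      spans <- vapply(r$occurrences, function(o) as.integer(o$sse_span), integer(1))
      list(
        catalog_id = r$catalog_id,
        n_nodes = length(r$graph$nodes),
        n_long_range = r$n_long_range,
        edges = purrr::pmap(ia, function(from, to, label) {
          list(from, to, label_geometry(label), label_range(label))
        }),
        sse_span_histogram = as.list(table(spans)),
        occurrences = lapply(unname(r$occurrences), function(o) {
          list(graph_id = o$graph_id, chain = o$chain,
               positions = o$nodes + 1L)  # 1-based, human-facing
        })
      )
    })
  )
  obj$rules$max_long_range <- if (is.finite(obj$rules$max_long_range)) {
    obj$rules$max_long_range
  } else "unbounded"
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_catalog_json
#' @export
read_catalog_json <- function(path) {
  obj <- jsonlite::read_json(path)
  rins <- lapply(obj$rins, function(r) {
    g <- rna_graph(paste0("rin", r$catalog_id), n = r$n_nodes)
    if (length(r$edges) > 0) {
      i <- vapply(r$edges, function(e) as.integer(e[[1]]), integer(1))
      j <- vapply(r$edges, function(e) as.integer(e[[2]]), integer(1))
      lab <- edge_label(vapply(r$edges, function(e) e[[3]], character(1)),
                        vapply(r$edges, function(e) e[[4]], character(1)))
      g$edges <- tibble(from = c(i, j), to = c(j, i), label = c(lab, iota(lab)))
    }
    occs <- list()
    for (o in r$occurrences) {
      occ <- list(graph_id = o$graph_id, chain = o$chain,
                  nodes = unlist(o$positions) - 1L, injection = NULL,
                  sse_span = NA_integer_)
      occs[[occurrence_key(occ)]] <- occ
    }
    structure(list(catalog_id = r$catalog_id, graph = g, occurrences = occs,
                   n_long_range = r$n_long_range), class = "rin")
  })
  structure(list(rins = rins, rules = rin_rules(obj$preset),
                 manifest = tibble(graph_id = character(0), chain = character(0),
                                   n_nodes = integer(0))),
            class = "rin_catalog")
}
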