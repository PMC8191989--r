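# ---- rule sets ---------------------------------------------------------------

#' Rule sets defining RIN classes
#'
#' A Recurrent Interaction Network class is defined by a set of structural
#' rules applied to the canonical graph S of each candidate:
#'
#' * rule x (`require_cycles`): every node of S lies on a cycle of the
#'   undirected graph induced by S — no danglings.
#' * rule y (`forbid_pure_stack_extension`): every local canonical (cWW)
#'   basepair of S has a witness node, a neighbor of either partner involved
#'   in a long-range or non-canonical interaction — pure cWW stacks are never
#'   extended (else every stem would match every stem).
#' * rule z (`require_basepair_per_node`): every node of S forms at least one
#'   basepair — no backbone-only chains.
#' * rule b (`min_long_range`): S contains at least this many long-range
#'   interactions (2 for the classic interaction-network classes); the
#'   complementary `max_long_range = 0` expresses the "no long-range" variant
#'   used for purely local 3D modules.
#' * rule c (`sse_span`): the nucleotides of each occurrence are captured by
#'   exactly this many SSEs (2 in the classic definition), or unconstrained
#'   (`NULL`).
#'
#' Presets: `"abc"` (x, y, z, >= 2 long-range, exactly 2 SSEs), `"ab"` (rule c
#' relaxed), `"a"` (rules b and c relaxed), and `"local_modules"` (x, y, no
#' long-range interactions allowed, z relaxed so that bulged backbone-only
#' nucleotides on a cycle — as in kink-turns — are kept).
#'
#' @param preset one of `"abc"`, `"ab"`, `"a"`, `"local_modules"`.
#' @param require_cycles,forbid_pure_stack_extension,require_basepair_per_node,min_long_range,max_long_range,sse_span
#'   override individual fields of the preset.
#' @return a `rin_ruleset`.
#' @export
rin_rules <- function(preset = c("abc", "ab", "a", "local_modules"),
                      require_cycles = NULL, forbid_pure_stack_extension = NULL,
                      require_basepair_per_node = NULL, min_long_range = NULL,
                      max_long_range = NULL, sse_span = NULL) {
  preset <- match.arg(preset)
  base <- switch(preset,
    abc = list(require_cycles = TRUE, forbid_pure_stack_extension = TRUE,
               require_basepair_per_node = TRUE, min_long_range = 2L,
               max_long_range = Inf, sse_span = 2L),
    ab = list(require_cycles = TRUE, forbid_pure_stack_extension = TRUE,
              require_basepair_per_node = TRUE, min_long_range = 2L,
              max_long_range = Inf, sse_span = NULL),
    a = list(require_cycles = TRUE, forbid_pure_stack_extension = TRUE,
             require_basepair_per_node = TRUE, min_long_range = 0L,
             max_long_range = Inf, sse_span = NULL),
    local_modules = list(require_cycles = TRUE, forbid_pure_stack_extension = TRUE,
                         require_basepair_per_node = FALSE, min_long_range = 0L,
                         max_long_range = 0L, sse_span = NULL)
  )
  ovr <- list(require_cycles = require_cycles,
              forbid_pure_stack_extension = forbid_pure_stack_extension,
              require_basepair_per_node = require_basepair_per_node,
              min_long_range = min_long_range,
              max_long_range = max_long_range)
  for (nm in names(ovr)) if (!is.null(ovr[[nm]])) base[[nm]] <- ovr[[nm]]
  if (!missing(sse_span)) base$sse_span <- sse_span
  structure(c(list(name = preset), base), class = "rin_ruleset")
}

#' @export
print.rin_ruleset <- function(x, ...) {
  span <- if (is.null(x$sse_span)) "any" else x$sse_span
  cat(sprintf(
    "<rin_ruleset '%s'> cycles:%s stacks-excluded:%s basepair-per-node:%s long-range:[%s,%s] SSE span:%s\n",
    x$name, x$require_cycles, x$forbid_pure_stack_extension,
    x$require_basepair_per_node, x$min_long_range,
    ifelse(is.finite(x$max_long_range), x$max_long_range, "Inf"), span))
  invisible(x)
}

# ---- individual rules --------------------------------------------------------

#' Nodes lying on a cycle (rule x)
#'
#' Returns the nodes lying on at least one cycle of the undirected simple
#' graph obtained by merging the directed twin edges. A node is on a cycle iff
#' it is incident to a non-bridge edge.
#'
#' @param g an `rna_graph`.
#' @return sorted integer vector of node ids.
#' @export
rule_x_nodes_in_cycles <- function(g) {
  if (length(g$nodes) == 0 || nrow(g$edges) == 0) return(integer(0))
  ig <- to_igraph_undirected(g)
  if (igraph::ecount(ig) == 0) return(integer(0))
  br <- igraph::bridges(ig)
  keep <- setdiff(seq_len(igraph::ecount(ig)), as.integer(br))
  if (length(keep) == 0) return(integer(0))
  ends <- igraph::ends(ig, keep, names = FALSE)
  sort(unique(g$nodes[as.vector(ends)]))
}

# does node c carry a long-range or non-canonical (non-cWW) pair interaction?
qualifying_nodes <- function(g) {
  e <- g$edges
  pair <- is_pair_label(e$label)
  qual <- pair & (label_range(e$label) == "long_range" | label_geometry(e$label) != "cWW")
  sort(unique(e$from[qual]))
}

#' Local canonical pairs with no witness (rule y)
#'
#' Finds the local cWW basepairs `(a, b)` such that no neighbor of `a` or `b`
#' (via any edge, the partner itself included) is involved in a long-range or
#' non-canonical interaction. Such pairs are pure stack extensions and are
#' excluded from RINs.
#'
#' @param g an `rna_graph`.
#' @return tibble of violating pairs (`a`, `b`).
#' @export
rule_y_check <- function(g) {
  ia <- interactions(g)
  cww <- ia[ia$label == edge_label("cWW", "local"), , drop = FALSE]
  if (nrow(cww) == 0) return(tibble(a = integer(0), b = integer(0)))
  qual <- qualifying_nodes(g)
  e <- g$edges
  neigh <- function(v) unique(c(v, e$to[e$from %in% v]))
  viol <- vapply(seq_len(nrow(cww)), function(k) {
    !any(neigh(c(cww$from[k], cww$to[k])) %in% qual)
  }, logical(1))
  tibble(a = cww$from[viol], b = cww$to[viol])
}

# ---- fixpoint pruning (shared by the pre- and post-filter) -------------------

# iteratively remove everything that infringes the (graph-local) rules x, y, z
# and, when max_long_range == 0, every long-range interaction
prune_to_rules <- function(g, rules) {
  repeat {
    before <- c(length(g$nodes), nrow(g$edges))
    if (rules$max_long_range == 0) {
      lr <- label_range(g$edges$label) == "long_range"
      g$edges <- g$edges[!lr, , drop = FALSE]
    }
    if (rules$forbid_pure_stack_extension) {
      v <- rule_y_check(g)
      if (nrow(v) > 0) {
        g <- drop_edges_by_key(g, interaction_key(v$a, v$b, edge_label("cWW", "local")))
      }
    }
    if (rules$require_basepair_per_node) {
      has_pair <- unique(g$edges$from[is_pair_label(g$edges$label)])
      g <- subgraph_nodes(g, has_pair)
    }
    if (rules$require_cycles) {
      g <- subgraph_nodes(g, rule_x_nodes_in_cycles(g))
    }
    if (identical(c(length(g$nodes), nrow(g$edges)), before)) return(g)
  }
}

#' Pre-filter a structure graph against a rule set
#'
#' The optional performance filter f'_R: removes from a chain graph every node
#' and edge that already infringes a rule and therefore cannot belong to any
#' valid RIN of the class — backbone-only nodes (rule z), nodes outside every
#' cycle (rule x), unwitnessed local cWW stack pairs (rule y), long-range
#' edges when the class forbids them, and whole connected components whose
#' long-range interaction count falls below the class minimum. The output is a
#' subgraph of the input, and every RIN findable in the input is findable in
#' the output; it iterates to a fixpoint because each removal can expose new
#' violations.
#'
#' @param g a PEC-valid `rna_graph`.
#' @param rules a [rin_rules()] rule set.
#' @return the pruned `rna_graph` (original node ids preserved).
#' @export
prefilter <- function(g, rules) {
  g <- prune_to_rules(g, rules)
  if (rules$min_long_range > 0 && length(g$nodes) > 0) {
    comps <- graph_components(g)
    keep <- unlist(lapply(comps, function(ns) {
      sub <- g$edges$from %in% ns
      lr <- sum(label_range(g$edges$label[sub]) == "long_range") / 2
      if (lr >= rules$min_long_range) ns else NULL
    }))
    g <- subgraph_nodes(g, keep %||% integer(0))
  }
  g
}

# ---- extraction from maximal common subgraphs --------------------------------

count_long_range <- function(g) {
  sum(label_range(g$edges$label) == "long_range") / 2
}

#' Extract candidate RINs from a maximal common subgraph
#'
#' The post-filter f_R: prunes a maximal common subgraph of two chain graphs
#' to its rule-satisfying core (same fixpoint as [prefilter()]), splits the
#' result into connected components, and keeps each component satisfying the
#' long-range interaction bounds (rule b) and — when the class constrains it —
#' spanning exactly `sse_span` SSEs in both source chains (rule c, evaluated
#' per occurrence). Each surviving component becomes one candidate RIN
#' fragment carrying its two occurrences.
#'
#' @param mcs a `common_subgraph` from [all_maximal_common_subgraphs()].
#' @param rules a [rin_rules()] rule set.
#' @param G,H the source `rna_graph`s the subgraph was computed from (their
#'   `sse` metadata, when present, is used for rule c and for span reporting).
#' @return list of candidates; each has `graph` (canonical 0-based
#'   `rna_graph`), `occurrences` (list of `graph_id`, `chain`, `nodes`,
#'   `injection`, `sse_span`) and `n_long_range`.
#' @export
extract_rins <- function(mcs, rules, G, H) {
  if (nrow(mcs$pairs) == 0) return(list())
  # a subgraph with no long-range and no non-canonical interaction has no
  # rule-y witness anywhere, so the fixpoint empties it: skip it outright
  # (this disposes of the plentiful backbone/stem-only alignments cheaply)
  lab <- mcs$edges$label
  if (!any(is_pair_label(lab) &
             (label_range(lab) == "long_range" | label_geometry(lab) != "cWW"))) {
    return(list())
  }
  sg <- rna_graph(G$id, nodes = mcs$pairs$g, chain = G$chain)
  sg$edges <- mcs$edges
  pruned <- prune_to_rules(sg, rules)
  if (length(pruned$nodes) == 0) return(list())
  gh <- stats::setNames(mcs$pairs$h, mcs$pairs$g)

  out <- list()
  for (ns in graph_components(pruned)) {
    if (length(ns) < 2) next
    comp <- subgraph_nodes(pruned, ns)
    lr <- count_long_range(comp)
    if (lr < rules$min_long_range || lr > rules$max_long_range) next
    h_ns <- unname(gh[as.character(ns)])
    span_g <- occurrence_span(G, ns)
    span_h <- occurrence_span(H, h_ns)
    if (!is.null(rules$sse_span)) {
      if (is.na(span_g) || is.na(span_h)) {
        abort("rule c (SSE span) requires SSE metadata on both source graphs")
      }
      if (span_g != rules$sse_span || span_h != rules$sse_span) next
    }
    ren <- renumber_graph(comp)
    inj_g <- stats::setNames(ren$map, ren$graph$nodes)           # canonical -> G node
    inj_h <- stats::setNames(unname(gh[as.character(ren$map)]), ren$graph$nodes)
    out[[length(out) + 1]] <- list(
      graph = ren$graph,
      occurrences = list(
        list(graph_id = G$id, chain = G$chain, nodes = sort(ren$map),
             injection = inj_g, sse_span = span_g),
        list(graph_id = H$id, chain = H$chain, nodes = sort(unname(inj_h)),
             injection = inj_h, sse_span = span_h)
      ),
      n_long_range = lr
    )
  }
  out
}

occurrence_span <- function(g, nodes) {
  if (is.null(g$sse)) return(NA_integer_)
  length(unique(g$sse[as.character(nodes)]))
}
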