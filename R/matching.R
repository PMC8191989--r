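# ---- bridging rna_graph objects to the C++ core ------------------------------

# shared label dictionary, lexicographic so that integer order == label order
label_dict <- function(...) {
  sort(unique(unlist(lapply(list(...), function(g) g$edges$label))))
}

# 0-based contiguous matrix encoding of a graph under a label dictionary;
# returns list(n, m (edge matrix), nodes (original ids, position k+1 <-> id))
encode_graph <- function(g, dict) {
  idx <- stats::setNames(seq_along(g$nodes) - 1L, g$nodes)
  lab <- match(g$edges$label, dict) - 1L
  m <- cbind(unname(idx[as.character(g$edges$from)]),
             unname(idx[as.character(g$edges$to)]),
             lab)
  storage.mode(m) <- "integer"
  if (nrow(g$edges) == 0) m <- matrix(integer(0), 0, 3)
  list(n = length(g$nodes), m = m, nodes = g$nodes)
}

decode_pairs <- function(mat, encG, encH) {
  tibble(g = encG$nodes[mat[, 1] + 1L], h = encH$nodes[mat[, 2] + 1L])
}

# ---- the extension core ------------------------------------------------------

#' Extend a partial matching between two PEC graphs
#'
#' The deterministic extension core shared by the three matching algorithms.
#' Starting from a seed of matched node pairs, the matched frontier is expanded
#' breadth-first: for a matched pair `(g, h)` and each label carried by both
#' nodes, the proper edge-coloring leaves at most one candidate pair of
#' neighbors, so no permutation search is ever needed. In `"strict"` mode any
#' conflict (an endpoint already matched elsewhere, a pattern edge with no
#' counterpart, a forbidden pair) aborts the extension; in `"permissive"` mode
#' conflicts are recorded as discrepancies and the extension continues to a
#' maximal matching.
#'
#' @param G,H `rna_graph` objects (PEC-valid).
#' @param seed two-column matrix or data frame of matched node pairs
#'   (G node, H node), non-empty.
#' @param forbidden optional two-column matrix of node pairs this extension
#'   must never match.
#' @param mode `"strict"` or `"permissive"`.
#' @return list with `failed` (strict-mode failure flag), `mapping` (tibble
#'   `g`,`h` in match order), `discrepancies` (tibble of conflicting pairs, in
#'   encounter order) and `maximal` (whether no compatible free pair extends
#'   the result).
#' @export
extend_matching <- function(G, H, seed, forbidden = NULL, mode = c("permissive", "strict")) {
  mode <- match.arg(mode)
  dict <- label_dict(G, H)
  encG <- encode_graph(G, dict)
  encH <- encode_graph(H, dict)
  seed <- as.matrix(as.data.frame(seed))
  if (nrow(seed) == 0) abort("seed matching must be non-empty")
  sm <- cbind(match(seed[, 1], encG$nodes) - 1L, match(seed[, 2], encH$nodes) - 1L)
  if (anyNA(sm)) abort("seed refers to nodes absent from G or H")
  storage.mode(sm) <- "integer"
  fm <- matrix(integer(0), 0, 2)
  if (!is.null(forbidden) && nrow(forbidden) > 0) {
    forbidden <- as.matrix(as.data.frame(forbidden))
    fm <- cbind(match(forbidden[, 1], encG$nodes) - 1L,
                match(forbidden[, 2], encH$nodes) - 1L)
    storage.mode(fm) <- "integer"
  }
  cpp_mode <- if (mode == "strict") 1L else 2L
  res <- cpp_extend(encG$n, encG$m, encH$n, encH$m, sm, fm, cpp_mode)
  list(
    failed = res$failed,
    mapping = decode_pairs(res$pairs, encG, encH),
    discrepancies = decode_pairs(res$discrepancies, encG, encH),
    maximal = res$maximal
  )
}

#' Seed color selection
#'
#' Returns the edge label (color) minimizing `|E_G,c| * |E_H,c|` over the
#' labels present in both graphs; seeding the extension on the rarest shared
#' color minimizes the number of starting points. Ties break to the
#' lexicographically smallest label.
#'
#' @param G,H `rna_graph` objects.
#' @return a label string, or `NA_character_` when the graphs share no label
#'   ("no-seed": they have no common subgraph with an edge).
#' @export
pick_seed_color <- function(G, H) {
  dict <- label_dict(G, H)
  encG <- encode_graph(G, dict)
  encH <- encode_graph(H, dict)
  col <- cpp_pick_seed_color(encG$n, encG$m, encH$n, encH$m)
  if (col < 0) NA_character_ else dict[col + 1]
}

# ---- isomorphism -------------------------------------------------------------

component_subgraphs <- function(g) {
  lapply(graph_components(g), function(ns) subgraph_nodes(g, ns))
}

component_signature <- function(g) {
  cnt <- table(g$edges$label)
  paste(length(g$nodes), paste(names(cnt), cnt, sep = "=", collapse = ","), sep = "|")
}

#' Graph isomorphism on properly edge-colored graphs
#'
#' Seed-and-extend isomorphism test: after cheap early exits (node count and
#' per-label edge counts), an extension is launched from every pair of
#' equally-colored edges of the seed color; the PEC makes each extension
#' deterministic and linear, giving O(n^3) overall. Disconnected graphs are
#' handled by matching connected components with identical invariants.
#'
#' @param G,H `rna_graph` objects.
#' @return a bijection as a named integer vector (names = G node ids, values =
#'   H node ids), or `NULL` when the graphs are not isomorphic.
#' @export
are_isomorphic <- function(G, H) {
  if (length(G$nodes) != length(H$nodes)) return(NULL)
  if (nrow(G$edges) != nrow(H$edges)) return(NULL)
  cg <- sort(paste(G$edges$label))
  ch <- sort(paste(H$edges$label))
  if (!identical(cg, ch)) return(NULL)

  dict <- label_dict(G, H)
  compsG <- component_subgraphs(G)
  compsH <- component_subgraphs(H)
  if (length(compsG) != length(compsH)) return(NULL)
  sigG <- vapply(compsG, component_signature, character(1))
  sigH <- vapply(compsH, component_signature, character(1))
  if (!identical(sort(sigG), sort(sigH))) return(NULL)

  encsG <- lapply(compsG, encode_graph, dict = dict)
  encsH <- lapply(compsH, encode_graph, dict = dict)
  nC <- length(compsG)
  used <- logical(nC)
  assignment <- vector("list", nC)
  memo <- new.env(parent = emptyenv())

  comp_iso <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    eg <- encsG[[i]]; eh <- encsH[[j]]
    res <- if (nrow(eg$m) == 0) {
      # edgeless components are single nodes (backbone-free isolated nucleotides)
      if (eg$n == eh$n) cbind(seq_len(eg$n) - 1L, seq_len(eh$n) - 1L) else matrix(integer(0), 0, 2)
    } else {
      cpp_iso_connected(eg$n, eg$m, eh$n, eh$m)
    }
    memo[[key]] <- res
    res
  }

  solve <- function(i) {
    if (i > nC) return(TRUE)
    for (j in which(!used & sigH == sigG[i])) {
      m <- comp_iso(i, j)
      if (nrow(m) > 0 || (encsG[[i]]$n == 0)) {
        if (nrow(m) == 0 && encsG[[i]]$n > 0) next
        used[j] <<- TRUE
        assignment[[i]] <<- list(j = j, m = m)
        if (solve(i + 1)) return(TRUE)
        used[j] <<- FALSE
      }
    }
    FALSE
  }
  if (!solve(1)) return(NULL)

  out <- integer(0)
  nms <- integer(0)
  for (i in seq_len(nC)) {
    a <- assignment[[i]]
    m <- a$m
    nms <- c(nms, encsG[[i]]$nodes[m[, 1] + 1L])
    out <- c(out, encsH[[a$j]]$nodes[m[, 2] + 1L])
  }
  ord <- order(nms)
  stats::setNames(out[ord], nms[ord])
}

# ---- subgraph isomorphism ----------------------------------------------------

#' Subgraph isomorphism on properly edge-colored graphs
#'
#' Tests whether `G` occurs in `H`, i.e. whether there is an injection of
#' `V(G)` into `V(H)` under which every edge of `G` (with its label) is present
#' in `H`. Same seed-and-extend strategy as [are_isomorphic()]; thanks to the
#' PEC each seed forces a unique candidate injection, so the test is O(n^3)
#' with n the smaller node count. Disconnected patterns are placed component by
#' component with backtracking over disjoint images.
#'
#' @param G pattern `rna_graph`.
#' @param H host `rna_graph`.
#' @return an injection as a named integer vector (names = G node ids, values =
#'   H node ids), or `NULL`.
#' @export
is_subgraph <- function(G, H) {
  if (length(G$nodes) > length(H$nodes)) return(NULL)
  if (length(G$nodes) == 0) return(stats::setNames(integer(0), character(0)))
  dict <- label_dict(G, H)
  encH <- encode_graph(H, dict)
  comps <- component_subgraphs(G)
  has_edge <- vapply(comps, function(cc) nrow(cc$edges) > 0, logical(1))
  # larger / edge-bearing components first; isolated nodes last
  comps <- comps[order(-has_edge, -vapply(comps, function(cc) length(cc$nodes), integer(1)))]
  encs <- lapply(comps, encode_graph, dict = dict)

  place <- function(i, blocked) {
    if (i > length(comps)) return(list())
    enc <- encs[[i]]
    if (nrow(enc$m) == 0) {
      free <- setdiff(seq_len(encH$n) - 1L, blocked)
      if (length(free) < enc$n) return(NULL)
      img <- free[seq_len(enc$n)]
      rest <- place(i + 1, c(blocked, img))
      if (is.null(rest)) return(NULL)
      return(c(list(cbind(seq_len(enc$n) - 1L, img)), rest))
    }
    injs <- cpp_sub_connected(enc$n, enc$m, encH$n, encH$m,
                              as.integer(blocked), FALSE)
    for (m in injs) {
      rest <- place(i + 1, c(blocked, m[, 2]))
      if (!is.null(rest)) return(c(list(m), rest))
    }
    NULL
  }

  sol <- place(1, integer(0))
  if (is.null(sol)) return(NULL)
  nms <- integer(0); out <- integer(0)
  for (i in seq_along(comps)) {
    m <- sol[[i]]
    nms <- c(nms, encs[[i]]$nodes[m[, 1] + 1L])
    out <- c(out, encH$nodes[m[, 2] + 1L])
  }
  ord <- order(nms)
  stats::setNames(out[ord], nms[ord])
}

# ---- all maximal common subgraphs -------------------------------------------

# matched (label-agreeing) directed edges among matched pairs; map = named int
matched_edges <- function(G, H, map) {
  eg <- G$edges[G$edges$from %in% as.integer(names(map)) &
                  G$edges$to %in% as.integer(names(map)), , drop = FALSE]
  if (nrow(eg) == 0) return(tibble(from = integer(0), to = integer(0), label = character(0)))
  hf <- unname(map[as.character(eg$from)])
  ht <- unname(map[as.character(eg$to)])
  key_h <- paste(H$edges$from, H$edges$to, H$edges$label, sep = "\r")
  ok <- paste(hf, ht, eg$label, sep = "\r") %in% key_h
  eg[ok, , drop = FALSE]
}

#' All maximal connected common subgraphs
#'
#' Enumerates every maximal connected common subgraph (with at least one edge)
#' of two PEC graphs. An extension is seeded from every pair of
#' equally-labelled edges; conflicts met along the way do not abort the
#' extension (it still completes into one maximal common subgraph) but each
#' spawns a new branch replayed from the same seed under an extra constraint
#' forbidding the blocking pair, so that the alternative matching suggested by
#' the discrepancy is explored too. Branch results are deduplicated by their
#' pair sets and audited for maximality.
#'
#' @param G,H `rna_graph` objects.
#' @param cap safety cap on the number of branches explored per seed-edge pair
#'   family (default 1e6); exceeding it is an error.
#' @return list of `common_subgraph` objects, each with `pairs` (tibble of
#'   matched node pairs `g`,`h`) and `edges` (the matched directed G-edges;
#'   their images under the pair map are the matched H-edges).
#' @export
all_maximal_common_subgraphs <- function(G, H, cap = 1e6) {
  dict <- label_dict(G, H)
  encG <- encode_graph(G, dict)
  encH <- encode_graph(H, dict)
  mats <- cpp_all_mcs(encG$n, encG$m, encH$n, encH$m, cap)
  out <- lapply(mats, function(m) {
    pairs <- decode_pairs(m, encG, encH)
    map <- stats::setNames(pairs$h, pairs$g)
    structure(list(pairs = pairs, edges = matched_edges(G, H, map)),
              class = "common_subgraph")
  })
  out
}

#' @export
print.common_subgraph <- function(x, ...) {
  cat(sprintf("<common_subgraph> %d node pairs, %d matched directed edges\n",
              nrow(x$pairs), nrow(x$edges)))
  invisible(x)
}
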