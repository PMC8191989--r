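# Brute-force reference implementations for the three matching problems.
# They are deliberately independent of the extension-based production
# algorithms (plain backtracking over node assignments / exhaustive growth of
# pair sets) and are used only as ground truth in tests and in the acceptance
# checks; the production code never calls them.

oracle_edge_index <- function(g) {
  stats::setNames(as.list(g$edges$to),
                  paste(g$edges$from, g$edges$label, sep = "\r"))
}

oracle_edge_set <- function(g) {
  paste(g$edges$from, g$edges$to, g$edges$label, sep = "\r")
}

#' Brute-force matching oracles
#'
#' `oracle_isomorphic()` and `oracle_subgraph()` search over all node
#' assignments with incremental pruning; `oracle_all_mcs()` exhaustively grows
#' every connected label-preserving partial injection and keeps the
#' non-extendable ones. All three are exponential and guarded by a size bound;
#' they exist as independent ground truth for the PEC-based algorithms.
#'
#' @param G,H `rna_graph` objects with at most `max_nodes` nodes.
#' @param max_nodes hard size bound.
#' @return `oracle_isomorphic()`/`oracle_subgraph()`: `TRUE`/`FALSE`;
#'   `oracle_all_mcs()`: sorted character vector of canonical result keys, one
#'   per maximal connected common subgraph (with >= 1 edge), each of the form
#'   `"g1:h1 g2:h2 ..."` over the matched pairs.
#' @export
oracle_isomorphic <- function(G, H, max_nodes = 10) {
  ng <- length(G$nodes); nh <- length(H$nodes)
  if (ng > max_nodes || nh > max_nodes) abort("oracle size bound exceeded")
  if (ng != nh) return(FALSE)
  if (nrow(G$edges) != nrow(H$edges)) return(FALSE)
  eh <- oracle_edge_set(H)
  eg_set <- oracle_edge_set(G)
  eg <- G$edges
  gn <- G$nodes; hn <- H$nodes
  assign_next <- function(map, used) {
    k <- length(map) + 1
    if (k > ng) return(TRUE)
    for (c in which(!used)) {
      map2 <- c(map, hn[c])
      ok <- TRUE
      # check all G-edges with both ends assigned, in both directions
      for (r in which((eg$from == gn[k] & eg$to %in% gn[seq_len(k)]) |
                      (eg$to == gn[k] & eg$from %in% gn[seq_len(k)]))) {
        fi <- map2[match(eg$from[r], gn)]
        ti <- map2[match(eg$to[r], gn)]
        if (!(paste(fi, ti, eg$label[r], sep = "\r") %in% eh)) { ok <- FALSE; break }
      }
      if (ok) {
        # reverse direction: H-edges between assigned images must exist in G
        imgs <- map2
        sub_h <- H$edges[H$edges$from %in% imgs & H$edges$to %in% imgs, , drop = FALSE]
        back <- paste(gn[match(sub_h$from, imgs)], gn[match(sub_h$to, imgs)],
                      sub_h$label, sep = "\r")
        if (!all(back %in% eg_set)) ok <- FALSE
      }
      if (ok) {
        used[c] <- TRUE
        if (assign_next(map2, used)) return(TRUE)
        used[c] <- FALSE
      }
    }
    FALSE
  }
  assign_next(integer(0), logical(nh))
}

#' @rdname oracle_isomorphic
#' @export
oracle_subgraph <- function(G, H, max_nodes = 10) {
  ng <- length(G$nodes); nh <- length(H$nodes)
  if (ng > max_nodes || nh > max_nodes) abort("oracle size bound exceeded")
  if (ng > nh) return(FALSE)
  eh <- oracle_edge_set(H)
  eg <- G$edges
  gn <- G$nodes; hn <- H$nodes
  assign_next <- function(map, used) {
    k <- length(map) + 1
    if (k > ng) return(TRUE)
    for (c in which(!used)) {
      map2 <- c(map, hn[c])
      ok <- TRUE
      for (r in which((eg$from == gn[k] & eg$to %in% gn[seq_len(k)]) |
                      (eg$to == gn[k] & eg$from %in% gn[seq_len(k)]))) {
        fi <- map2[match(eg$from[r], gn)]
        ti <- map2[match(eg$to[r], gn)]
        if (!(paste(fi, ti, eg$label[r], sep = "\r") %in% eh)) { ok <- FALSE; break }
      }
      if (ok) {
        used[c] <- TRUE
        if (assign_next(map2, used)) return(TRUE)
        used[c] <- FALSE
      }
    }
    FALSE
  }
  assign_next(integer(0), logical(nh))
}

#' @rdname oracle_isomorphic
#' @export
oracle_all_mcs <- function(G, H, max_nodes = 10) {
  ng <- length(G$nodes); nh <- length(H$nodes)
  if (ng > max_nodes || nh > max_nodes) abort("oracle size bound exceeded")
  gn <- G$nodes; hn <- H$nodes
  eh <- oracle_edge_set(H)

  # label-agreeing edge between pair (g1,h1) and (g2,h2)?
  ge <- G$edges
  agree <- function(g1, h1, g2, h2) {
    rows <- which(ge$from == g1 & ge$to == g2)
    any(paste(h1, h2, ge$label[rows], sep = "\r") %in% eh)
  }

  results <- new.env(parent = emptyenv())
  visited <- new.env(parent = emptyenv())

  grow <- function(pairs) {
    # pairs: 2-col matrix (g, h), sorted by g then h
    key <- paste(paste(pairs[, 1], pairs[, 2], sep = ":"), collapse = " ")
    if (!is.null(visited[[key]])) return(invisible())
    visited[[key]] <- TRUE
    gs <- pairs[, 1]; hs <- pairs[, 2]
    ext <- list()
    for (g2 in setdiff(gn, gs)) for (h2 in setdiff(hn, hs)) {
      touches <- any(vapply(seq_len(nrow(pairs)), function(r) {
        agree(gs[r], hs[r], g2, h2) || agree(g2, h2, gs[r], hs[r])
      }, logical(1)))
      if (touches) ext[[length(ext) + 1]] <- c(g2, h2)
    }
    if (length(ext) == 0) {
      results[[key]] <- TRUE
      return(invisible())
    }
    for (e in ext) {
      np <- rbind(pairs, e)
      np <- np[order(np[, 1], np[, 2]), , drop = FALSE]
      grow(np)
    }
  }

  for (r1 in which(G$edges$from < G$edges$to)) {
    g1 <- G$edges$from[r1]; g2 <- G$edges$to[r1]
    for (r2 in seq_len(nrow(H$edges))) {
      h1 <- H$edges$from[r2]; h2 <- H$edges$to[r2]
      # both orientations are covered because H edges are enumerated directed
      if (agree(g1, h1, g2, h2)) {
        grow(matrix(c(g1, h1, g2, h2), 2, 2, byrow = TRUE))
      }
    }
  }
  sort(ls(results))
}
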