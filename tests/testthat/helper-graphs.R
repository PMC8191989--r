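# shared fixture builders for the matching and rule tests (built in code)

# canonical key of a common subgraph, for comparisons against the oracle
cs_key <- function(cs) {
  paste(paste(cs$pairs$g, cs$pairs$h, sep = ":"), collapse = " ")
}

mcs_keys <- function(res) sort(vapply(res, cs_key, character(1)))

# a triangle of three pairwise interactions (all nodes on a cycle)
triangle_graph <- function(id = "tri") {
  g <- rna_graph(id, n = 3)
  g <- add_interaction(g, 0, 1, edge_label("tHS"))
  g <- add_interaction(g, 1, 2, edge_label("tWS"))
  g <- add_interaction(g, 2, 0, edge_label("cWH"))
  g
}

# two squares fused along one shared edge (all six nodes on cycles)
fused_squares_graph <- function(id = "fused") {
  g <- rna_graph(id, n = 6)
  g <- add_interaction(g, 0, 1, edge_label("tHS"))
  g <- add_interaction(g, 1, 2, edge_label("tSS"))
  g <- add_interaction(g, 2, 3, edge_label("tHS"))
  g <- add_interaction(g, 3, 0, edge_label("tSS"))
  g <- add_interaction(g, 2, 4, edge_label("cWH"))
  g <- add_interaction(g, 4, 5, edge_label("tWW"))
  g <- add_interaction(g, 5, 3, edge_label("cWH"))
  g
}

# apply a node permutation (perm[k+1] = new id of node k) to a 0..n-1 graph
permute_graph <- function(g, perm) {
  h <- g
  h$edges <- tibble::tibble(
    from = perm[g$edges$from + 1],
    to = perm[g$edges$to + 1],
    label = g$edges$label
  )
  h
}

# does a named injection map respect all edges of g inside h?
injection_respects_edges <- function(map, g, h) {
  key_h <- paste(h$edges$from, h$edges$to, h$edges$label)
  all(paste(map[as.character(g$edges$from)],
            map[as.character(g$edges$to)],
            g$edges$label) %in% key_h)
}

random_graph_pair <- function(k, n_range = 3:7) {
  labs <- edge_label(c("cWW", "tHS", "tSS", "cHW"))
  g <- random_pec_graph(sample(n_range, 1), labels = sample(labs, sample(2:4, 1)),
                        density = stats::runif(1, 0.2, 0.7),
                        connected = k %% 2 == 0, id = "g")
  h <- random_pec_graph(sample(n_range, 1), labels = sample(labs, sample(2:4, 1)),
                        density = stats::runif(1, 0.2, 0.7),
                        connected = k %% 3 == 0, id = "h")
  list(g = g, h = h)
}

# a pure 5-bp cWW hairpin stem chain graph
pure_stem_graph <- function() {
  ch <- parse_fr3d(data.frame(chain = "S", i = 1:5, j = 16:12, lw = "cWW"),
                   length = 16)
  build_graph(ch)[[1]]
}
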