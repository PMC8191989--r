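test_that("extension is forced by the coloring and reports discrepancies", {
  # star neighborhoods with distinct colors: a single forced assignment
  g <- rna_graph("g", n = 4)
  g <- add_interaction(g, 0, 1, edge_label("cWH"))
  g <- add_interaction(g, 0, 2, edge_label("tHS"))
  g <- add_interaction(g, 0, 3, edge_label("tSS"))
  h <- permute_graph(g, c(2, 0, 3, 1))
  res <- extend_matching(g, h, seed = cbind(0, 2), mode = "strict")
  expect_false(res$failed)
  expect_equal(nrow(res$mapping), 4)
  expect_true(injection_respects_edges(
    stats::setNames(res$mapping$h, res$mapping$g), g, h))

  # seed on isolated matched nodes with no shared-label edges: unchanged
  g2 <- rna_graph("g2", n = 3)
  g2 <- add_interaction(g2, 1, 2, edge_label("tHS"))
  h2 <- rna_graph("h2", n = 3)
  h2 <- add_interaction(h2, 1, 2, edge_label("tWW"))
  res2 <- extend_matching(g2, h2, seed = cbind(0, 0), mode = "permissive")
  expect_equal(nrow(res2$mapping), 1)

  # incompatible neighborhoods: permissive mode records the discrepancy and
  # still returns a maximal matching; strict mode fails fast
  g3 <- triangle_graph("g3")
  h3 <- rna_graph("h3", n = 4)
  h3 <- add_interaction(h3, 0, 1, edge_label("tHS"))
  h3 <- add_interaction(h3, 1, 2, edge_label("tWS"))
  h3 <- add_interaction(h3, 2, 3, edge_label("cWH"))  # closes on 3, not 0
  resp <- extend_matching(g3, h3, seed = cbind(c(0, 1), c(0, 1)), mode = "permissive")
  expect_false(resp$failed)
  expect_gte(nrow(resp$discrepancies), 1)
  expect_true(resp$maximal)
  ress <- extend_matching(g3, h3, seed = cbind(c(0, 1), c(0, 1)), mode = "strict")
  expect_true(ress$failed)
})

test_that("extension results are invariant under node relabeling", {
  set.seed(17)
  for (k in 1:15) {
    pair <- random_graph_pair(k, n_range = 5:7)
    g <- pair$g; h <- pair$h
    base <- mcs_keys(all_maximal_common_subgraphs(g, h))
    perm_g <- sample(seq_along(g$nodes)) - 1L
    perm_h <- sample(seq_along(h$nodes)) - 1L
    gp <- permute_graph(g, perm_g)
    hp <- permute_graph(h, perm_h)
    shuffled <- all_maximal_common_subgraphs(gp, hp)
    # translate back into original coordinates
    back <- lapply(shuffled, function(cs) {
      cs$pairs$g <- match(cs$pairs$g, perm_g) - 1L
      cs$pairs$h <- match(cs$pairs$h, perm_h) - 1L
      cs$pairs <- cs$pairs[order(cs$pairs$g, cs$pairs$h), ]
      cs
    })
    expect_identical(sort(vapply(back, cs_key, character(1))), base)
  }
})

test_that("seed color minimises the edge-pair product with lexicographic ties", {
  g <- rna_graph("g", n = 12)
  for (k in 0:4) g <- add_interaction(g, 2 * k, 2 * k + 1, edge_label("cWW"))
  g <- add_interaction(g, 0, 11, edge_label("tHS"))
  h <- g
  expect_equal(pick_seed_color(g, h), "tHS/local")  # 1 < 25

  d1 <- rna_graph("d1", n = 2); d1 <- add_interaction(d1, 0, 1, edge_label("tHS"))
  d2 <- rna_graph("d2", n = 2); d2 <- add_interaction(d2, 0, 1, edge_label("tWW"))
  expect_true(is.na(pick_seed_color(d1, d2)))  # no shared label: no-seed

  e1 <- rna_graph("e1", n = 4)
  e1 <- add_interaction(e1, 0, 1, edge_label("tWW"))
  e1 <- add_interaction(e1, 2, 3, edge_label("cWH"))
  expect_equal(pick_seed_color(e1, e1), "cHW/local")  # tie: lexicographic
})

test_that("isomorphism finds bijections and rejects label changes", {
  set.seed(23)
  for (k in 1:15) {
    g <- random_pec_graph(sample(4:8, 1), density = 0.5, connected = k %% 2 == 0)
    perm <- sample(seq_along(g$nodes)) - 1L
    h <- permute_graph(g, perm)
    m <- are_isomorphic(g, h)
    expect_false(is.null(m))
    expect_true(injection_respects_edges(m, g, h))

    # flip one interaction's label: no longer isomorphic
    h2 <- h
    r <- which(h2$edges$label == h2$edges$label[1])[1]
    tw <- which(h2$edges$from == h2$edges$to[r] & h2$edges$to == h2$edges$from[r] &
                  h2$edges$label == iota(h2$edges$label[r]))[1]
    new_lab <- if (label_geometry(h2$edges$label[r]) == "tHH") "tSS" else "tHH"
    h2$edges$label[r] <- edge_label(new_lab, label_range(h2$edges$label[r]))
    h2$edges$label[tw] <- iota(h2$edges$label[r])
    expect_null(are_isomorphic(g, h2))
  }
})

test_that("subgraph isomorphism embeds planted patterns and certifies them", {
  set.seed(29)
  found <- 0
  for (k in 1:15) {
    g <- random_pec_graph(8, density = 0.5, connected = TRUE)
    perm <- sample(seq_along(g$nodes)) - 1L
    h <- permute_graph(g, perm)
    sub <- subgraph_nodes(g, sample(g$nodes, 5))  # may be disconnected
    inj <- is_subgraph(sub, h)
    expect_false(is.null(inj))  # induced piece of g must embed in permuted g
    expect_true(injection_respects_edges(inj, sub, h))
    found <- found + 1
  }
  expect_equal(found, 15)
  # identity embedding
  tri <- triangle_graph()
  expect_false(is.null(is_subgraph(tri, tri)))
  # a single-edge pattern in a host containing that label
  p <- rna_graph("p", n = 2); p <- add_interaction(p, 0, 1, edge_label("tSS"))
  expect_false(is.null(is_subgraph(p, fused_squares_graph())))
})

test_that("the three matching operations agree with brute-force oracles", {
  set.seed(42)
  for (k in 1:60) {
    pair <- random_graph_pair(k)
    expect_identical(unname(mcs_keys(all_maximal_common_subgraphs(pair$g, pair$h))),
                     unname(oracle_all_mcs(pair$g, pair$h)))
    expect_equal(!is.null(are_isomorphic(pair$g, pair$h)),
                 oracle_isomorphic(pair$g, pair$h))
    expect_equal(!is.null(is_subgraph(pair$g, pair$h)),
                 oracle_subgraph(pair$g, pair$h))
  }
})

test_that("isomorphism calls agree with an independent general-purpose matcher", {
  # igraph's VF2 with edge colors as an external cross-check (tests only)
  to_igraph_colored <- function(g) {
    dict <- sort(unique(g$edges$label))
    ig <- igraph::make_empty_graph(length(g$nodes), directed = TRUE)
    if (nrow(g$edges) > 0) {
      ig <- igraph::add_edges(ig, rbind(g$edges$from + 1L, g$edges$to + 1L))
    }
    list(ig = ig, col = match(g$edges$label, dict))
  }
  set.seed(57)
  for (k in 1:20) {
    g <- random_pec_graph(sample(4:7, 1), density = 0.5, connected = TRUE, id = "g")
    h <- if (k %% 2 == 0) {
      permute_graph(g, sample(seq_along(g$nodes)) - 1L)
    } else {
      random_pec_graph(length(g$nodes), density = 0.5, connected = TRUE, id = "h")
    }
    if (nrow(g$edges) != nrow(h$edges)) next
    both <- sort(unique(c(g$edges$label, h$edges$label)))
    cg <- match(g$edges$label, both); ch <- match(h$edges$label, both)
    ig <- to_igraph_colored(g)$ig; ih <- to_igraph_colored(h)$ig
    ref <- igraph::isomorphic(ig, ih, method = "vf2",
                              edge.color1 = cg, edge.color2 = ch)
    expect_equal(!is.null(are_isomorphic(g, h)), ref)
  }
})

test_that("enumerated common subgraphs are connected, maximal and duplicate-free", {
  set.seed(71)
  for (k in 1:25) {
    pair <- random_graph_pair(k, n_range = 4:7)
    res <- all_maximal_common_subgraphs(pair$g, pair$h)
    keys <- vapply(res, cs_key, character(1))
    expect_equal(anyDuplicated(keys), 0)
    pair_sets <- lapply(res, function(cs) paste(cs$pairs$g, cs$pairs$h))
    for (a in seq_along(res)) {
      cs <- res[[a]]
      expect_gte(nrow(cs$edges), 1)
      # label-consistency: every matched edge exists in H under the pair map
      map <- stats::setNames(cs$pairs$h, cs$pairs$g)
      sg <- pair$g; sg$nodes <- sort(cs$pairs$g); sg$edges <- cs$edges
      expect_true(injection_respects_edges(map, sg, pair$h))
      # connectivity of the matched subgraph
      expect_length(rinnet:::graph_components(sg), 1)
      # pairwise non-nesting
      for (b in seq_along(res)) {
        if (a != b) expect_false(all(pair_sets[[a]] %in% pair_sets[[b]]))
      }
      # non-extendability: no free compatible pair touches the matching
      gset <- cs$pairs$g; hset <- cs$pairs$h
      eg <- pair$g$edges; eh_key <- paste(pair$h$edges$from, pair$h$edges$to,
                                          pair$h$edges$label)
      for (r in which(eg$from %in% gset & !(eg$to %in% gset))) {
        hfrom <- map[as.character(eg$from[r])]
        cand <- pair$h$edges[pair$h$edges$from == hfrom &
                               pair$h$edges$label == eg$label[r], ]
        if (nrow(cand) == 1 && !(cand$to %in% hset)) {
          fail(sprintf("extendable matching in case %d", k))
        }
      }
    }
  }
})

test_that("enumeration is symmetric in its two arguments", {
  set.seed(83)
  for (k in 1:20) {
    pair <- random_graph_pair(k)
    ab <- mcs_keys(all_maximal_common_subgraphs(pair$g, pair$h))
    ba <- sort(vapply(all_maximal_common_subgraphs(pair$h, pair$g), function(cs) {
      paste(sort(paste(cs$pairs$h, cs$pairs$g, sep = ":")), collapse = " ")
    }, character(1)))
    ab_resorted <- sort(vapply(strsplit(ab, " "), function(x) paste(sort(x), collapse = " "),
                               character(1)))
    expect_identical(ab_resorted, ba)
  }
})

test_that("whole-graph self-matching is the unique result when labels are unique", {
  g <- triangle_graph()  # three distinct asymmetric labels: every color class
  # holds a single edge, so only the identity seed exists
  res <- all_maximal_common_subgraphs(g, g)
  expect_length(res, 1)
  expect_equal(nrow(res[[1]]$pairs), 3)
  expect_identical(res[[1]]$pairs$g, res[[1]]$pairs$h)
})
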