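test_that("rule presets encode the class definitions", {
  abc <- rin_rules("abc")
  expect_true(abc$require_cycles && abc$forbid_pure_stack_extension &&
                abc$require_basepair_per_node)
  expect_equal(abc$min_long_range, 2)
  expect_equal(abc$sse_span, 2)
  ab <- rin_rules("ab")
  expect_null(ab$sse_span)
  expect_equal(ab$min_long_range, 2)
  a <- rin_rules("a")
  expect_equal(a$min_long_range, 0)
  expect_null(a$sse_span)
  loc <- rin_rules("local_modules")
  expect_false(loc$require_basepair_per_node)  # rule z relaxed (bulges allowed)
  expect_equal(loc$max_long_range, 0)
  custom <- rin_rules("ab", min_long_range = 3)
  expect_equal(custom$min_long_range, 3)
})

test_that("rule x returns exactly the nodes lying on undirected cycles", {
  expect_equal(rule_x_nodes_in_cycles(triangle_graph()), c(0, 1, 2))
  # a tree has no cycle
  tree <- rna_graph("tree", n = 4)
  tree <- add_interaction(tree, 0, 1, edge_label("tHS"))
  tree <- add_interaction(tree, 1, 2, edge_label("tSS"))
  tree <- add_interaction(tree, 1, 3, edge_label("cWH"))
  expect_length(rule_x_nodes_in_cycles(tree), 0)
  # two fused squares sharing an edge: all six nodes
  expect_equal(rule_x_nodes_in_cycles(fused_squares_graph()), 0:5)
  # cycle plus a dangling node: dangling excluded
  dang <- add_interaction(triangle_graph("d"), 0, 1, edge_label("b53")) # already has pair 0-1
  dang$nodes <- c(dang$nodes, 3L)
  dang <- add_interaction(dang, 2, 3, edge_label("tWW"))
  expect_equal(rule_x_nodes_in_cycles(dang), c(0, 1, 2))
})

test_that("rule y flags exactly the unwitnessed local canonical pairs", {
  # cWW pair whose partner's neighbor has a tHS edge: witnessed
  g <- rna_graph("w", n = 6)
  g <- add_interaction(g, 0, 5, edge_label("cWW"))
  g <- add_interaction(g, 0, 1, edge_label("b53"))
  g <- add_interaction(g, 1, 4, edge_label("tHS"))
  expect_equal(nrow(rule_y_check(g)), 0)

  # interior pairs of a pure 4-bp stack: all violating
  stem <- parse_fr3d(data.frame(chain = "S", i = 1:4, j = 12:9, lw = "cWW"),
                     length = 12)
  sg <- build_graph(stem)[[1]]
  v <- rule_y_check(sg)
  expect_equal(nrow(v), 4)

  # a long-range cWW neighbor qualifies as witness
  g2 <- rna_graph("lr", n = 8)
  g2 <- add_interaction(g2, 0, 7, edge_label("cWW"))
  g2 <- add_interaction(g2, 0, 1, edge_label("b53"))
  g2 <- add_interaction(g2, 1, 5, edge_label("cWW", "long_range"))
  v2 <- rule_y_check(g2)
  expect_false(any(v2$a == 0 & v2$b == 7))
  # the long-range cWW itself is not subject to rule y
  expect_false(any(v2$a == 1 & v2$b == 5))
})

test_that("prefilter empties rule-violating structure and keeps motif cores", {
  # a pure 5-bp stem with backbone reduces to nothing
  expect_length(prefilter(pure_stem_graph(), rin_rules("abc"))$nodes, 0)

  # dangling backbone-only nodes are removed, the planted core is intact
  fx <- plant_motif(fixture_spec(n_chains = 2, copies = c(aminor = 2),
                                 extra_hairpins = 1, seed = 19))
  rules <- rin_rules("abc")
  pf <- prefilter(fx$graphs[[1]], rules)
  core6 <- fx$truth$abc[[1]][[2]]
  expect_true(all(core6 %in% pf$nodes))
  # rule z holds on the prefiltered graph: every node keeps a basepair
  paired <- unique(pf$edges$from[is_pair_label(pf$edges$label)])
  expect_setequal(pf$nodes, paired)
  expect_lt(length(pf$nodes), length(fx$graphs[[1]]$nodes) / 2)
})

test_that("extraction applies long-range and SSE-span rules per component", {
  fx <- plant_motif(fixture_spec(n_chains = 2, copies = c(tripod = 2),
                                 extra_hairpins = 0, seed = 23))
  g1 <- prefilter(fx$graphs[[1]], rin_rules("ab"))
  g2 <- prefilter(fx$graphs[[2]], rin_rules("ab"))
  mcss <- all_maximal_common_subgraphs(g1, g2)
  # tripod spans 3 SSEs: rejected under abc (rule c), kept under ab
  got_ab <- unlist(lapply(mcss, function(m)
    length(extract_rins(m, rin_rules("ab"), fx$graphs[[1]], fx$graphs[[2]]))))
  got_abc <- unlist(lapply(mcss, function(m)
    length(extract_rins(m, rin_rules("abc"), fx$graphs[[1]], fx$graphs[[2]]))))
  expect_gte(sum(got_ab), 1)
  expect_equal(sum(got_abc), 0)

  # a component with fewer long-range interactions than rule b demands is
  # rejected; with min_long_range = 0 it is kept
  fx2 <- plant_motif(fixture_spec(n_chains = 2, copies = c(loop_cycle = 2),
                                  extra_hairpins = 0, seed = 29))
  ga <- prefilter(fx2$graphs[[1]], rin_rules("a"))
  gb <- prefilter(fx2$graphs[[2]], rin_rules("a"))
  mcs2 <- all_maximal_common_subgraphs(ga, gb)
  kept_a <- sum(unlist(lapply(mcs2, function(m)
    length(extract_rins(m, rin_rules("a"), fx2$graphs[[1]], fx2$graphs[[2]])))))
  kept_ab <- sum(unlist(lapply(mcs2, function(m)
    length(extract_rins(m, rin_rules("ab"), fx2$graphs[[1]], fx2$graphs[[2]])))))
  expect_gte(kept_a, 1)
  expect_equal(kept_ab, 0)
})
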