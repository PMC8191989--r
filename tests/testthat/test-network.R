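# a hand-built catalog of nested motifs: triangle < triangle+pendant-cycle
toy_catalog <- function() {
  g1 <- triangle_graph("s1")
  g2 <- fused_squares_graph("s2")
  # g3: the triangle with one extra interaction closing a second cycle
  g3 <- add_interaction(triangle_graph("s3"), 0, 1, edge_label("tWW"))
  fake_rin <- function(g, k) {
    structure(list(catalog_id = k, graph = g,
                   occurrences = stats::setNames(
                     list(list(graph_id = paste0("G", k), chain = paste0("G", k),
                               nodes = g$nodes, injection = NULL, sse_span = NA)),
                     paste0("G", k, ":x")),
                   n_long_range = 0), class = "rin")
  }
  structure(list(rins = list(fake_rin(g1, 1L), fake_rin(g3, 2L), fake_rin(g2, 3L)),
                 rules = rin_rules("a"),
                 manifest = tibble::tibble(graph_id = character(0),
                                           chain = character(0),
                                           n_nodes = integer(0))),
            class = "rin_catalog")
}

test_that("inclusion edges are exact and certified by injections", {
  ct <- toy_catalog()
  nw <- build_network(ct)
  # triangle < triangle+cycle; mutually non-included motifs stay unlinked
  expect_true(any(nw$edges$from == 1 & nw$edges$to == 2))
  expect_false(any(nw$edges$from == 1 & nw$edges$to == 3))
  expect_false(any(nw$edges$to == 1))
  for (k in seq_len(nrow(nw$edges))) {
    key <- paste0(nw$edges$from[k], "->", nw$edges$to[k])
    inj <- nw$injections[[key]]
    small <- ct$rins[[nw$edges$from[k]]]$graph
    big <- ct$rins[[nw$edges$to[k]]]$graph
    expect_true(injection_respects_edges(inj, small, big))
  }
})

test_that("an inclusion chain gains all transitive edges, then reduces", {
  # A < B < C by construction: A = single-cycle square, B = A plus a pendant
  # cycle, C = B plus one more interaction
  a <- rna_graph("a", n = 4)
  a <- add_interaction(a, 0, 1, edge_label("tHS"))
  a <- add_interaction(a, 1, 2, edge_label("tWS"))
  a <- add_interaction(a, 2, 3, edge_label("cWH"))
  a <- add_interaction(a, 3, 0, edge_label("tWW"))
  b <- a; b$id <- "b"
  b <- add_interaction(b, 0, 2, edge_label("cSS"))
  cg <- b; cg$id <- "c"
  cg <- add_interaction(cg, 1, 3, edge_label("cHH"))
  fake <- function(g, k) structure(
    list(catalog_id = k, graph = g, occurrences = list(), n_long_range = 0),
    class = "rin")
  ct <- structure(list(rins = list(fake(a, 1L), fake(b, 2L), fake(cg, 3L)),
                       rules = rin_rules("a"),
                       manifest = tibble::tibble()), class = "rin_catalog")
  nw <- build_network(ct)
  expect_equal(nrow(nw$edges), 3)  # 1->2, 1->3, 2->3 before reduction
  red <- transitive_reduce(nw)
  expect_equal(nrow(red$edges), 2)
  expect_false(any(red$edges$from == 1 & red$edges$to == 3))
  # idempotence
  expect_identical(transitive_reduce(red)$edges, red$edges)
})

test_that("transitive reduction preserves reachability on random DAGs", {
  closure <- function(nodes, edges) rinnet:::reachability_matrix(nodes, edges)
  set.seed(37)
  for (k in 1:25) {
    n <- sample(4:9, 1)
    nodes <- seq_len(n)
    # random DAG: edges only from smaller to larger id
    all_pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    take <- all_pairs[stats::runif(nrow(all_pairs)) < 0.4, , drop = FALSE]
    nw <- structure(list(nodes = nodes,
                         edges = tibble::tibble(from = take[, 1], to = take[, 2]),
                         injections = list(), reduced = FALSE),
                    class = "rin_network")
    red <- transitive_reduce(nw)
    expect_identical(closure(nodes, red$edges), closure(nodes, nw$edges))
    expect_lte(nrow(red$edges), nrow(nw$edges))
  }
  # a cycle is rejected
  bad <- structure(list(nodes = 1:2,
                        edges = tibble::tibble(from = c(1, 2), to = c(2, 1)),
                        injections = list(), reduced = FALSE),
                   class = "rin_network")
  expect_error(transitive_reduce(bad), "cycle")
})

test_that("component statistics summarise the inclusion landscape", {
  edgeless <- structure(list(nodes = 1:5, edges = tibble::tibble(from = integer(0),
                                                                 to = integer(0)),
                             injections = list(), reduced = FALSE),
                        class = "rin_network")
  st <- component_stats(edgeless)
  expect_equal(st$n_components, 5)
  expect_equal(st$n_singletons, 5)
  expect_equal(st$giant_size, 1)

  # three meshes: 4+3+2 nodes plus one singleton
  e <- tibble::tibble(from = c(1, 2, 3, 5, 6, 8), to = c(2, 3, 4, 6, 7, 9))
  meshy <- structure(list(nodes = 1:10, edges = e, injections = list(),
                          reduced = FALSE), class = "rin_network")
  st2 <- component_stats(meshy)
  expect_equal(st2$n_components, 4)
  expect_equal(st2$giant_size, 4)
  expect_equal(st2$giant_fraction, 0.4)
  expect_equal(st2$component_sizes[[1]], c(4, 3, 2, 1))
})

test_that("a planted inclusion hierarchy forms one giant component", {
  # nested catalog RINs from the aminor fixture: 4-node core inside the 6-node
  fx <- plant_motif(fixture_spec(n_chains = 3, copies = c(aminor = 3), seed = 11))
  ct <- run_corpus(fx$graphs, rin_rules("abc"))
  nw <- build_network(ct)
  st <- component_stats(nw)
  expect_equal(st$n_components, 1)
  expect_equal(st$giant_fraction, 1)
})

test_that("network DOT and JSON exports are well-formed", {
  ct <- toy_catalog()
  nw <- build_network(ct)
  pj <- withr::local_tempfile(fileext = ".json")
  write_network_json(nw, pj)
  obj <- jsonlite::read_json(pj)
  expect_equal(length(obj$nodes), 3)
  pd <- withr::local_tempfile(fileext = ".dot")
  write_network_dot(nw, pd)
  lines <- readLines(pd)
  expect_match(lines[1], "digraph")
  expect_equal(sum(grepl("->", lines)), nrow(nw$edges))
})
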