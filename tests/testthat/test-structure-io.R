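test_that("parse_fr3d normalises coordinates, mirrors and unknown codes", {
  ch <- parse_fr3d(data.frame(chain = "A", i = 3, j = 10, lw = "cWW"), length = 12)
  expect_equal(ch$pairs$i, 2)  # 1-based input, 0-based internal
  expect_equal(ch$pairs$j, 9)

  # duplicates and iota-mirrored rows collapse onto one pair
  tab <- data.frame(chain = "A",
                    i = c(3, 3, 10), j = c(10, 10, 3),
                    lw = c("cWH", "cWH", "cHW"))
  ch2 <- parse_fr3d(tab, length = 12)
  expect_equal(nrow(ch2$pairs), 1)
  expect_equal(ch2$pairs$lw, "cWH")

  expect_message(
    ch3 <- parse_fr3d(data.frame(chain = "A", i = c(1, 2), j = c(8, 7),
                                 lw = c("cWW", "ncWW")), length = 8),
    "non-canonical")
  expect_equal(nrow(ch3$pairs), 1)

  expect_error(parse_fr3d(data.frame(chain = c("A", "B"), i = 1, j = 5, lw = "cWW")),
               "mixes chains")
  # file input
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("chain,i,j,lw", "A,2,9,tHS"), path)
  ch4 <- parse_fr3d(path, length = 10)
  expect_equal(ch4$pairs$lw, "tHS")
})

test_that("double-cWW conflicts keep the pair in the largest stack", {
  # node 4 (0-based) in stacks of length 4 vs 1
  prs <- tibble::tibble(i = c(1, 2, 3, 4, 4), j = c(20, 19, 18, 17, 8), lw = "cWW")
  r <- resolve_double_cww(prs)
  expect_equal(nrow(r), 4)
  expect_false(any(r$i == 4 & r$j == 8))

  expect_identical(resolve_double_cww(prs[1:3, ]), prs[1:3, ])  # no conflicts

  # equal-length stacks: lexicographically smaller pair kept
  tie <- tibble::tibble(i = c(3, 3), j = c(9, 14), lw = "cWW")
  r2 <- resolve_double_cww(tie)
  expect_equal(r2$j, 9)
})

test_that("pseudoknot removal retains whole long stems and drops crossers", {
  nested <- tibble::tibble(i = c(0, 1, 3), j = c(9, 8, 6), lw = "cWW")
  pk <- remove_pseudoknots(nested)
  expect_equal(nrow(pk$nested), 3)
  expect_equal(nrow(pk$removed), 0)

  # crossing stems of lengths 3 and 1: the length-3 stem is retained
  # (max-retention answer checked by enumerating both alternatives by hand)
  cw <- tibble::tibble(i = c(0, 1, 2, 4), j = c(11, 10, 9, 13), lw = "cWW")
  pk2 <- remove_pseudoknots(cw)
  expect_equal(nrow(pk2$nested), 3)
  expect_equal(pk2$removed$i, 4)

  empty <- tibble::tibble(i = integer(0), j = integer(0), lw = character(0))
  pk3 <- remove_pseudoknots(empty)
  expect_equal(nrow(pk3$nested), 0)
  expect_equal(nrow(pk3$removed), 0)
})

test_that("no crossing pair survives pseudoknot removal (exhaustive check)", {
  set.seed(31)
  for (k in 1:25) {
    n <- 40
    i <- sample(0:(n - 2), 12, replace = TRUE)
    j <- pmin(n - 1, i + sample(2:20, 12, replace = TRUE))
    prs <- dplyr::distinct(tibble::tibble(i = i, j = j, lw = "cWW"))
    prs <- prs[prs$i < prs$j, ]
    prs <- resolve_double_cww(prs)
    kept <- remove_pseudoknots(prs)$nested
    if (nrow(kept) > 1) {
      for (a in 1:(nrow(kept) - 1)) for (b in (a + 1):nrow(kept)) {
        crossing <- (kept$i[a] < kept$i[b] & kept$i[b] < kept$j[a] & kept$j[a] < kept$j[b]) |
          (kept$i[b] < kept$i[a] & kept$i[a] < kept$j[b] & kept$j[b] < kept$j[a])
        expect_false(crossing)
      }
    }
  }
})

test_that("SSE decomposition labels stems and loops and covers every node", {
  # single hairpin: stem + hairpin loop (nodes 3-6)
  hp <- tibble::tibble(i = 0:2, j = 9:7, lw = "cWW")
  ss <- decompose_sses(hp, 10)
  expect_equal(ss$kind, c("stem", "hairpin"))
  expect_equal(which(ss$sse_of == 2) - 1, 3:6)

  # two stems separated on both strands: internal loop between them
  int <- tibble::tibble(i = c(0, 1, 4, 5), j = c(19, 18, 14, 13), lw = "cWW")
  ss2 <- decompose_sses(int, 20)
  expect_true("internal" %in% ss2$kind)

  # unpaired chain: one exterior SSE
  ss3 <- decompose_sses(hp[0, ], 10)
  expect_equal(ss3$kind, "exterior")
  expect_true(all(ss3$sse_of == 1))

  # multiloop: one enclosing stem with two child stems
  ml <- tibble::tibble(
    i = c(0, 1, 3, 4, 10, 11),
    j = c(24, 23, 8, 7, 16, 15), lw = "cWW")
  ss4 <- decompose_sses(ml, 25)
  expect_true("multi" %in% ss4$kind)

  # every node gets exactly one SSE, and SSE node counts sum to the length
  for (ss_k in list(ss, ss2, ss3, ss4)) {
    expect_false(anyNA(ss_k$sse_of))
    expect_equal(sum(table(ss_k$sse_of)), length(ss_k$sse_of))
  }
})

test_that("range classification is local for same/adjacent SSEs and symmetric", {
  hp2 <- tibble::tibble(i = c(0, 1, 12, 13), j = c(9, 8, 21, 20), lw = "cWW")
  ss <- decompose_sses(hp2, 24)
  # within one hairpin loop
  expect_equal(classify_range(3, 6, ss), "local")
  # stem to its own hairpin loop: adjacent SSEs
  expect_equal(classify_range(1, 4, ss), "local")
  # loop of hairpin 1 to loop of hairpin 2: distant SSEs
  expect_equal(classify_range(4, 16, ss), "long_range")
  # symmetry
  for (p in list(c(3, 6), c(1, 4), c(4, 16))) {
    expect_equal(classify_range(p[1], p[2], ss), classify_range(p[2], p[1], ss))
  }
})

test_that("build_graph assembles backbone, pairs, ranges and stays PEC-valid", {
  ch <- parse_fr3d(data.frame(chain = "A", i = 1, j = 4, lw = "cWW"), length = 4)
  gs <- build_graph(ch)
  expect_length(gs, 1)
  expect_equal(nrow(gs[[1]]$edges), 8)  # 3 backbone + 1 pair, both directions

  # a same-LW-edge conflict yields several PEC-valid graph versions
  tab <- data.frame(chain = "A", i = c(2, 2), j = c(8, 11), lw = "tHS")
  gs2 <- build_graph(parse_fr3d(tab, length = 12))
  expect_gt(length(gs2), 1)
  for (g in gs2) expect_length(validate_pec(g), 0)
  expect_equal(unique(vapply(gs2, function(g) g$chain, character(1))), "A")

  # long-range count: loop-loop contact between two hairpins is long-range
  tab3 <- data.frame(chain = "A",
                     i = c(1, 2, 13, 14, 5),
                     j = c(10, 9, 22, 21, 17),
                     lw = c("cWW", "cWW", "cWW", "cWW", "tSS"))
  g3 <- build_graph(parse_fr3d(tab3, length = 24))[[1]]
  lr <- g3$edges[rinnet:::label_range(g3$edges$label) == "long_range", ]
  expect_equal(nrow(lr), 2)  # one interaction, two directed edges
  expect_setequal(unique(rinnet:::label_geometry(lr$label)), "tSS")
})
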