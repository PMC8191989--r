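# ---- seeded random PEC graphs ------------------------------------------------

with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a random properly edge-colored graph
#'
#' Draws interactions uniformly among the feasible (node, label) slots: every
#' interaction `(u, v, L)` occupies the outgoing slot `L` at `u` and
#' `iota(L)` at `v`, so at most `n * length(labels) / 2` interactions fit.
#' Optionally a random backbone-like path is laid down first so the graph is
#' connected.
#'
#' @param n number of nodes.
#' @param labels character vector of edge labels to draw from (see
#'   [edge_label()]); twins are added automatically.
#' @param density target number of interactions as a fraction of the PEC
#'   maximum `n * length(labels) / 2`.
#' @param seed optional RNG seed (restores the caller's RNG state).
#' @param connected lay down a random spanning path first.
#' @param id graph id.
#' @return a PEC-valid `rna_graph`.
#' @export
random_pec_graph <- function(n, labels = edge_label(c("cWW", "tHS", "tSS")),
                             density = 0.3, seed = NULL, connected = FALSE,
                             id = "random") {
  check_label(labels)
  labels <- sort(unique(labels))
  max_int <- floor(n * length(labels) / 2)
  m_target <- round(density * n * length(labels) / 2)
  if (m_target > max_int) {
    abort(sprintf("density %.2f infeasible under the PEC (max %d interactions)",
                  density, max_int))
  }
  with_local_seed(seed, {
    g <- rna_graph(id, n = n)
    used <- new.env(parent = emptyenv())  # "node\rlabel" -> TRUE
    slot_free <- function(v, l) is.null(used[[paste(v, l, sep = "\r")]])
    take <- function(u, v, l) {
      used[[paste(u, l, sep = "\r")]] <- TRUE
      used[[paste(v, iota(l), sep = "\r")]] <- TRUE
      g <<- add_interaction(g, u, v, l, lenient = TRUE)
    }
    placed <- 0L
    if (connected && n > 1) {
      path <- sample(0:(n - 1))
      for (k in 1:(n - 1)) {
        u <- path[k]; v <- path[k + 1]
        ok <- labels[vapply(labels, function(l) slot_free(u, l) && slot_free(v, iota(l)),
                            logical(1))]
        if (length(ok) == 0) abort("cannot lay a connected path with these labels")
        take(u, v, sample(ok, 1))
        placed <- placed + 1L
      }
    }
    attempts <- 0L
    while (placed < m_target && attempts < 50 * (m_target + 1)) {
      attempts <- attempts + 1L
      uv <- sample(0:(n - 1), 2)
      l <- sample(labels, 1)
      if (!slot_free(uv[1], l) || !slot_free(uv[2], iota(l))) next
      if (any(g$edges$from == uv[1] & g$edges$to == uv[2] & g$edges$label == l)) next
      take(uv[1], uv[2], l)
      placed <- placed + 1L
    }
    g
  })
}

# ---- synthetic chains with planted motifs ------------------------------------

# A chain is assembled from hairpin-like units separated by unpaired spacers.
# Unit builders return length, internal cWW pairs (relative coordinates) and
# named anchor positions used to wire planted motifs.

unit_plain <- function(stem, loop) {
  list(kind = "plain", len = 2L * stem + loop,
       pairs = tibble(i = 0:(stem - 1), j = (2L * stem + loop - 1L):(stem + loop),
                      lw = "cWW"),
       anchors = list())
}

# donor/host hairpin: 2-bp stem, 5-nt loop; the anchor nucleotides sit at loop
# offsets 1-2, away from the stem, so the host stem stays unwitnessed and
# never enters any rule-valid core
unit_donor <- function() {
  u <- unit_plain(2L, 5L)
  u$kind <- "donor"
  u$anchors <- list(a = c(3L, 4L))
  u
}

# receptor hairpin with an exactly 2-bp stem: the planted tertiary contacts
# witness both stem pairs, so the whole stem survives rule-y pruning
unit_receptor <- function() {
  u <- unit_plain(2L, 4L)
  u$kind <- "receptor"
  u$anchors <- list(q = c(0L, 1L), t = c(6L, 7L))
  u
}

# hairpin with a 7-nt loop hosting a purely local module: a single trans pair
# closing a cycle over a bulged backbone run (kink-turn-like bulge topology)
unit_bulgeloop <- function() {
  u <- unit_plain(2L, 7L)
  u$kind <- "bulgeloop"
  u$pairs <- dplyr::bind_rows(u$pairs, tibble(i = 3L, j = 7L, lw = "tWH"))
  u$anchors <- list(core = 3:7)
  u
}

# hairpin with an 8-nt loop carrying two crossing cis non-canonical pairs that
# close a 4-cycle of paired nucleotides; fully local, no bulge required
unit_loopcycle <- function() {
  u <- unit_plain(2L, 8L)
  u$kind <- "loopcycle"
  u$pairs <- dplyr::bind_rows(u$pairs,
                              tibble(i = c(3L, 4L), j = c(6L, 7L),
                                     lw = c("cHS", "cSW")))
  u$anchors <- list(core_z = c(3L, 4L, 6L, 7L), core_local = 3:7)
  u
}

# Motif definitions: units consumed per copy, inter-unit pairs, and the
# hand-derived ground truth: for each rule preset, the list of rule-valid
# cores the pipeline distills one planted copy to (possibly several, possibly
# none). The single-cycle motifs (loop_clamp, tripod, bulge_loop) have no
# valid proper sub-network, so each contributes exactly one core; the
# stem-wired aminor additionally yields the 4-node donor/strand cycle that
# remains valid when the strand's cWW partners are stripped.
motif_defs <- function() {
  list(
    # two consecutive loop nucleotides clamping two consecutive nucleotides of
    # a distant hairpin loop with tSS pairs: one 4-cycle, 2 long-range
    # interactions, 2 SSEs -> valid for abc, ab and a
    loop_clamp = list(
      units = c("donor", "donor"),
      wire = function(anch) tibble(
        i = anch[[1]]$a, j = anch[[2]]$a,
        lw = "tSS"),
      truth = function(anch) {
        core <- list(sort(c(anch[[1]]$a, anch[[2]]$a)))
        list(abc = core, ab = core, a = core, local_modules = list())
      }
    ),
    # three hairpin loops joined into a single hexagonal cycle by three
    # distinct trans pairs: 3 long-range interactions over 3 SSEs -> breaks
    # rule c (abc) but valid for ab and a; no sub-cycle exists
    tripod = list(
      units = c("donor", "donor", "donor"),
      wire = function(anch) tibble(
        i = c(anch[[1]]$a[2], anch[[2]]$a[2], anch[[3]]$a[2]),
        j = c(anch[[2]]$a[1], anch[[3]]$a[1], anch[[1]]$a[1]),
        lw = c("tHH", "tWW", "tSH")),
      truth = function(anch) {
        core <- list(sort(c(anch[[1]]$a, anch[[2]]$a, anch[[3]]$a)))
        list(abc = list(), ab = core, a = core, local_modules = list())
      }
    ),
    # purely local module without bulges: two cis non-canonical pairs closing
    # a 4-cycle inside one hairpin loop; valid under preset a (0 long-range
    # interactions) and, with the intervening loop nucleotide, under
    # local_modules — but never under ab/abc (rule b)
    loop_cycle = list(
      units = "loopcycle",
      wire = function(anch) tibble(i = integer(0), j = integer(0), lw = character(0)),
      truth = function(anch) {
        list(abc = list(), ab = list(),
             a = list(sort(anch[[1]]$core_z)),
             local_modules = list(sort(anch[[1]]$core_local)))
      }
    ),
    # purely local loop module: a trans pair closing a 5-node cycle with three
    # backbone-only nucleotides; only valid when rule z is relaxed and
    # long-range interactions are not required
    bulge_loop = list(
      units = "bulgeloop",
      wire = function(anch) tibble(i = integer(0), j = integer(0), lw = character(0)),
      truth = function(anch) {
        core <- list(sort(anch[[1]]$core))
        list(abc = list(), ab = list(), a = list(), local_modules = core)
      }
    ),
    # classic A-minor-like wiring: two consecutive loop nucleotides contacting
    # the 5' strand of a 2-bp receptor stem with tSS pairs; the rule system
    # extracts both the full 6-node core (stem included, witnessed by the tSS
    # contacts) and the 4-node donor/strand cycle that stays valid when the
    # strand's partners are stripped by a discrepant matching
    aminor = list(
      units = c("donor", "receptor"),
      wire = function(anch) tibble(
        i = anch[[1]]$a, j = anch[[2]]$q,
        lw = "tSS"),
      truth = function(anch) {
        core4 <- sort(c(anch[[1]]$a, anch[[2]]$q))
        core6 <- sort(c(anch[[1]]$a, anch[[2]]$q, anch[[2]]$t))
        cores <- list(core4, core6)
        list(abc = cores, ab = cores, a = cores, local_modules = list())
      }
    ),
    # single-chain control: loop_clamp shape with its own labels, planted in
    # one chain only; recurrence must exclude it from every catalog
    solo = list(
      units = c("donor", "donor"),
      wire = function(anch) tibble(
        i = anch[[1]]$a, j = anch[[2]]$a,
        lw = "tWS"),
      truth = function(anch) list(abc = list(), ab = list(), a = list(),
                                  local_modules = list())
    )
  )
}

#' Specify a synthetic corpus with planted motifs
#'
#' Describes a corpus of toy RNA chains assembled from hairpin units separated
#' by unpaired spacers, with recurrent motifs planted across chains:
#' `loop_clamp` (a tSS loop-loop clamp: one 4-cycle, 2 long-range
#' interactions, 2 SSEs), `tripod` (three hairpin loops joined into one
#' hexagonal cycle, 3 long-range interactions, 3 SSEs), `bulge_loop` (a purely
#' local loop module whose cycle runs over bulged backbone-only nucleotides),
#' `aminor` (the classic wiring of two tSS contacts into the strand of a 2-bp
#' receptor stem), and `solo`, a single-chain control that recurrence must
#' exclude. Host stems and spacers never satisfy the rules, so the planted
#' cores are the only rule-valid recurrent structures.
#'
#' @param n_chains number of chains.
#' @param copies named integer vector: total copies per motif (each copy in a
#'   different chain, round-robin), for motifs `loop_clamp`, `tripod`,
#'   `bulge_loop`, `aminor`, `solo`. `solo` copies all land in the first
#'   chain.
#' @param extra_hairpins plain (motif-free) hairpin units added per chain.
#' @param spacer unpaired nucleotides between units and at the chain ends.
#' @param seed RNG seed; the same seed yields a byte-identical corpus.
#' @return a `fixture_spec`.
#' @export
fixture_spec <- function(n_chains = 10,
                         copies = c(loop_clamp = 4, tripod = 3, bulge_loop = 3,
                                    solo = 0),
                         extra_hairpins = 1, spacer = 2, seed = 1) {
  stopifnot(n_chains >= 2, all(names(copies) %in% names(motif_defs())))
  structure(list(n_chains = n_chains, copies = copies,
                 extra_hairpins = extra_hairpins, spacer = spacer, seed = seed),
            class = "fixture_spec")
}

#' Generate a planted-motif corpus with ground truth
#'
#' Assembles the chains described by a [fixture_spec()], builds their
#' PEC-valid structure graphs through the standard pipeline (secondary
#' structure, SSEs, range classification), and records every planted motif
#' occurrence: for each rule preset, the exact node sets that the rule system
#' distills the occurrence to (hand-derived from the rule semantics; e.g. the
#' bulged nucleotides of `bulge_loop` survive only when rule z is relaxed,
#' host stems never enter a core because their pairs are unwitnessed, and the
#' stem-wired `aminor` contributes two nested cores).
#'
#' @param spec a [fixture_spec()].
#' @return list with `graphs` (one per chain), `truth` (tibble: `motif`,
#'   `graph_id`, `chain`, one list-column of expected core node sets per
#'   preset) and `spec`.
#' @export
plant_motif <- function(spec) {
  defs <- motif_defs()
  copies <- spec$copies[spec$copies > 0]
  with_local_seed(spec$seed, {
    # assign each motif copy to a chain
    assignments <- list()  # per chain: list of motif names
    for (ci in seq_len(spec$n_chains)) assignments[[ci]] <- character(0)
    offset <- 0L
    for (m in names(copies)) {
      for (k in seq_len(copies[[m]])) {
        ci <- if (m == "solo") 1L else ((offset + k - 1L) %% spec$n_chains) + 1L
        assignments[[ci]] <- c(assignments[[ci]], m)
      }
      offset <- offset + copies[[m]]
    }

    graphs <- list()
    truth <- list()
    for (ci in seq_len(spec$n_chains)) {
      units <- list()
      inst <- list()  # per instance: motif name + unit indices
      for (m in assignments[[ci]]) {
        uix <- integer(0)
        for (uk in defs[[m]]$units) {
          units[[length(units) + 1]] <- switch(uk,
            donor = unit_donor(), receptor = unit_receptor(),
            bulgeloop = unit_bulgeloop(), loopcycle = unit_loopcycle())
          uix <- c(uix, length(units))
        }
        inst[[length(inst) + 1]] <- list(motif = m, units = uix)
      }
      for (k in seq_len(spec$extra_hairpins)) {
        units[[length(units) + 1]] <- unit_plain(sample(3:5, 1), sample(4:6, 1))
      }
      # shuffle unit order; instances follow their units wherever they land
      perm <- sample(seq_along(units))
      units <- units[perm]
      relocate <- match(seq_along(perm), perm)
      inst <- lapply(inst, function(x) { x$units <- relocate[x$units]; x })

      # absolute unit offsets
      pos <- spec$spacer
      starts <- integer(length(units))
      for (u in seq_along(units)) {
        starts[u] <- pos
        pos <- pos + units[[u]]$len + spec$spacer
      }
      len <- pos

      pairs <- purrr::map_dfr(seq_along(units), function(u) {
        p <- units[[u]]$pairs
        tibble(i = p$i + starts[u], j = p$j + starts[u], lw = p$lw)
      })
      cid <- sprintf("C%02d", ci)
      for (x in inst) {
        anch <- lapply(x$units, function(u) {
          lapply(units[[u]]$anchors, function(a) a + starts[u])
        })
        w <- defs[[x$motif]]$wire(anch)
        if (nrow(w) > 0) {
          flip <- w$i > w$j
          w <- tibble(i = ifelse(flip, w$j, w$i), j = ifelse(flip, w$i, w$j),
                      lw = ifelse(flip, label_geometry(iota(edge_label(w$lw))), w$lw))
        }
        pairs <- dplyr::bind_rows(pairs, w)
        tr <- defs[[x$motif]]$truth(anch)
        truth[[length(truth) + 1]] <- tibble(
          motif = x$motif, graph_id = cid, chain = cid,
          abc = list(tr$abc), ab = list(tr$ab), a = list(tr$a),
          local_modules = list(tr$local_modules))
      }

      chain <- structure(list(chain_id = cid, length = len,
                              pairs = pairs[order(pairs$i, pairs$j), ], seq = NULL),
                         class = "annotated_chain")
      built <- build_graph(chain)
      if (length(built) != 1) abort("fixture chain unexpectedly PEC-ambiguous")
      graphs[[ci]] <- built[[1]]
    }
    list(graphs = graphs, truth = dplyr::bind_rows(truth), spec = spec)
  })
}

#' Expected catalog occurrence keys for a preset
#'
#' Collapses a [plant_motif()] ground truth into, per motif valid under the
#' preset, the set of occurrence keys (`"graph_id:n1,n2,..."`) the extracted
#' catalog must reproduce exactly.
#'
#' @param truth the `truth` tibble from [plant_motif()].
#' @param preset rule preset name.
#' @return named list (motif -> sorted character vector of occurrence keys),
#'   motifs with no valid occurrences omitted.
#' @export
ground_truth_keys <- function(truth, preset) {
  out <- list()
  for (r in seq_len(nrow(truth))) {
    cores <- truth[[preset]][[r]]
    for (v in seq_along(cores)) {
      grp <- paste0(truth$motif[r], "/", v)
      out[[grp]] <- c(out[[grp]],
                      paste0(truth$graph_id[r], ":", paste(cores[[v]], collapse = ",")))
    }
  }
  lapply(out, sort)
}

catalog_occurrence_keys <- function(catalog) {
  lapply(catalog$rins, function(r) sort(names(r$occurrences)))
}
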