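# ---- FR3D-style annotation tables -------------------------------------------

#' Parse an FR3D-style basepair annotation table
#'
#' Reads per-chain basepair annotations in the tabular style of FR3D output:
#' columns `chain`, `i`, `j`, `lw` (Leontis-Westhof code), 1-based nucleotide
#' positions. Rows are deduplicated, mirrored rows (`j, i, iota-code`)
#' collapsed onto the `i < j` orientation, and positions shifted to the 0-based
#' internal convention. Annotations outside the 18 canonical LW codes (e.g.
#' near pairs such as `"ncWW"`) are dropped with a message, as are malformed
#' rows.
#'
#' @param x a data frame, or the path of a CSV/TSV file. The first four
#'   columns are taken as chain, i, j, lw code (by name when named).
#' @param chain keep only this chain id; required when the table mixes chains.
#' @param length chain length in nucleotides; defaults to the largest position
#'   seen.
#' @param sequence optional residue string (metadata only).
#' @return an `annotated_chain`: list with `chain_id`, `length`, `pairs`
#'   (tibble `i`, `j`, `lw` with `i < j`, 0-based) and `seq`.
#' @export
parse_fr3d <- function(x, chain = NULL, length = NULL, sequence = NULL) {
  if (is.character(x) && length(x) == 1) {
    first <- readLines(x, n = 1)
    sep <- if (grepl(",", first)) "," else ""
    header <- grepl("chain", first, ignore.case = TRUE)
    x <- utils::read.table(x, sep = sep, header = header,
                           stringsAsFactors = FALSE, comment.char = "#")
  }
  df <- as.data.frame(x)
  nm <- tolower(names(df))
  pick <- function(want, fallback) {
    hit <- which(nm %in% want)
    if (length(hit)) df[[hit[1]]] else df[[fallback]]
  }
  tab <- data.frame(
    chain = as.character(pick("chain", 1)),
    i = suppressWarnings(as.integer(pick("i", 2))),
    j = suppressWarnings(as.integer(pick("j", 3))),
    lw = as.character(pick(c("lw", "lw_code", "code"), 4)),
    stringsAsFactors = FALSE
  )

  bad <- is.na(tab$i) | is.na(tab$j) | tab$i < 1 | tab$j < 1 | tab$i == tab$j
  if (any(bad)) {
    message(sum(bad), " malformed annotation row(s) skipped")
    tab <- tab[!bad, , drop = FALSE]
  }
  if (!is.null(chain)) tab <- tab[tab$chain == chain, , drop = FALSE]
  chains <- unique(tab$chain)
  if (length(chains) > 1) {
    abort(paste0("table mixes chains (", paste(chains, collapse = ", "),
                 "); pass `chain` to select one"))
  }
  chain_id <- if (length(chains)) chains else (chain %||% "chain")

  known <- tab$lw %in% LW_GEOMETRIES
  if (any(!known)) {
    message(sum(!known), " annotation(s) with non-canonical LW codes dropped: ",
            paste(unique(tab$lw[!known]), collapse = ", "))
    tab <- tab[known, , drop = FALSE]
  }

  # 1-based -> 0-based; collapse mirrored duplicates onto i < j
  i0 <- tab$i - 1L; j0 <- tab$j - 1L
  flip <- i0 > j0
  pairs <- tibble(
    i = ifelse(flip, j0, i0),
    j = ifelse(flip, i0, j0),
    lw = ifelse(flip, label_geometry(iota(edge_label(tab$lw))), tab$lw)
  )
  pairs <- dplyr::distinct(pairs)
  pairs <- pairs[order(pairs$i, pairs$j, pairs$lw), , drop = FALSE]

  len <- as.integer(length %||% (max(c(pairs$j, 0L)) + 1L))
  if (nrow(pairs) > 0 && len <= max(pairs$j)) {
    abort("`length` is smaller than the largest annotated position")
  }
  structure(list(chain_id = chain_id, length = len, pairs = pairs,
                 seq = sequence),
            class = "annotated_chain")
}

#' @export
print.annotated_chain <- function(x, ...) {
  cat(sprintf("<annotated_chain '%s'> %d nt, %d basepairs\n",
              x$chain_id, x$length, nrow(x$pairs)))
  invisible(x)
}

# ---- double-cWW resolution ---------------------------------------------------

#' Resolve nucleotides carrying two canonical cWW pairs
#'
#' The nested secondary structure is built from cWW pairs, and a nucleotide
#' annotated with two cWW partners makes that assignment ambiguous. For each
#' such conflict the pair embedded in the longest run of consecutive nested
#' cWW pairs (the largest stack) is kept and the other dropped; equal stack
#' lengths break ties toward the lexicographically smaller `(i, j)`.
#'
#' @param pairs tibble with columns `i`, `j`, `lw` (0-based, `i < j`).
#' @return the pairs tibble with losing cWW pairs removed.
#' @export
resolve_double_cww <- function(pairs) {
  repeat {
    cww <- pairs[pairs$lw == "cWW", , drop = FALSE]
    nodes <- c(cww$i, cww$j)
    dup <- unique(nodes[duplicated(nodes)])
    if (length(dup) == 0) return(pairs)
    node <- min(dup)
    cand <- which(cww$i == node | cww$j == node)
    len <- cww_stack_lengths(cww$i, cww$j)[cand]
    ord <- order(-len, cww$i[cand], cww$j[cand])
    drop <- cand[ord][-1]
    drop_key <- paste(cww$i[drop], cww$j[drop], "cWW")
    pairs <- pairs[!(paste(pairs$i, pairs$j, pairs$lw) %in% drop_key), , drop = FALSE]
  }
}

# ---- pseudoknot removal ------------------------------------------------------

crossing_any <- function(i, j, ri, rj) {
  # does pair (i, j) cross any retained pair (ri, rj)?
  any((ri < i & i < rj & rj < j) | (i < ri & ri < j & j < rj))
}

# stem membership of a set of cWW pairs: consecutive nested runs share an id
stem_ids <- function(i, j) {
  if (length(i) == 0) return(integer(0))
  ord <- order(i)
  id <- integer(length(i))
  key <- paste(i, j)
  nxt <- match(paste(i + 1L, j - 1L), key)  # index of the stacked-inside pair
  cur <- 0L
  prv <- rep(NA_integer_, length(i))
  prv[nxt[!is.na(nxt)]] <- which(!is.na(nxt))
  for (k in ord) {
    if (is.na(prv[k]) || id[prv[k]] == 0L) {
      if (is.na(prv[k])) { cur <- cur + 1L; id[k] <- cur } else { id[k] <- id[prv[k]] }
    } else id[k] <- id[prv[k]]
  }
  # second pass for runs whose outer pair appears later in i-order (cannot
  # happen: outer pair has smaller i), kept for safety
  id
}

#' Remove pseudoknots from a cWW pair set
#'
#' Selects a crossing-free (pseudoknot-free) subset of the resolved cWW pairs.
#' Whole stems are retained greedily in order of decreasing stem length
#' (ties: smaller first position); a stem crossing an already-retained pair is
#' removed wholesale. The removed pairs re-enter the structure graph later as
#' ordinary basepairs whose range is classified against the nested structure.
#'
#' @param cww_pairs tibble with columns `i`, `j` (0-based, `i < j`), cWW only.
#' @return list with `nested` and `removed` pair tibbles.
#' @export
remove_pseudoknots <- function(cww_pairs) {
  p <- cww_pairs[order(cww_pairs$i, cww_pairs$j), , drop = FALSE]
  if (nrow(p) == 0) return(list(nested = p, removed = p))
  sid <- stem_ids(p$i, p$j)
  slen <- as.integer(table(sid))[sid]
  smin <- stats::ave(p$i, sid, FUN = min)
  stem_order <- unique(sid[order(-slen, smin, p$i)])
  keep <- logical(nrow(p))
  ri <- integer(0); rj <- integer(0)
  for (s in stem_order) {
    rows <- which(sid == s)
    crosses <- any(vapply(rows, function(r) crossing_any(p$i[r], p$j[r], ri, rj),
                          logical(1)))
    if (!crosses) {
      keep[rows] <- TRUE
      ri <- c(ri, p$i[rows]); rj <- c(rj, p$j[rows])
    }
  }
  list(nested = p[keep, , drop = FALSE], removed = p[!keep, , drop = FALSE])
}

# ---- SSE decomposition -------------------------------------------------------

#' Decompose a nested structure into secondary structure elements
#'
#' Stems are maximal runs of two or more stacked cWW pairs. The loop regions
#' they delimit are labelled by the number of stems they enclose: hairpin
#' (none), internal (one), multi (two or more); nucleotides outside every stem
#' span form the exterior SSE. Isolated (unstacked) nested pairs do not form
#' stems; their nucleotides stay in the surrounding loop. Two SSEs are
#' adjacent when they touch along the backbone.
#'
#' @param nested_pairs crossing-free cWW pair tibble (`i`, `j`, 0-based).
#' @param length chain length.
#' @return an `sse_decomposition`: list with `sse_of` (integer SSE id per node,
#'   position `k + 1` for node `k`), `kind` (per-SSE label: `stem`, `hairpin`,
#'   `internal`, `multi`, `exterior`), and `adjacency` (symmetric logical
#'   matrix over SSE ids).
#' @export
decompose_sses <- function(nested_pairs, length) {
  p <- nested_pairs[order(nested_pairs$i), , drop = FALSE]
  sid <- stem_ids(p$i, p$j)
  run_len <- if (nrow(p)) as.integer(table(sid))[sid] else integer(0)
  stems <- unique(sid[run_len >= 2])

  sse_of <- rep(NA_integer_, length)
  kind <- character(0)
  new_sse <- function(k) { kind[length(kind) + 1] <<- k; length(kind) }

  stem_span <- list()
  for (s in stems) {
    rows <- which(sid == s)
    id <- new_sse("stem")
    sse_of[c(p$i[rows], p$j[rows]) + 1L] <- id
    stem_span[[as.character(id)]] <- c(min(p$i[rows]), max(p$j[rows]),
                                       max(p$i[rows]), min(p$j[rows]))
  }

  # loop enclosed by each stem: positions strictly inside its innermost pair
  # that are not covered by the outer span of a child stem
  spans <- do.call(rbind, stem_span)
  covered_by_stem_span <- function(pos) {
    if (is.null(spans)) rep(FALSE, length(pos))
    else vapply(pos, function(q) any(spans[, 1] <= q & q <= spans[, 2]), logical(1))
  }
  for (id in seq_along(stem_span)) {
    sp <- stem_span[[id]]
    inner <- if (sp[3] + 1 <= sp[4] - 1) (sp[3] + 1):(sp[4] - 1) else integer(0)
    if (length(inner) == 0) next
    # child stems: those whose whole span sits inside this stem's innermost pair
    child <- which(vapply(stem_span, function(cs) cs[1] > sp[3] & cs[2] < sp[4],
                          logical(1)))
    child_cov <- rep(FALSE, length(inner))
    for (cid in child) {
      cs <- stem_span[[cid]]
      child_cov <- child_cov | (inner >= cs[1] & inner <= cs[2])
    }
    # direct children only: stems inside this one but not inside a sibling
    direct <- Filter(function(cid) {
      cs <- stem_span[[cid]]
      !any(vapply(child, function(oid) {
        os <- stem_span[[oid]]
        oid != cid && os[1] < cs[1] && cs[2] < os[2]
      }, logical(1)))
    }, child)
    loop_nodes <- inner[!child_cov]
    k <- if (length(direct) == 0) "hairpin" else if (length(direct) == 1) "internal" else "multi"
    if (length(loop_nodes) > 0) {
      lid <- new_sse(k)
      sse_of[loop_nodes + 1L] <- lid
    }
  }

  exterior <- which(is.na(sse_of)) - 1L
  if (length(exterior) > 0) {
    eid <- new_sse("exterior")
    sse_of[exterior + 1L] <- eid
  }

  nsse <- length(kind)
  adjacency <- matrix(FALSE, nsse, nsse)
  if (length > 1) {
    a <- sse_of[1:(length - 1)]
    b <- sse_of[2:length]
    for (k in which(a != b)) {
      adjacency[a[k], b[k]] <- TRUE
      adjacency[b[k], a[k]] <- TRUE
    }
  }
  structure(list(sse_of = sse_of, kind = kind, adjacency = adjacency),
            class = "sse_decomposition")
}

#' @export
print.sse_decomposition <- function(x, ...) {
  cat(sprintf("<sse_decomposition> %d nodes, %d SSEs (%s)\n",
              length(x$sse_of), length(x$kind),
              paste(names(table(x$kind)), table(x$kind), sep = ":", collapse = ", ")))
  invisible(x)
}

#' Classify an interaction as local or long-range
#'
#' An interaction is local when its two nucleotides lie in the same SSE or in
#' adjacent SSEs (sharing a backbone border), long-range otherwise. Symmetric
#' in the two nodes. Vectorized.
#'
#' @param i,j node ids (0-based).
#' @param sses an [decompose_sses()] result.
#' @return character vector, `"local"` or `"long_range"`.
#' @export
classify_range <- function(i, j, sses) {
  si <- sses$sse_of[i + 1L]
  sj <- sses$sse_of[j + 1L]
  ifelse(si == sj | sses$adjacency[cbind(si, sj)], "local", "long_range")
}

# ---- graph building ----------------------------------------------------------

# wholesale edge-table constructor (lenient: PEC checked afterwards)
graph_from_interaction_table <- function(id, n, tab, chain = id, seq = NULL) {
  g <- rna_graph(id, n = n, chain = chain, seq = seq)
  if (nrow(tab) == 0) return(g)
  check_label(tab$label)
  g$edges <- tibble(
    from = c(tab$i, tab$j),
    to = c(tab$j, tab$i),
    label = c(tab$label, iota(tab$label))
  )
  g
}

#' Build RNA 2D structure graphs from an annotated chain
#'
#' Runs the full per-chain pipeline: resolve double-cWW conflicts, remove
#' pseudoknots, decompose the nested structure into SSEs, classify every
#' retained pair (including the removed pseudoknot pairs, which re-enter here)
#' as local or long-range, then assemble the directed edge-labelled graph with
#' backbone `b53`/`b35` edges along the nucleotide order. Remaining proper
#' edge-coloring violations (two interactions on the same Leontis-Westhof
#' edge) trigger [duplicate_for_exceptions()], so the result is a list of one
#' or more PEC-valid graphs sharing the chain id.
#'
#' @param chain an [parse_fr3d()] `annotated_chain`.
#' @param cap exception-duplication cap passed to [duplicate_for_exceptions()].
#' @return list of PEC-valid `rna_graph`s with SSE metadata attached.
#' @export
build_graph <- function(chain, cap = 16L) {
  stopifnot(inherits(chain, "annotated_chain"))
  n <- chain$length
  pairs <- resolve_double_cww(chain$pairs)
  cww <- pairs[pairs$lw == "cWW", , drop = FALSE]
  pk <- remove_pseudoknots(cww)
  sses <- decompose_sses(pk$nested, n)

  tab <- pairs
  tab$label <- edge_label(tab$lw, classify_range(tab$i, tab$j, sses))
  if (n > 1) {
    bb <- tibble(i = 0:(n - 2), j = 1:(n - 1), label = edge_label("b53"))
    tab <- dplyr::bind_rows(tab[, c("i", "j", "label")], bb)
  } else {
    tab <- tab[, c("i", "j", "label")]
  }

  g <- graph_from_interaction_table(chain$chain_id, n, tab, seq = chain$seq)
  versions <- duplicate_for_exceptions(g, cap = cap)
  lapply(versions, function(v) {
    v$sse <- stats::setNames(sses$sse_of, 0:(n - 1))
    v$sse_kind <- sses$kind
    v
  })
}
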