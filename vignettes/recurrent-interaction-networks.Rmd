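---
title: "Mining recurrent interaction networks with properly edge-colored graph matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining recurrent interaction networks with properly edge-colored graph matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rinnet)
```

## The graph model

A nucleotide chain becomes a directed edge-labelled graph: one node per
nucleotide position (0-based internally, 1-based in human-facing output),
edges for the backbone and for every annotated basepair. A label combines a
geometry — one of the 18 Leontis-Westhof codes `{c,t} x {W,H,S}^2`, or the
backbone codes `b53`/`b35` — with a range flag, `local` or `long_range`.
Every interaction is stored as two directed edges `(u, v, L)` and
`(v, u, iota(L))`, where `iota` swaps the interacting edges (`xYZ -> xZY`,
`b53 <-> b35`) and preserves the range; `iota` is an involution, and the
abstract `b35` color exists precisely so that backbone edges satisfy the
coloring constraint in both directions.

Because a nucleotide engages each of its three chemical edges at most once,
no node carries two outgoing edges with the same label: the labels form a
**proper edge-coloring** (PEC). This is an intrinsic property of the data,
not a computed coloring, and it is the only structural assumption the
matching layer makes. Annotation data occasionally breaks it (two
interactions reported on the same Leontis-Westhof edge of one nucleotide —
a fraction of a percent of nucleotides in real corpora); such graphs are
duplicated into PEC-valid versions, one per interpretation, capped at 16
versions per chain (beyond the cap a single version is kept, retaining per
conflict the interaction whose partner sits in the largest cWW stack, the
same tie rule used for the secondary structure). Sequence letters are
carried as metadata only; no logic depends on base identity.

## Secondary structure, SSEs, and the range flag

The local/long-range flag needs a pseudoknot-free secondary structure:

1. **Double-cWW resolution.** A nucleotide with two cWW partners keeps the
   pair embedded in the longest stack of consecutive nested cWW pairs; ties
   go to the lexicographically smaller `(i, j)`. The losing pair is dropped
   from the graph altogether.
2. **Pseudoknot removal.** Whole stems are retained greedily by decreasing
   stem length (ties: smaller start position); a stem crossing an
   already-retained pair is removed. This is a deliberate, documented
   stand-in for the K2N algorithm: downstream logic depends only on the
   result being crossing-free, but real-data reproductions should expect
   boundary cases where K2N's nested structure differs from ours.
   Removed pairs re-enter the graph as ordinary basepairs and get their
   range from the rule below — a pseudoknot helix typically becomes a
   long-range cWW patch, which is exactly what makes it minable.
3. **SSE decomposition.** Stems are maximal runs of two or more stacked cWW
   pairs; isolated nested pairs do not form stems and stay in their loop.
   Loop regions are labelled by the number of stems they enclose — hairpin
   (0), internal (1), multi (>= 2) — and everything outside any stem span is
   one exterior SSE.
4. **Range classification.** An interaction is `local` iff its nucleotides
   lie in the same SSE or in SSEs that touch along the backbone ("adjacent").
   The backbone-border definition of adjacency is our choice — it makes
   stem/loop contacts local, which matches the intuitive picture — but it is
   a declared convention, not something the data dictates.

## The extension core and the three matching problems

All matching starts from a seed of matched node pairs and grows it
breadth-first: for a matched pair `(g, h)` and each label both nodes carry,
the PEC leaves at most one candidate pair of neighbors, so extension is
linear in the number of nodes times the (fixed) number of colors, and a
given seed plus constraint set always produces the same matching regardless
of processing order (the frontier is processed in ascending node order for
reproducible logs).

* **Isomorphism / subgraph isomorphism** run the extension in strict mode
  (any conflict aborts) from every pair of equally-colored edges of the seed
  color — the label minimising `|E_G,c| x |E_H,c|`, ties broken
  lexicographically — giving O(n³) overall. Disconnected inputs are handled
  by decomposing into components and backtracking over component
  assignments; RNA chain graphs are backbone-connected, so this path mainly
  serves the random-graph test harness and disconnected pattern queries.
* **All maximal common subgraphs** runs the extension in permissive mode: a
  conflicting candidate pair is logged, not fatal, and the extension still
  completes into one maximal common subgraph. Each conflict identifies a
  *blocking pair* already in the matching; a new branch is replayed from the
  same seed with the blocking pair added to a forbidden list, exploring the
  alternative the discrepancy suggests. Branches partition the alternatives
  disjointly: the i-th branch of an exploration forbids the i-th blocking
  pair while committing the earlier ones, so no alternative is explored
  twice. Results are deduplicated by matched pair set and audited for
  maximality (a branch whose forbidden pair ends up unused yields a
  non-maximal matching, which the audit discards); enumeration seeds over
  every shared label, not just the cheapest one, so components with no
  minimal-color edge are not missed. Matching is connected by construction,
  so "maximal common subgraph" here means *maximal connected* common
  subgraph with at least one edge — the RIN definition requires
  connectivity anyway, and single-node common subgraphs are not meaningful.
  A configurable branch cap (default 10^6 per seed family) turns pathological
  blow-ups into a clean error rather than an endless run.

The load-bearing correctness evidence is oracle equivalence: on hundreds of
seeded random PEC graphs (up to 8 nodes, 2-4 labels, connected and not), all
three operations agree exactly with exhaustive brute-force searches that
share no code with the production path, and isomorphism additionally agrees
with an independent general-purpose colored-graph matcher. The brute-force
oracles are exported (`oracle_*`) so the acceptance script can recompute the
agreement, but nothing in the production pipeline calls them.

## From common subgraphs to RINs

A RIN is a pair `(S, O)`: a connected canonical graph and its occurrences,
at least two of which must come from distinct chains. The rule system
restricts which `S` are interesting:

* **x** — every node on an undirected cycle (no danglings);
* **y** — every local cWW pair needs a witness: a neighbor of either partner
  (the partners themselves qualify, as in A-minor receptors) involved in a
  long-range or non-canonical interaction. Without it, every stem would
  match every stem. The witness must be inside `S`, a reading we fixed
  deliberately since neighborhood membership outside the common subgraph is
  not preserved by matching;
* **z** — every node carries a basepair (no backbone-only runs);
* **b** — a minimum number of long-range interactions (counted as directed
  long-range edges divided by two);
* **c** — occurrences span exactly a configured number of SSEs, evaluated
  per occurrence: SSE span is a property of an occurrence, not of `S`, and
  occurrences of one RIN may legitimately span different SSE counts once
  rule c is relaxed.

Preset `abc` is the classic interaction-network definition (>= 2 long-range,
exactly 2 SSEs); `ab` relaxes the span; `a` also drops the long-range
requirement; `local_modules` inverts it (no long-range interactions at all)
and relaxes z, because purely local modules such as kink-turns contain
bulged backbone-only nucleotides that sit on the defining cycle.

`prune_to_rules` applies x, y, z (and the no-long-range constraint where
active) to a fixpoint — each removal can expose new violations — and backs
both filters: the post-filter `f_R` prunes each maximal common subgraph,
splits it into components and applies b and c per component; the pre-filter
`f'_R` applies the same fixpoint to whole chain graphs before any matching,
plus one extra step, dropping components whose total long-range count is
below the class minimum (sound because a connected `S` cannot straddle
components). Every removal is justified by a monotonicity argument — a node
or edge invalid in the chain graph is invalid in every subgraph — and the
package property-tests the resulting guarantee directly: catalogs computed
with and without the pre-filter are identical on dozens of corpora.

Pairwise candidate sets are clustered by exact isomorphism (bucketed first
on an invariant vector — node count, per-label edge counts, degree multiset
— exactness preserved since bucket collisions still get the full test).
Occurrences merge keyed by (graph id, occupied node set), collapsing
automorphic re-matchings. Pairs of graphs are processed independently — the
contract that makes the pipeline trivially parallelizable — and the catalog
is invariant under corpus permutation, with ids assigned on a deterministic
sort. Chains duplicated by exception handling keep their chain id, so their
occurrences never fabricate recurrence on their own.

The catalog's internal structure is exposed as an inclusion network: an edge
`r1 -> r2` iff `S1` is a subgraph of `S2`, computed by the subgraph
isomorphism algorithm behind an invariant-dominance pre-screen, every edge
certified by a stored injection. The relation is a strict partial order
(isomorphic duplicates cannot exist in a catalog), so transitive reduction —
dropping any edge paralleled by a two-step path — is well defined and
reachability-preserving.

## The synthetic corpus generator

`plant_motif()` assembles chains from hairpin units separated by unpaired
spacers and wires motifs across them; everything flows through the real
pipeline (secondary structure, SSEs, range classification), so planted
long-range contacts are long-range because the SSE decomposition says so,
not by fiat. The motif library is designed so that ground truth is
hand-derivable from the rule semantics:

* `loop_clamp` — two consecutive loop nucleotides clamp two consecutive
  nucleotides of a distant hairpin loop with tSS pairs: a single 4-cycle,
  2 long-range interactions, 2 SSEs. No proper sub-network satisfies rule x,
  so it contributes exactly one core.
* `tripod` — three loops joined into one hexagonal cycle by three distinct
  trans pairs: 3 long-range interactions over 3 SSEs; valid once rule c is
  relaxed, and again free of valid sub-networks.
* `bulge_loop` — one trans pair closing a 5-node cycle over three
  backbone-only nucleotides inside a hairpin loop: recoverable only under
  `local_modules` (rule z would prune the bulge and break the cycle).
* `loop_cycle` — two cis non-canonical pairs closing a 4-cycle inside one
  loop: valid under `a` (and, with the intervening nucleotide, under
  `local_modules`), never under `ab`/`abc` — it is what makes the `a`
  catalog strictly larger than `ab` in the nesting tests.
* `aminor` — the classic wiring of two tSS contacts into the 5' strand of a
  2-bp receptor stem. Its ground truth deliberately contains *two* nested
  cores: the full 6-node core (the receptor stem is witnessed by the
  contacts) and the 4-node donor/strand cycle that stays rule-valid when a
  discrepant matching strips the strand's cWW partners. Recovering both —
  and the inclusion edge between them — is a designed positive control for
  the discrepancy-replay machinery and the inclusion network.
* `solo` — a single-chain control with its own labels that the recurrence
  requirement must exclude.

Host stems are never witnessed (anchors sit mid-loop, away from stem
borders), receptor stems are exactly 2 bp so they survive pruning whole, and
the non-canonical label sets of different motifs are disjoint, so cross-motif
common subgraphs die in the fixpoint. Under these conditions planted cores
are provably the only rule-valid recurrent structures, and the acceptance
tests demand *exact* equality between catalog occurrence sets and ground
truth under all four presets.

What the generator does not emulate: annotation noise and near-pairs,
modified or missing nucleotides, base stacking, multi-model structures,
sequence-dependent effects, and ribosome-scale graphs (hundreds of nodes;
unit tests stay desk-scale by design). Passing tests therefore demonstrate
algorithmic correctness under the stated graph model, not robustness to the
full messiness of experimental annotation.

## Numerical and design choices

* Problem sizes in the test and acceptance suites: oracle equivalence on 200
  random pairs of up to 8 nodes (the exhaustive oracle is exponential);
  planted-motif recovery on a 10-chain corpus of 28-84 nt chains; pre-filter
  equivalence on 50 two-graph corpora (42 random 12-node pairs plus 8 paired
  24-nt chains matched without pre-filtering). These sizes were chosen once,
  as the smallest corpora that exercise every rule and code path.
* Determinism: label order is lexicographic everywhere a tie must break;
  frontier processing is FIFO in node order; the same seed reproduces a
  corpus byte for byte, and `random_pec_graph()` restores the caller's RNG
  state.
* Degenerate inputs: empty graphs and empty corpora error early with plain
  messages; chains of length 1 have no backbone; isolated nodes are legal in
  random graphs and are matched by count in isomorphism.
* The graph JSON dialect stores each interaction once (the `iota` twin is
  implicit) plus optional SSE annotations, so pipelines can round-trip
  through files; catalogs serialise with 1-based positions for human
  consumption.

## Known limitations

* The pseudoknot-removal heuristic is not K2N; catalogs built from real
  corpora may differ at structures where maximal-stem greediness and K2N
  disagree.
* Exception duplication enumerates interpretations independently per
  conflict; overlapping conflicts (one interaction in two violations) are
  resolved by consistency filtering, and interpretation counts beyond the
  cap collapse to the largest-stack choice.
* `all_maximal_common_subgraphs` enumerates connected maximal common
  subgraphs; a disconnected maximal common subgraph is represented by its
  components, which is what the RIN layer consumes but differs from the
  unconstrained mathematical definition.
* Worst-case behaviour remains exponential (the problem is NP-hard); the
  branch cap makes that explicit. Un-pre-filtered matching of whole chains
  is the expensive path and exists mainly to certify the pre-filter.
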