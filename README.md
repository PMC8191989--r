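# rinnet

Mining Recurrent Interaction Networks (RINs) in RNA 2D structure graphs with
fast exact matching of properly edge-colored graphs.

## The problem

RNA architecture is stabilised by networks of non-canonical basepairs inside
loops and by long-range contacts bridging distant secondary structure elements
(SSEs). These interaction networks — A-minors, ribose zippers, kink-turns and
many patterns without a name — recur across unrelated molecules and carry
structural information that free-energy models miss. Finding them
systematically means comparing every pair of annotated chains and enumerating
their common basepair networks, a maximal-common-subgraph problem that is
NP-hard on general graphs.

`rinnet` exploits a chemical fact: a nucleotide can use each of its three
interacting edges (Watson-Crick, Hoogsteen, Sugar) at most once. Representing
a chain as a directed graph whose edges carry a Leontis-Westhof geometry
(`{c,t} x {W,H,S}^2`), a range flag (local vs long-range) and backbone labels
`b53`/`b35` — every interaction stored as the directed twins `(u,v,L)` and
`(v,u,iota(L))` with `iota(xYZ) = xZY` — makes the label set a *proper
edge-coloring* (PEC): no node has two outgoing edges of the same color.
Extending a partial matching between two such graphs therefore never requires
a permutation search over neighborhoods — at most one assignment is valid —
which yields:

* **graph isomorphism** and **subgraph isomorphism** in O(n³): seed an
  extension from every pair of equally-colored edges of the color minimising
  `|E_G,c| x |E_H,c|`;
* **all maximal connected common subgraphs**: a permissive extension that
  logs conflicting pairs instead of aborting, and replays itself from the
  same seed with a constraint list forbidding each blocking pair, so every
  alternative matching suggested by a discrepancy is explored exactly once.

On top of the matching layer, a rule system distills maximal common subgraphs
into RINs — connected subgraphs `S` observed in at least two distinct chains,
recorded as `(S, O)` with `O` the occurrence collection:

| rule | meaning |
|------|---------|
| x | every node of S lies on an undirected cycle |
| y | local cWW pairs need a neighbor with a long-range or non-canonical interaction (stacks are not extended) |
| z | every node forms at least one basepair |
| b | at least 2 long-range interactions |
| c | occurrences span exactly 2 SSEs |

Presets `abc`, `ab`, `a` (rules x+y+z only) and `local_modules` (no long-range
interactions, rule z relaxed so bulged nucleotides on a cycle survive, as in
kink-turns) reproduce successive relaxations of the classic definition. A
pre-filter `f'_R` prunes each chain graph of everything that already violates
a rule before any matching — provably catalog-preserving and property-tested —
and the resulting non-redundant catalog is organised into an inclusion
network by subgraph isomorphism, transitively reduced for display.

## Worked example

Ten lines from chains to a catalog. `plant_motif()` builds a seeded synthetic
corpus of annotated chains (hairpin scaffolds with a recurrent tSS loop-loop
clamp planted in three of four chains) through the standard pipeline —
secondary structure assignment, pseudoknot removal, SSE decomposition,
local/long-range classification:

```r
library(rinnet)
fx <- plant_motif(fixture_spec(n_chains = 4, copies = c(loop_clamp = 3), seed = 42))
catalog <- run_corpus(fx$graphs, rin_rules("abc"))
catalog
#> <rin_catalog> 1 RINs, 3 occurrences, rules 'abc', 4 graphs
tidy(catalog)
#> # A tibble: 1 × 8
#>   catalog_id n_nodes n_interactions n_long_range n_occurrences n_chains ...
#> 1          1       4              4            2             3        3
interactions(catalog$rins[[1]]$graph)
#> # A tibble: 4 × 3
#>    from    to label
#> 1     0     1 b53/local
#> 2     0     2 tSS/long_range
#> 3     1     3 tSS/long_range
#> 4     2     3 b53/local
names(catalog$rins[[1]]$occurrences)
#> [1] "C01:5,6,28,29" "C02:5,6,16,17" "C03:5,6,16,17"
```

The one catalog entry is the planted clamp: a 4-node cycle of two long-range
tSS pairs bridging two backbone steps, spanning 2 SSEs, found at its exact
planted coordinates in chains C01-C03 and nowhere else (host stems are
excluded by rule y, unpaired spacers by rules z and x). Real FR3D-style
annotation tables enter the same pipeline through
`parse_fr3d() |> build_graph()`; `build_network()` then relates catalog
entries by inclusion, and `autoplot()` has methods for catalogs and networks.

A command-line front end wrapping the same functions ships in
`inst/cli/rin.R` (`extract`, `network`, `fixtures` subcommands).

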