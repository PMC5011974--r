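---
title: "Dominating sets as regulatory key players: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dominating sets as regulatory key players}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

A gene regulatory network is a directed graph whose arcs run from a
transcription factor (TF) to each gene it regulates. Control over the
network is formalised as *domination*: a gene set `D` dominates the network
when every gene either belongs to `D` or receives an arc from a member of
`D`. A minimum dominating set (MDS) is a smallest set with direct
regulatory reach over everything — a candidate list of key drivers. The
connected variant (MCDS) additionally requires the members to induce one
connected piece of the underlying undirected graph, encoding the biological
expectation that a master-regulatory core is a set of *interacting* genes
rather than scattered hubs. MCDS members split into **dominators**
(selected for coverage) and **connectors** (kept only to hold the set
together). Both problems are NP-hard; the package offers an exact
integer-programming route for small-to-moderate components and a
polynomial-time greedy heuristic for the rest.

## Exact route

The MDS program has one binary indicator per gene and one covering
constraint per gene: `x_u + Σ_{v ∈ δ⁻(u)} x_v ≥ 1`, where `δ⁻(u)` is the
regulator set of `u`. The MCDS program adds binary indicators `x_e` on the
edges of the underlying undirected graph (antiparallel arcs merged), the
tree-cardinality equality `Σ x_e = Σ y_i − 1`, the valid inequalities
`x_e ≤ y_u`, `x_e ≤ y_v`, and — because enumerating them all is hopeless —
subtour-elimination-type constraints `Σ_{e∈E(S)} x_e ≤ Σ_{i∈S∖{j}} y_i`
generated lazily: after each solve, the selected nodes are decomposed into
weakly connected pieces (a hand-written BFS, independently cross-checked in
the test suite against igraph); if there is more than one piece, a cut is
posted for every piece `S` and every `j ∈ S`, and the strengthened program
is re-solved. Cuts accumulate and are never dropped; each round adds at
least one previously absent member of a finite family, so the loop
terminates. The iteration count and cut log are kept on the solver state
and reported in the result metadata.

No linear-programming solver package is available in the target
environment, so the 0/1 backend is the package's own branch-and-bound
search (`src/bnb.cpp`): per-constraint attainable-range propagation with
forced-variable fixing, depth-first search branching on nodes in
descending out-degree order (value 1 first, so a covering incumbent is
found early), and incumbent-based pruning. Completing the search proves
optimality; a wall-clock or node budget instead yields `status =
"feasible"` with the incumbent. On the certified instance sizes used by
the test suite the search is exhaustive within milliseconds; the test
suite certifies it against enumeration oracles rather than against another
solver.

### Role split in the exact route

The heuristic names its connectors constructively, the ILP does not, so the
package labels an exact-solution member `v` a connector when dropping it
leaves the remainder still dominating but disconnected — i.e. `v`'s only
contribution is connectivity. At a proven optimum no member can be dropped
with both properties intact, so this is the unique consistent reading; for
a single-gene solution the member is a dominator.

## Heuristic route

Three phases over a colouring (white = uncovered, gray = dominated,
black = dominator, dark gray = connector):

1. **Dominators.** Repeatedly pick the white node covering the most
   still-white out-neighbours, colour it black and its white targets gray,
   until no white node remains. The published rule says "highest
   outdegree"; ranking by *static* out-degree can stall on nodes whose
   targets are already covered, so the default ranking is the coverage
   gain, with the literal static ranking available via `rank = "static"`.
2. **Connectors.** While the structure (black ∪ dark gray) has two or more
   weak components, add the outside node adjacent — in either arc
   direction — to the most structure nodes. Counting both directions and
   counting dark-gray members, and not requiring a single pick to merge two
   components, is what keeps chains of length ≥ 2 between components from
   deadlocking; connectivity is reached in aggregate.
3. **Pruning.** Scan members by ascending static out-degree and remove any
   whose removal preserves domination and connectivity, restarting the
   scan after every removal.

Every choice is resolved by a fixed tie cascade — phase 1: coverage, then
in-degree, then first appearance; phase 2: adjacency count, out-degree,
in-degree, first appearance; phase 3: out-degree ascending, in-degree
descending, first appearance — so identical input files give byte-identical
output. Degrees are static degrees in the input component with self-loops
excluded.

## Component selection

MDS applies to any network. MCDS needs a connected input, so a
disconnected network is reduced to one component: the whole network when
weakly connected; otherwise the denser of the largest weakly connected
component (LCC) and the largest strongly connected component (LSCC), with
density `|E| / (|V|(|V|−1))`. Denser components need fewer connectors,
which is the point of the rule. Two package-level choices where the rule
is silent: a singleton component has density 0 (the formula divides by
zero, and a one-node component has no MCDS problem to solve), and a
density tie prefers the LCC because it covers more of the network.
Non-largest components can still be solved explicitly by passing them to
the solvers; no minimum SCC size is enforced.

## Self-loops

Autoregulation is parsed and retained as data but excluded from
`δ⁻`, from edge variables, from all degrees, and from density
denominator counts: a self-loop cannot make a *non-selected* gene
dominated, and including `u ∈ δ⁻(u)` would make `u`'s covering constraint
vacuous for every node with a self-loop.

## Hypergeometric test and the printed-precision question

Enrichment of a result set (sample of size `N`) against `k` annotated
genes in an `M`-gene network with overlap `x` is scored by the
hypergeometric upper tail. Two conventions are implemented: the default
**inclusive** tail `P(X ≥ x)` (the standard enrichment p-value) and the
**strict** tail `P(X > x)`, which is what a formula of the shape
`1 − Σ_{i=0}^{x}` yields literally. The computation uses R's log-space
`phyper` and is verified in the tests against explicit
binomial-coefficient summation.

The two published worked examples that anchor the acceptance targets give,
under the inclusive tail, 0.0041048 (printed 0.004) and 0.0385803 (printed
0.03). The second printed value is *not* the half-up rounding of either
convention (inclusive → 0.04, strict 0.0200601 → 0.02). The single
presentation rule consistent with both printed numbers is truncation
(flooring) of the inclusive tail at the printed number of decimals, and
that is exactly what the acceptance script reports, uniformly for both
targets, with the raw values always computed at run time. The package
itself never floors: `hypergeom_pvalue()` returns the full-precision tail.
The significance cutoff 0.05 is a reporting convention, not part of the
computation; Benjamini–Hochberg adjustment is provided as a utility over
p-value vectors.

## Synthetic benchmark world

The generators exist so that every solver is certifiable without external
downloads, and their defaults state that world once:

* `erdos-renyi-np` — each ordered pair an arc with probability `p`; the
  published benchmarking procedure for these solvers ("different sizes and
  densities"). The certified ranges used by the acceptance suite — `n ≤
  10`, `p ∈ [0.1, 0.5]`, ≥ 200 MDS and ≥ 100 MCDS instances — follow the
  stated property-based substitution for the real-network results, which
  depend on database snapshots that are deliberately not fixtures.
* `erdos-renyi-nm` — exactly `m` arcs, for density-controlled grids.
* `tf-target-bipartite` — `n_tf` regulators, arcs only TF→target, every
  target covered at least once: the shape of a curated GRN, where a correct
  MDS never needs a zero-coverage pure target.
* `planted-hub` — a universal out-hub plus noise arcs among the others
  (noise probability default 0.05, zero in planted-truth tests): instances
  with known optimum {hub}.

All sampling runs under a locally scoped seed, so a spec is byte-reproducible
and the caller's RNG state is untouched. What the generators do **not**
emulate: scale-free degree distributions, autoregulation (self-loops are
never generated), signed regulation logic, or the modular structure of real
disease networks — a green certification therefore establishes solver
correctness on the stated random ensemble, not biological fidelity of any
particular solution.

The observed behaviour on this world matches the published qualitative
claims: mean heuristic MCDS size at `n = 60` falls monotonically with
density (14.3 → 8.5 → 4.8 → 2.4 over `p` = 0.1, 0.2, 0.4, 0.8 across ten
seeds — computed by the acceptance suite, not asserted as constants), and
the heuristic is never smaller than the exact optimum. Its mean size
inflation on the small certified ensemble is a few percent — below the
10–50 % reported on real disease modules, as expected for small dense
random graphs, and therefore tracked as a statistic rather than asserted
as a bound.

## Numerical and degenerate-input choices

* Branch-and-bound tolerances are `1e-9` on row bounds and objective
  comparisons; all model coefficients are integers, so these are safety
  margins, not calibrated constants.
* The brute-force oracles enumerate subsets in increasing cardinality with
  hard guards (15 nodes for MDS, 12 for MCDS) and collect *all* optima,
  lexicographically sorted, so tests can assert witness sets exactly.
* Empty networks are usage errors for the solvers and component selection;
  an arc-free network has the full node set as its unique MDS.
* A singleton incumbent component in the cut loop would generate a vacuous
  cut `0 ≤ 0`; it is logged but not posted as a row. With ≥ 2 selected
  nodes the tree-cardinality equality makes this branch unreachable — it
  is defensive.
* Timeouts: the ILP routes return `status = "feasible"` (time limit with
  incumbent) or `"timeout"` (iteration cap), and raise a typed error only
  when no incumbent exists; the benchmark grid flags such rows rather than
  dropping them, and the CLI maps them to exit code 2.

## Known limitations

* The exact backend is a plain branch-and-bound without an LP relaxation
  bound; it is exhaustive and fast at certified sizes but will not scale to
  the thousands-of-genes regime, where the heuristic (or an external ILP
  solver behind the same model surface) is the practical route.
* TF-restricted domination (`tf_only`) can be infeasible when a gene has no
  TF regulator; this is reported as an error rather than silently relaxed.
* YAML configuration is not implemented (no YAML parser in the target
  environment); every documented option is a command-line flag.
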