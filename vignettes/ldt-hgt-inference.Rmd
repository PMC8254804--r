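---
title: "Indirect horizontal gene transfer inference from later-divergence-time graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indirect horizontal gene transfer inference from later-divergence-time graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldthgt)
```

## The model

Horizontal gene transfer (HGT) moves genetic material between co-existing
species.  Indirect phylogenetic methods detect it without reconstructing
trees, from a simple signal: two genes that are *more similar than their
species are* must have diverged after their species did, which is only
possible if at least one transfer separates them.

`ldthgt` formalizes this with **relaxed scenarios**: 6-tuples
$(T, S, \sigma, \mu, \tau_T, \tau_S)$ of a planted gene tree $T$, a planted
species tree $S$, a gene-to-species coloring $\sigma$, a reconciliation
$\mu: V(T) \to V(S) \cup E(S)$ and time maps $\tau_T, \tau_S$.  Only root,
leaf and time-consistency constraints are imposed — events (speciation,
duplication, transfer) are a matter of interpretation, not definition, which
makes the framework general enough to contain the usual
duplication-transfer-loss models.

Two derived graphs on the genes carry the transfer signal:

* the **LDT graph** $G_<(\mathcal S)$, with an edge $ab$ iff
  $\tau_T(\mathrm{lca}_T(a,b)) < \tau_S(\mathrm{lca}_S(\sigma(a),\sigma(b)))$
  — the "later-divergence-time" pairs;
* the **Fitch graph** $\digamma(\mathcal S)$, with an edge iff the tree path
  between the two genes contains a *transfer edge* (an edge of $T$ whose
  endpoint images under $\mu$ are incomparable in $S$) — the complete
  xenology relation.

The central facts the package implements and tests:

1. $(G,\sigma)$ is an LDT graph **iff** it is a properly colored cograph
   whose species-triple set $\mathfrak S(G,\sigma)$ is compatible
   (`is_ldt_graph()`).  The species triples $AB|C$ are read off induced
   paths $x - z - y$ with distinct colors; compatibility is decided with
   the Aho graph / BUILD recursion (`species_triples()`, `build_tree()`).
2. For every LDT graph an explaining relaxed scenario can be constructed in
   polynomial time (`explain_ldt()`), and $G_<(\mathcal S) \subseteq
   \digamma(\mathcal S)$ for *every* explaining scenario: every LDT edge is
   a certified xenolog pair, i.e. LDT predictions have no false positives.
3. Fitch graphs are exactly the complete multipartite graphs; a *colored*
   graph is realizable as the Fitch graph of some scenario (an rs-Fitch
   graph) iff, in addition, some maximal independent set can be removed so
   that the auxiliary color graph of the remaining sets is disconnected
   (`is_rs_fitch()`, `fitch_aux_graph()`).
4. Since the LDT graph underestimates the Fitch graph, the full xenology
   relation can be estimated by **minimum edge completion** to a complete
   multipartite graph — solved exactly as cluster deletion on the
   complement cograph by greedy maximum-clique peeling on its cotree
   (`complete_to_multipartite()`, `fitch_from_ldt()`).

## Scenario construction (the algorithm behind `explain_ldt()`)

The species tree defaults to the BUILD (Aho) tree of
$\mathfrak S(G,\sigma)$ on the observed colors — the least resolved
admissible choice; any supplied planted tree that displays the triples is
accepted after checking.  The gene tree is grown top-down on pairs
$(L', u_S)$ of a vertex subset and a species vertex:

* a 0-type vertex $u_T$ placed *just above* $u_S$ (inside the edge into
  $u_S$) separates the connected components of $G[L']$ — pairs split here
  get no LDT edge because their species lca lies at or below $u_S$;
* per connected component, a 1-type vertex $v_T$ placed *just below*
  $u_S$ forces LDT edges between its child classes, whose species lca is
  exactly $u_S$;
* the classes are the equivalence classes of "same component and colors in
  the same child subtree of $u_S$" (`relation_R()`, `child_partition()`);
  each class recurses into its species child.  When $u_S$ is a leaf all
  remaining genes share its color, are pairwise non-adjacent, and are
  attached below a single vertex.

Times are allocated by bisecting the available open interval: each
recursion level consumes a fresh sub-interval, which guarantees the strict
inequalities of both the time maps and the edge-placement constraints
without global bookkeeping.  Where several classes of a component could
anchor the component vertex, the lexicographically smallest class is used,
making the output deterministic.  Single-child vertices are suppressed at
the end, and the result is validated and its LDT graph compared
edge-by-edge against the input before it is returned (an internal error —
never observed — would indicate a bug rather than a property of the
input).

The labels of the construction double as a cotree for $G$: the lca of two
genes is a 1-type vertex iff they are adjacent.  This is checked
pair-by-pair in the test suite.

## Numerical and degenerate-input choices

* Times are compared **exactly** (`<` on doubles, no epsilon): all time
  maps in the package are constructed, not measured, and the bisection
  scheme keeps comparable vertices strictly apart.
* `assign_time_map()` uses the max-over-children-plus-gap rule with a
  default gap of 1; any positive gap gives the same downstream results
  because only the ordering matters.
* Single-vertex graphs, edgeless graphs, and single-class recursions are
  all legal; they exercise the planted-tree convention that a tree on one
  leaf is just the planted edge.
* The color universe `M` of a colored graph is stored explicitly and never
  silently shrunk to the observed colors: a same-color gene pair can be
  realizable as xenologs when an unsampled species exists, but not when
  the universe is restricted — rs-Fitch verdicts depend on it.
* BUILD recurses on the connected components of the Aho graph with sorted
  label order, so the Aho tree is reproducible; triples with a label
  outside the current label set are ignored (standard BUILD semantics).

## The simulator

`simulate_species_tree()` + `simulate_true_scenario()` +
`prune_to_observable()` emulate gene family evolution with losses hiding
part of the history:

* **Species trees** (10–50 leaves by default) grow by an innovation
  process: species are feature sets; an innovation founds a new species
  with a brand-new feature, a feature loss founds one only if the reduced
  set is not already present.  This yields the imbalanced shapes typical
  of real taxonomies; a Yule model is available as a fallback
  (`model = "yule"`) to check that downstream statistics are robust to the
  species-tree prior.  Node times come from a constant-rate branching
  clock (exponential waits with rate proportional to the number of
  lineages), rescaled so the root sits at time 1 and all leaves at 0;
  multifurcations are introduced by contracting each inner edge with
  probability 0.2.
* **Gene trees** evolve along the dated species tree from a single
  ancestral gene: each resident lineage speciates into every descendant
  branch at species vertices; within branches, duplications, losses and
  transfers are Poisson events.  Transfer recipients are drawn uniformly
  from the branches co-existing at the event time, excluding the donor
  (an event with no possible recipient is discarded); events cannot occur
  above the first speciation.
* **Pruning** removes loss leaves and suppresses unary vertices, keeping
  times and reconciliation images — the observable relaxed scenario.  A
  transfer followed by back-transfer and loss becomes invisible: the true
  Fitch graph restricted to survivors (`true_fitch_restricted()`) can
  strictly contain the observable one.

What the generator does *not* emulate: sequence evolution and the
estimation of LDT graphs from (dis)similarity data, rate heterogeneity
across lineages or time, replacing transfer as a distinct mechanism, and
gene conversion.  Passing tests therefore certify the combinatorial
machinery and the event-level statistics of the model — not the
end-to-end accuracy on real sequence data.

## The evaluation study

`evaluate_batch()` scores three Fitch estimates per scenario against the
observable ground truth $\digamma(\mathcal S)$ over all unordered gene
pairs: the raw LDT graph, the greedy minimum edge completion ("m.e.c."),
and the Fitch graph of the scenario constructed from the LDT graph.
Scenarios with an edgeless LDT graph are excluded from precision/recall
aggregation but counted in the edgeless fraction.  The default rate grid
pairs duplication = loss over \{0.25, 0.5, 1.0\} crossed with transfer
rates \{0.25, 0.5, 1.0\} — a stand-in spanning low/medium/high intensities
for each event type, chosen once; the exact published tuples are not
printed in the source material.  `scripts/acceptance.R` runs 100
replicates per combination (900 scenarios, a deliberately reduced
replicate count that one CPU completes in minutes); the test suite
additionally verifies the scenario round trip on 1000 smaller simulated
scenarios (5–20 species) where the construction is exercised most
densely.

## Known limitations

* The minimum edge completion is optimal as a *multipartite* completion,
  but is not guaranteed to be an rs-Fitch graph, nor to share a scenario
  with the input LDT graph; the diagnostics only report this (the
  harder completion variants have open or NP-complete status).
* `explain_ldt()` returns *one* explaining scenario; explaining scenarios
  are far from unique and no optimality (e.g. fewest transfers) is
  claimed.
* Recognition is desk-scale: cograph decomposition by recursive
  complement-connectivity is $O(n \cdot m)$-ish, not the linear-time
  modular decomposition, which is deliberate — inputs are gene families,
  not genomes.
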