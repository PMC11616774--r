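---
title: "Static screening of Boolean networks for gatekeeper intervention targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Static screening of Boolean networks for gatekeeper intervention targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnscreen)
```

## The problem

A Boolean network models a regulatory system as $n$ binary variables
$x(t) \in \mathbb{B}^n$, each updated by a logical rule over other
variables; under synchronous update, $x(t+1) = f(x(t))$, every trajectory
eventually enters an attractor — a fixed point or cycle commonly read as a
biological phenotype. In-silico target screening asks which single-node
knockouts or overexpressions reshape this attractor landscape. Answering
that question directly requires enumerating $2^n$ states per candidate
perturbation, which is hopeless for models with dozens to hundreds of
components.

`bnscreen` instead scores candidates on the *interaction graph* — the
directed graph with an edge $g \to h$ whenever $g$ appears in $h$'s rule —
which has only $n$ vertices. Two static measures act as proxies for dynamic
impact:

* **Vertex betweenness (VB).** The Freeman/Brandes centrality on the
  directed, unweighted interaction graph: for node $v$, the sum over
  ordered pairs $(s, t)$ of the fraction of shortest $s \to t$ paths that
  pass through $v$. High-VB nodes are structural bottlenecks.
* **Determinative power (DP).** For an edge $g \to h$, the mutual
  information $\mathrm{MI}(x_g; f_h) = H(f_h) - H(f_h \mid x_g)$ computed
  with binary Shannon entropy by exhaustively enumerating $h$'s truth table
  under independent uniform Bernoulli(1/2) inputs;
  $\mathrm{DP}(g) = \sum_h \mathrm{MI}(x_g; f_h)$ over all targets $h$ of
  $g$. DP measures how strongly a node's state pins down the next state of
  everything it regulates.

Nodes are ranked on each measure with descending competition ranking
(largest value gets rank 1; ties share the minimal rank) and **selected**
if they rank in the top $\lceil T \cdot n \rceil$ on *both* VB and DP. The
selection threshold $T$ defaults to 73%, the value reported to balance
sensitivity and specificity for a binary high/low dynamic-impact label in
the study that derived the approach; here it is simply a tunable parameter
(CLI flag `--threshold`, in percent).

Selected nodes still include hubs — central regulators with z-transformed
connectivity

$$C_i = \frac{\delta_i - \bar{\delta}}{\sigma} \ge 2.5,$$

where $\delta_i$ is total (in + out) degree. Hubs are poor drug targets:
hard to modulate selectively, and their perturbation risks lethality. The
interesting class is instead the **gatekeepers**: selected nodes whose
connectivity rank lags their static ranks,

$$\mathrm{mismatch}(g) = \mathrm{rank}_C(g) -
  \tfrac{1}{2}\left(\mathrm{rank}_{VB}(g) + \mathrm{rank}_{DP}(g)\right) > 0.$$

A positive mismatch flags a sparsely wired node that nevertheless ranks
among the strongest structural and informational drivers — the
recommendation list is exactly the gatekeepers sorted by descending
mismatch.

## A worked example

The shipped `bottleneck12` fixture joins two dense five- and six-node
clusters through a single two-in/two-out bridge `B`; all left-to-right
shortest paths cross `B`, and `B` is the sole input of its two targets, so
it determines them completely (1 bit each):

```{r}
net <- fixture("bottleneck12")
scores <- score_nodes(net)
scores[order(-scores$mismatch), c("node", "VB", "DP", "degree", "C",
                                  "rank_VB", "rank_DP", "rank_C", "mismatch")]
classify(scores, T = 0.73)
```

`B` ranks first on both VB and DP but only eighth on connectivity, giving
the top mismatch of +7. The exhaustive dynamics engine confirms the
prediction on this small model:

```{r}
orig <- find_attractors(net)
pert <- find_attractors(apply_perturbation(net, "B", 0))
impact_metrics(orig, pert)
```

## Design choices

Several aspects of the procedure are underdetermined by its verbal
description; the package fixes them as follows, and the test suite pins
each choice.

* **Truth-table bit order.** The first listed input of a rule is the
  least-significant bit of the table index. Any fixed convention works; it
  is documented and observable via `compile_truth_table()`.
* **Fractional path counting.** VB uses the standard fractional
  (Freeman/Brandes) definition rather than counting a path integrally for
  every node it touches, matching the centrality implemented across the R
  graph ecosystem. Self-loops are ignored by shortest paths; pairs with no
  connecting path contribute nothing.
* **Population standard deviation.** $C_i$ standardizes with the
  divide-by-$n$ $\sigma$ of the degree distribution. On degree-regular
  graphs $\sigma = 0$ and all $C_i$ are defined as 0, so no hubs exist and
  no division by zero occurs. The hub boundary $C_i = 2.5$ is inclusive.
* **Input distribution for DP.** Independent uniform Bernoulli(1/2) per
  node, the standard assumption of the determinative-power literature. MI
  is computed from the truth table, so a syntactically listed but
  non-essential input (as in `B | !B`) contributes exactly 0 bits and needs
  no pruning; self-loops do contribute to their node's DP.
* **Mismatch combination.** The two static ranks enter through their
  arithmetic mean — symmetric in VB and DP and on the same scale as the
  connectivity rank. Gatekeeper membership requires strictly positive
  mismatch; a node ranking equally on both sides is not recommended.
* **Tie handling.** Competition (minimum) ranking makes boundary ties at
  $\lceil T n \rceil$ all-in; the recommendation list breaks mismatch ties
  by node name, so output is deterministic.
* **Hubs are annotations.** A hub can be a gatekeeper (rendered purple in
  the graph export); raising the hub threshold never changes the
  classification, only the flags.
* **Attractor identity across perturbation.** An original and a perturbed
  attractor count as the same only when their full $n$-dimensional state
  sets are equal, including the perturbed node's frozen coordinate — the
  strict, unambiguous option. Each attractor is stored in canonical
  rotation (lexicographically smallest state first), making set comparison
  well defined.
* **Capacity cap.** `find_attractors()` refuses networks above 20 nodes
  (about $10^6$ states) with an explicit error. The engine exists to
  validate the static screen on small models, not to replace it.
* **SBML-qual specifics.** Species ids (unique by schema) are the node
  names; `maxLevel > 1` or arithmetic MathML raise unsupported-model
  errors; a transition's function terms are evaluated in document order
  with the `defaultTerm` covering uncovered assignments; species without
  transitions become constants at their initial level (0 when unset) —
  their attractor contribution is then exactly the initial state. Rules
  imported this way get a minterm-DNF expression synthesized from the
  compiled table, so the expression/table consistency invariant holds for
  both input formats.

## The random-network generator

`random_boolean_network(n, k, bias, seed)` draws, per node, `k` distinct
regulators uniformly (self-inputs allowed, as real models contain
autoregulation) and an i.i.d. Bernoulli(`bias`) truth table; `bias`
defaults to 0.5, the unbiased case in which every Boolean function on `k`
inputs is equally likely. A rule whose sampled table is constant is
normalized to an input-less constant rule — it has no effective regulators,
and the normalization keeps text round-trips exact. Seeding is local: the
caller's RNG state is untouched.

These networks emulate the combinatorial structure of regulatory logic —
sparse in-degree, arbitrary Boolean rules, self-loops — but not features of
curated disease models: no scale-free degree distribution, no canalyzing
bias, no signed activation/inhibition semantics, and no biological module
structure. Tests passing on them demonstrate the *correctness* of the
measures and of the attractor engine against brute-force oracles, not that
gatekeepers of random networks are biologically meaningful; the engineered
`bottleneck12` fixture covers the qualitative topology (dense modules
joined by a sparse bridge) the method is designed to detect.

Verification problem sizes were chosen so every oracle remains exhaustive:
50 random digraphs with up to 10 nodes for betweenness (per-pair BFS path
enumeration), 50 networks with up to 4 inputs per rule for MI
(joint-distribution tabulation, agreement to $10^{-12}$), and 50 networks
with up to 8 nodes for attractors (explicit state-graph strong-components
detection). All are exact comparisons, not statistical ones.

## Limitations

* Only synchronous, deterministic update semantics; asynchronous or
  probabilistic schemes can change the attractor landscape.
* Multi-valued logical models (`maxLevel > 1`) and probabilistic BoolNet
  extensions are rejected, not approximated.
* The screen scores single-node perturbations; combination interventions
  are out of scope.
* $T = 0.73$ is inherited as a default, not re-derived; for a new model
  class the threshold may warrant re-calibration against exhaustive
  dynamics on trimmed submodels.
* The raw impact metrics (fraction lost, new attractors, minimal Hamming
  distances) are reported without collapsing them into a single
  high/low-impact label, since any such cutoff is application-specific.
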