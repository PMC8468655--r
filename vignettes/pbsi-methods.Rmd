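---
title: "Partition-based spreader identification: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partition-based spreader identification: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbsi)
library(dplyr)
```

## The problem

Picking the seed nodes that maximise a spreading process on a network is
harder than ranking nodes one at a time: the best individual spreaders tend
to sit in the same dense core (the rich-club effect), so their influence
overlaps and a top-*k* list wastes most of its budget re-infecting the same
region. `pbsi` implements a two-phase remedy: partition the graph into
communities, then pick locally top-ranked nodes *per community*,
proportionally to community size. The selected seeds are both individually
strong and well scattered.

## Ranking: the gravity k-shell score

Nodes are ranked by a gravity-style combination of coreness and proximity,

$$\mathrm{GKSW}(v) \;=\; \sum_{w \in \psi_r(v)} \frac{ks(v)\,ks(w)}{d_{vw}^2},$$

where $ks(\cdot)$ is the k-shell index from iterative degree pruning,
$d_{vw}$ is the hop distance and $\psi_r(v)$ is the set of nodes within
$r$ hops of $v$ (default $r = 3$), excluding $v$ itself. Shell indices act
as masses, distance attenuates quadratically. Three numerical choices are
deliberate and tested:

* $v \notin \psi_r(v)$ — including it would divide by $d_{vv} = 0$;
* pairs beyond the radius contribute **nothing** (they are not included at
  their true distance); the radius trades locality against cost and $r=3$
  is the conventional default;
* isolated nodes, and generally nodes with shell index 0, score exactly 0
  rather than being dropped.

Scores are computed globally — community structure never enters the score,
only the selection.

## Selection: community-proportional allocation

Given $P$ seeds and communities sorted by increasing size (ties broken by
the lexicographically smallest member, the package-wide tie rule), each
community $c_u$ receives

$$p_{c_u} = \max\{1,\ \lfloor P_r \cdot |c_u| / n_u \rfloor\},$$

where $P_r$ is the number of still-unallocated seeds and $n_u$ the number
of still-unprocessed nodes. Processing smallest-first guarantees every
community at least one seed while the last (largest) community absorbs the
remainder, so the counts sum to $P$ exactly whenever
$|C| \le P \le n$ — a property the test suite verifies over a thousand
random size vectors. Two guard rails handle edge cases the rule itself does
not: a per-community cap at $|c_u|$ (with the surplus carried forward, and
a backward redistribution pass in the degenerate limit $P \to n$), and a
separate branch for $P < |C|$, where the $P$ largest communities get one
seed each. Within a community, seeds are the top-scored nodes (ties again
by node identifier).

`pbsi_select()` composes the whole pipeline; `combined_variant()` applies
the same allocation to *any* score table or ranker ("starred" variants such
as DEG⋆), which is how the package quantifies what the distribution
strategy alone contributes.

## Evaluating seed sets: the SIR contact process

Seed quality is measured by simulation under a discrete-time
susceptible–infected–recovered model with a **single-contact** rule: at
each step every infected node contacts *one* neighbour chosen uniformly at
random and infects it with probability $\beta$ if susceptible; at the same
time each node infected at the start of the step recovers with probability
$\mu$ (default 1, i.e. one infectious step). Contacts are resolved from the
step-start state and newly infected nodes become infectious the next step.
This contact rule spreads far more slowly than the more common
any-neighbour rule — with $\mu = 1$ each infected node gets exactly one
contact attempt, so the mean number of secondary infections is at most
$\beta$ and outbreaks are always subcritical. That matters when comparing
absolute spreading-scope values across implementations: published
large-outbreak figures are only reachable under the textbook rule in which
every susceptible neighbour receives an independent transmission attempt,
available here as `sir_config(contact = "all")`; the single-contact rule
remains the default because it is the model as literally specified.

The final spreading scope (FSS) is the recovered count at termination,
equal by construction to seeds plus all newly infected; the tests assert
this identity, compartment conservation, and three analytic limits (e.g.
$E[\mathrm{FSS}] = 1 + \beta$ on a single edge). Replicate ensembles derive
one RNG stream per replicate from a root seed, so any replicate is
reproducible in isolation. The sensible operating range for $\beta$ starts
just above the mean-field epidemic threshold
$\beta_{th} \approx \langle k\rangle / \langle k^2\rangle$
(`epidemic_threshold()`); the command-line front end defaults to
$1.5 \times \beta_{th}$ when no rate is given, a package choice logged at
run time.

Scatter is measured by `avg_spreader_distance()` (LS): the mean hop
distance over unordered seed pairs. The defining sum is written over the
whole vertex set in some formulations; here it is restricted to the seed
set, and pairs in different components are excluded from numerator and
denominator with the excluded count reported, rather than silently
contributing infinities.

## Benchmark rankers

Seven reference strategies are provided with tidy score/selection
interfaces: degree, closeness (component-restricted sums on disconnected
graphs; singleton components score 0), betweenness (unordered-pair
convention — the ordered variant differs by a constant factor and cannot
reorder nodes), VoteRank, HybridRank, indirect spreading strength (SC) and
the entropy-based improved k-shell (IKS), plus the simulation-based true
spreading ability (TSA). Design points where the literature is silent were
fixed as follows and frozen by tests:

* **VoteRank** weakening subtracts $f = 1/\langle k\rangle$ from a
  neighbour's voting ability, clamped at 0 — the canonical rule that keeps
  abilities in $[0,1]$.
* **HybridRank** multiplies the summed neighbour coreness (ICC) by the
  principal-eigenvector centrality. The eigenvector is computed per
  connected component by power iteration on $A + I$ (same eigenvector as
  $A$, but convergent on bipartite components), max-normalised, tolerance
  $10^{-10}$. When neighbour-pruning empties the candidate list before $P$
  picks, selection falls back to the highest-scoring remaining nodes.
* **SC** uses $c_{ij} = (1 + k_j^{out})(1 + |D_{ij,2}|)^{2\alpha}$ with
  $k_j^{out}$ the edges from $j$ leaving the closed neighbourhood of $i$
  and $D_{ij,2}$ the common neighbours. The published typography of this
  expression is ambiguous; this reading is isolated in one function so an
  alternative can be swapped without touching the aggregation. $\alpha$
  defaults to 1 and is user-settable; no per-network tuner is provided
  (the published tuning procedure is itself prohibitively expensive).
* **IKS** cycles shells from the highest down, taking each shell's current
  top-entropy node and skipping exhausted shells immediately; entropy ties
  are broken by node identifier (a deterministic stand-in for random
  choice, required for testability).

## Synthetic study conditions

All tests and the acceptance analysis run on synthetic graphs generated in
code. The planted-partition generator (`planted_partition()`) draws a
stochastic block model: blocks of given sizes, intra-block probability
`p_in`, inter-block probability `p_out`. The strong-community regime used
throughout (e.g. three blocks of 20–30 nodes, `p_in` 0.25–0.6, `p_out`
0.01–0.02) gives Louvain-recoverable blocks (≥95% label agreement in the
detection test) while keeping every suite fast; the hub-block fixture
(one denser block of 30 among blocks of 20) creates the degree-concentration
regime in which plain top-$k$ degree selection collapses into one block and
the community distribution visibly scatters it. Degree heterogeneity is
supplied separately by a preferential-attachment generator. Replicate
counts are 500 for synthetic spreading estimates and $10^4$ for the
two-node analytic check, sizes at which the Monte-Carlo error is far below
the asserted tolerances. What these fixtures do **not** emulate: the fat
tails, degree correlations and overlapping-community structure of large
real networks, so passing tests certify the algorithms' correctness and
qualitative behaviour, not the absolute spreading-scope values reported on
real data.

A deterministic library of hand-analysable toys (`toy_fixtures()`)
underpins the exact assertions: complete graphs, paths, stars, a 4-cycle,
K4 plus a pendant, two bridged 5-cliques and two disjoint triangles, each
with hand-derived shell indices, gravity scores and centralities frozen in
the tests.

## Reference tables

Two small published summary tables ship with the package:
`reference_networks()` (node/edge counts and topological summaries of nine
public benchmark networks) and `reference_fss()` (final spreading scope of
eight benchmark methods, simple vs community-distributed, on eight of those
networks at $\beta = 0.13$, $\mu = 1$, one seed per Louvain community).
They feed the arithmetic cross-checks — mean degree $2E/V$, per-cell profit
$\Delta = \mathrm{FSS}^\star/\mathrm{FSS}$ — and the profit aggregation
`profit_summary()`, which reports the mean of $\Delta - 1$ in percent both
with and without the TSA row, since the published headline average can be
read either way. Of note: the aggregations computed from the printed cells
(6.36% including TSA, 6.30% excluding) straddle but do not equal the 5.95%
headline figure those cells accompany; the discrepancy is inherent to the
source tables and the package reports what the cells actually give.

## Known limitations

* Louvain community counts are implementation- and seed-dependent;
  ground-truth membership files override detection precisely so that
  results do not hinge on detection drift.
* The single-contact SIR rule is the evaluation model, not a general
  epidemic simulator; SIS/SEIR and continuous-time dynamics are out of
  scope.
* TSA scores cost one SIR ensemble per node and are only practical on
  small graphs.
* Directed or weighted semantics are not supported; weights in edge lists
  are ignored with a warning.

## Problem sizes

The shipped test and acceptance analyses use graphs of 2–90 nodes for
exact/oracle checks, 50–300 nodes for generator and spreading behaviour,
$10^4$ replicates for the sharpest analytic ensemble check and 500
replicates per cell elsewhere — sizes chosen so the full distributional
claims are testable at interactive speed while leaving the estimators'
standard errors well inside the asserted bounds.
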