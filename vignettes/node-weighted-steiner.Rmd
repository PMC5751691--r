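---
title: "Identifying signaling-pathway elements with node-weighted Steiner trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying signaling-pathway elements with node-weighted Steiner trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nwsteiner)
```

## The problem and the model

Signals in a pathway such as PI3K/Akt enter through receptor proteins
(sources) and end at downstream effectors (terminals). Given a large
protein–protein interaction (PPI) network with experimentally derived
confidence scores, we want a small, credible subnetwork that connects all
of these pathway anchors — a candidate skeleton of the pathway at the
protein level.

`nwsteiner` casts this as a *node-weighted Steiner tree* problem on an
undirected network $G = (V, E, w, c)$: find a connected subnetwork
$G' = (V', E')$ containing every *compulsory terminal* $t \in T$ that
minimizes

$$\sum_{e \in E'} c(e) \;-\; \sum_{v \in V'} w(v),$$

where edge costs $c$ are *in-confidence* scores (cheap edges = credible
interactions) and node weights $w$ score how much we want a protein
included. Non-terminal proteins get mildly negative weights, so irrelevant
detours are penalised but not forbidden; terminals are REQUIRED.

Concretely, for an interaction with confidence score $con$,

$$c(i,j) = \frac{\alpha}{con^{\beta}},$$

and for a vertex of degree $d$ in the cleaned network,

$$w(i) = \begin{cases} -\gamma / d, & i \notin T \\ \text{REQUIRED}, & i \in T. \end{cases}$$

Interactions already annotated as pathway members have their confidence
score raised by the `boost` fraction (default 50%) before the cost
transform; the boost is applied to the raw score without clamping to any
nominal score ceiling, since the transform is monotone either way.

The REQUIRED status of terminals is the hard-constraint reading of an
"infinite" weight. We deliberately represent it as a sentinel
(`NA_real_`) rather than `Inf`: every computation that touches a terminal
weight branches on terminal membership, so no arithmetic ever produces
non-finite intermediate values, and the objective simply drops terminal
weights (a constant offset shared by all feasible solutions).

### Parameters and defaults

| parameter | default | role |
|---|---|---|
| `alpha` | $2 \times 10^6$ | scales costs; with typical experimental scores (roughly 80–1000) costs land around 100–300 |
| `beta` | 2 | spread between cheap and expensive edges; larger values trust the scores more aggressively |
| `gamma` | 5 | depth of the non-terminal penalty $-\gamma/d$; larger values prune exploratory vertices harder |
| `boost` | 0.5 | fractional confidence raise for annotated pathway interactions |
| `s` | 2 | edge-splitting ratio of the growing phase (1:1 split) |
| `mu` | $10^{-6} \times$ mean edge cost | merge tolerance ending the re-splitting of nearly-tight edges |
| `seed` | 1 | root draw of the pruning phase (the only randomness) |

`s` and `mu` are named by the algorithm but have no canonical published
values; the defaults here are the package's own choices. `s = 2` makes the
two halves of every edge symmetric, which is the neutral choice when no
vertex ordering is privileged, and `mu` is tied to the instance's cost
scale so that "nearly tight" means the same thing whether costs sit at 1
or at $10^6$.

## Instance construction

`build_instance()` cleans the raw records before anything else: self-loops
are dropped; parallel records of a pair collapse to the *minimum* cost
(the most confident evidence wins); vertex degrees for the weight formula
are taken on this cleaned graph, *never* after reductions, so a protein's
penalty reflects its real connectivity; and the graph is restricted to the
connected component holding the terminals (terminals spread across several
components make the instance infeasible and raise an error).

## Preprocessing: two degree-1 tests

Two classic Steiner reductions carry over to negative node weights with
extra guards:

* **Terminal degree-1**: if $|T| \ge 2$, the unique edge at a degree-1
  terminal is in every optimal solution. It is recorded as *forced*, the
  terminal is contracted into its neighbor, and the neighbor becomes a
  terminal. The guard matters: with $|T| = 1$ the lone terminal may itself
  be the whole optimum. Contraction order processes original terminals
  before newly created ones, so a path between two terminals contracts
  inward from both ends.
* **Non-terminal degree-1**: a non-terminal leaf $i$ with
  $w(i) \le c(i,j)$ can never pay for its own attachment
  ($c(i,j) - w(i) \ge 0$) and is deleted, provided $|T| \ge 1$.

Both tests are iterated to a mutual fixpoint by default, since removals
expose new leaves; `mode = "single_pass"` preserves the literal one-sweep
behavior for comparison. A single sweep is what the tests' $O(|V|)$
complexity describes; fixpointing costs little more in practice and never
reduces less. Every removal lands in a `reduction_ledger`; replaying the
ledger reproduces the reduced instance exactly, and re-attaching the
forced edges (in reverse order) turns a solution of the reduced instance
into a solution of the original. The accounting identity

$$\mathrm{opt}(\text{original}) = \mathrm{opt}(\text{reduced}) +
\sum_{\text{forced}} c(e) - \sum_{\text{absorbed}} w(u)$$

is verified against an exhaustive oracle in the test suite.

## The solver: moat growing with dynamic edge splitting, then strong pruning

The growing phase is an unrooted Goemans–Williamson process adapted to
node weights of either sign. Each vertex starts as a cluster whose slack
is its node weight; clusters with positive slack — and all
terminal-containing clusters, which never exhaust — are *active* and grow
moats under a global clock. Each edge is split into two parts with slacks
$c/s$ and $(s-1)c/s$, each draining only while its own side's cluster is
active. When a part drains, the partner's remaining slack $r$ decides:
below the tolerance `mu`, the two clusters merge (the new slack is the
*sum*, which can be negative — a merged cluster can be born inactive, the
key departure from the prize-collecting original); otherwise $r$ is
re-split — evenly when the partner is active, or wholly onto the draining
side when the partner is inactive, in which case the active side pays the
full remainder. The loop ends with at most one active cluster; its merge
edges form the raw tree. Should no active cluster remain (possible only
without terminals), the cluster deactivated last is used.

Strong pruning then roots the raw tree at a seeded-random terminal and
walks leaves inward: a subtree whose accumulated reward $nw(i)$ cannot pay
its connecting edge ($c(i,j) > nw(i)$) is cut; otherwise the parent
absorbs the surplus, $nw(j) \leftarrow nw(j) + nw(i) - c(i,j)$.
Terminal-bearing branches are never cut — REQUIRED dominates any cost and
propagates to the parent instead of entering the update arithmetic.

Two behavioral consequences are worth understanding:

* With the study-condition weights ($-\gamma/d$, tiny against costs of
  100–300), growth emanates from the terminals and merges along the
  cheapest meeting paths; pruning then removes unprofitable fringe. On
  random 9-vertex instances the heuristic matches the exhaustive optimum
  on roughly nine in ten instances and stays well inside a factor-2 band
  on the rest (both measured in the test suite).
* The growing phase is *cost-driven*: an inactive (negative-weight)
  cluster does not resist an incoming moat — the active side simply pays
  the whole edge. A strongly repellent vertex that happens to be the
  cheapest bridge between two terminals will therefore still be used, and
  pruning cannot remove an internal bridge. The test suite pins this down
  on a 3-vertex example where the heuristic takes a penalised 2-edge path
  (objective 120) although a single direct edge (objective 25) is optimal.
  Under realistic weight scales the regime never arises, but users who
  load hand-crafted weights should know the heuristic's failure mode.

Determinism: event ties are broken edge-before-cluster, then by stable
element order; the $i < j$ orientation of the edge split is byte-wise
(C-locale) order of the protein identifiers; the only random draw is the
pruning root, controlled by `seed`.

## Scoring: source-to-terminal betweenness

Classical betweenness treats all vertex pairs alike, but pathway signals
flow from sources $S$ to terminals $T'$. The betweenness degree of a
protein $m$ counts the ordered pairs $(i \in S, j \in T')$ whose unique
tree path contains $m$ — endpoints included, which is the only reading
consistent with leaf terminals scoring $|S|$ — and likewise for each
interaction. A protein that is both source and terminal scores its
degenerate pair on the vertex only. The implementation computes all
degrees in one rooted traversal from subtree source/terminal counts; an
independent per-pair path-walking oracle must agree on random trees, and
does. The documented inequality $B(m) \ge B(e_{mn})$ for every incident
interaction falls out of path containment and is property-tested.

Selection uses a threshold: elements with degree *strictly* above it are
reported. The `"auto"` rule is $\max(|S|, |T'|)$ — a vertex that merely
relays all pairs of one single source (or terminal) reaches exactly this
value, so strict exceedance isolates true junctions. On the shipped
reference subnetwork (8 sources, 14 terminals) this gives threshold 14 and
selects 9 proteins and 8 interactions; proteins sitting exactly at 14 (the
receptors) stay out. When the identified tree misses some annotated
sources or terminals, only those present are counted.

## The reference subnetwork and the synthetic generator

`pi3k_mapk_subnetwork()` ships the published 29-protein, 28-interaction
PI3K/Akt–MAPK subnetwork with its published betweenness degrees. The
8-source/14-terminal labeling is *derived*: the published material names
the role split but not the list, and the labeling shipped here is
validated by regenerating every one of the 57 published betweenness values
from it (a test in the default suite; any relabeling that also reproduces
all values would be equally acceptable). Greek and formatting variants of
protein names are stored under ASCII-safe canonical identifiers with a
display-name map.

`synth_ppi_instance()` emulates the structural conditions the method is
designed for: a connected, preferential-attachment-plus-random-edges
topology; uniform confidence scores on [80, 145], which the default cost
transform maps to costs of roughly 95–310 (median near 160, asserted to
sit in [50, 600] as the generator's frozen calibration band); and a
planted connected pathway providing flagged member edges, sources, and
terminals. It does **not** emulate hub-biased confidence structure,
score-quality heterogeneity, or the sheer scale of organism-wide PPI
networks — so passing tests demonstrate algorithmic correctness on
realistic local structure, not retrieval performance on real databases.
Oracle-checked tests use 9-vertex instances (exhaustive enumeration over
vertex subsets is exponential; 9 keeps the 30-instance suite in seconds),
and property tests use 100 random 12-vertex trees.

## Degenerate inputs and numerical choices

Single-vertex instances (a terminal whose whole neighborhood was reduced
away) are legal throughout; the empty tree is returned, with a warning,
only for instances without any terminal. Duplicate interaction records
keep the cheapest cost; zero or negative confidence scores are rejected
rather than clamped. All comparisons against the merge tolerance and the
brute-force optimum use absolute slack $10^{-8}$–$10^{-12}$, far below
any cost scale the transforms produce. Text round-trips (the STP-dialect
instance files) write numbers at 17 significant digits, so re-reading an
instance is bit-exact.

## Limitations

* The solver is a heuristic: optimality is typical but not guaranteed, and
  adversarial weight scales (see above) defeat it by design.
* Betweenness is only meaningful on trees (unique paths); the metrics
  refuse non-tree input rather than fall back to shortest-path counting.
* The package deliberately ships no database clients; organism-scale
  score matrices, identifier mapping, and pathway curation are upstream
  concerns.
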