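---
title: "Wiring-cost-aware null models for spatially embedded networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wiring-cost-aware null models for spatially embedded networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wirecost)
```

## The problem

Structural brain networks — and spatially embedded networks in general —
show a recurring set of architectural signatures: small-world organisation,
hierarchy (hubs that are less clustered than average), strong modularity,
and core structures such as the s-core and the rich club. The standard way
to argue that such a property is "special" is to compare the network
against degree-preserving random surrogates. But a physical network also
pays for its wiring: connections have lengths, long connections are
expensive, and most real connections are short. A property that looks
remarkable against unconstrained random surrogates may be a plain
consequence of the network's wiring budget.

`wirecost` implements the comparison machinery needed to make that
distinction. Given a spatially embedded, weighted, undirected network it
generates three surrogate ensembles that all preserve node count, edge
count and the exact degree sequence, and differ only in their spatial
constraint:

* **random** — unconstrained degree-preserving edge swaps;
* **spatial** — swaps are accepted only if afterwards the total Euclidean
  connection length of each of the four touched regions does not exceed
  that region's total in the source network, so per-region wiring budgets
  are conserved;
* **reduced** — swaps are accepted only if they shorten the wiring, driving
  the network towards (but not to) its minimal attainable wiring length.

Reading the results follows a simple logic: if the source network and all
spatially constrained surrogates score alike but differ from random
surrogates, the property is attributable to wiring constraints; if the
source differs from every ensemble, something beyond wiring economics —
plausibly function — is at work.

## The rewiring engine

One swap step draws two connections $(r_1, r_2)$ and $(r_3, r_4)$ uniformly
at random and proposes replacing them with $(r_1, r_3)$ and $(r_2, r_4)$.
Proposals creating self-connections or parallel links are rejected. The
replacement edges inherit the weights of the removed edges, so the multiset
of connection weights is invariant (node *strength* is deliberately not
preserved — only degree is). Random and spatial surrogates run until every
connection has been rewired 20 times on average, i.e.
$\lfloor 20\,n_e/2 \rfloor$ accepted swaps; the far more constrained
reduced surrogates use one rewiring per connection
($\lfloor n_e/2 \rfloor$) because length-reducing swaps become
progressively scarcer and the process saturates. Saturation (hitting the
consecutive-rejection cap, `max_attempts_factor` rejections per required
swap) is recorded in the ensemble provenance, not treated as an error.

Two readings of "the wiring is reduced in every step" are defensible, so
both are implemented and selectable via `reduced_mode`:
`"per_region_strict"` (the default; every one of the four touched regions'
totals strictly decreases) and `"total_length"` (only the sum of the two
new edges must be shorter than the sum of the two removed ones). Both
guarantee strictly decreasing total wiring per accepted swap; the default
is the more literal, more restrictive reading.

Connection lengths are always Euclidean distances between node coordinates,
recomputed on demand — curved fibre trajectories cannot survive rewiring
anyway, so straight-line lengths are the only consistent currency. The
per-proposal loop runs in compiled code; member $i$ of an ensemble seeds
the RNG with `seed + i`, which makes members independent and the ensemble
reproducible regardless of generation order.

Numerical tolerances: the spatial cap is enforced with a `1e-9` mm slack so
that revisiting a region's own original configuration is never rejected for
floating-point reasons; the reduced rules use a `1e-12` slack to keep
"strictly decreasing" meaningful in floating point.

## Minimally wired baselines

Two bottom-up constructions bound the wiring question from below. The
**absolute minimal (AM)** network places edges on exactly the $E$ closest
node pairs — by construction no other $E$-edge simple graph on the same
layout has shorter total wiring, which the tests verify exhaustively for
tiny networks. The **degree-preserving minimal (DPM)** network walks all
pairs from shortest to longest and accepts a pair only while both endpoints
are below their source degrees; it approximates the degree sequence closely
but can end with slightly fewer edges, because residual degree can become
unplaceable late in the pass. Distance ties are broken lexicographically in
node-table order, so both constructions are deterministic. Both are
unweighted (weight 1): they are compared to real networks by binary
similarity only, and inventing weights for them would add nothing.

## Similarity and displacement measures

Topological overlap uses a similarity quotient defined as intersection over
union of edge sets, i.e. $QS^b = |A \cap B| / |A \cup B|$, rather than the
classical Sørensen normalisation $2|A \cap B| / (|A| + |B|)$ (available via
`classical = TRUE`). The weighted variant must satisfy three boundary
conditions: 1 exactly when the weighted edge sets coincide, 0 when they are
disjoint, and reduction to $QS^b$ when all weights are equal. The
implementation pins those conditions with a min/max construction — shared
edges contribute $\min(C_{ij}, S_{ij})$ to the numerator while the union
mass counts $\max(C_{ij}, S_{ij})$ for shared edges and the full weight of
unshared ones. This is a design choice of this package: other weighted
overlap kernels satisfy the same boundary conditions, but this one is the
most direct weighted extension of intersection-over-union.

Spatial similarity asks a different question: how far did a region's
neighbourhood *move*? For each region the original and surrogate neighbour
sets are paired greedily by ascending cross-distance (ties broken by id,
each node used once); the optimal assignment is deliberately not computed —
with ~35 neighbours per region the exact matching is infeasible at scale,
and on near-uniform spatial layouts the greedy pairing is a close proxy
(the test suite compares it against brute-force optimal assignments on tiny
instances). The per-region displacement is the mean of
$d(\text{original}, \text{rewired}) / d(r, \text{original})$ over the
pairing; pairs whose original neighbour coincides spatially with $r$ would
divide by zero and are excluded with a warning. A `rewired_only` flag
restricts the average to pairs with nonzero displacement, isolating the
connections that actually moved.

## The metric battery

* **Global efficiency** — mean inverse shortest-path length with edge costs
  $1/w$; unreachable pairs contribute 0, so multiple components are handled
  gracefully. Averaging runs over unordered pairs, which for undirected
  networks equals the ordered-pair average.
* **Clustering** — the Onnela geometric-mean triangle form with weights
  normalised by the global maximum ($\hat w = w / \max w$), $C_i = 2 t_i /
  (k_i (k_i - 1))$, $C_i = 0$ for degree < 2. The global-maximum
  normalisation is a convention; the defining property it buys is
  $C_i = 1$ exactly for a node whose neighbourhood is fully connected at
  the maximal weight.
* **Small-world index** — $(C / \bar C_{rnd}) \times (E / \bar E_{rnd})$
  against the random-ensemble means, so the random ensemble scores 1 by
  definition; efficiency rather than path length keeps the index defined
  on disconnected networks.
* **Hierarchy** — mean clustering per degree bin normalised by the global
  mean clustering (bin width 5 by default; the binning is cosmetic), plus
  the node-level Spearman correlation of degree and clustering as a scalar
  indicator. A negative correlation — hubs less clustered than the average
  node — is the hierarchical signature.
* **Degree assortativity** — the edge-based Pearson form symmetrised over
  unordered endpoints; undefined (NA with a warning) when all endpoint
  degrees are equal.
* **k-core / s-core** — iterative peeling; the s-core sweep uses the exact
  attained collapse thresholds rather than a fixed grid, because strengths
  are continuous and a grid either misses the final collapse point or
  wastes work. The innermost core's threshold is the largest value at
  which the core is still non-empty.
* **Weighted rich club** — for the club $N_{>k}$ of nodes with degree above
  $k$, $\varphi^w(k)$ divides the internal weight by the sum of the
  $E^{max}_{>k} = \binom{|N_{>k}|}{2}$ globally strongest edge weights.
  It is 1 only when the club is fully interconnected by exactly the
  strongest connections, and on binary networks it equals the classical
  k-density. The denominator is undefined once $E^{max}_{>k}$ exceeds the
  edge count, so only clubs up to the largest $x$ with $x(x-1)/2 \le E$
  can be assessed; `max_assessable_club()` solves exactly that inequality.
  For $E = 17865$ this gives 188 or 189 nodes depending on whether the
  strict or non-strict form of the quadratic is solved; this package uses
  the non-strict reading ($x(x-1)/2 \le E$, giving 189) and documents the
  ambiguity rather than hiding it.

## Modularity and partition consistency

Module detection is Newman's spectral bisection applied to the weighted
modularity matrix $B_{ij} = w_{ij} - k^w_i k^w_j / 2W$: starting from the
connected components, each candidate module is split along the sign of the
leading eigenvector of its generalised modularity matrix, the split is kept
only when it increases global $Q$, and recursion stops when no split gains.
The method is deterministic given two tie rules, both implemented
explicitly: the eigenvector sign is canonicalised (largest-magnitude entry
positive) and zero entries join the positive block. Kernighan–Lin style
single-node refinement is available behind `fine_tune = TRUE` but off by
default, keeping the default algorithm the plain spectral method. On tiny
graphs the returned $Q$ is compared in the tests against exhaustive
enumeration of all partitions; the spectral heuristic is allowed a 0.05
absolute gap.

Partition consistency across an ensemble uses scaled inclusivity: for a
reference partition $C$ and a member partition $S$, module pair $(p, q)$
scores $|S_p \cap C_q|^2 / (|S_p||C_q|)$, and a node's score in one member
is that of the two modules containing it. The squared intersection
penalises both splitting and merging; identical modules score 1, disjoint
modules 0, and an all-singletons member scores $1/|C_q|$ for every node of
reference module $C_q$ — these boundary cases are asserted in the tests.

## The synthetic generator

Because the package must be testable without any proprietary connectome,
the `synthetic` module generates networks with the statistical features the
analyses assume: nodes on a sphere surface (or in a box), and edges drawn
without replacement with probability proportional to
$a_i a_j \exp(-d_{ij}/\lambda)$, where $\lambda$ is the distance-decay
scale and the optional per-node propensities $a_i$ (log-normal,
`propensity_sd`) produce the right-skewed, exponential-like degree
distributions seen in cortical parcellations. With `propensity_sd = 0` the
model is purely geometric. Sampling uses the exponential-keys method for
exact weighted sampling without replacement — it always terminates, needs
no rejection fallback, and is fully reproducible from the seed.

The shared test network (`cortical_like_fixture()`) uses 500 nodes on a
70 mm sphere, 8900 edges, $\lambda = 8$ mm and `propensity_sd = 0.6`,
calibrated once so the mean connection length lands in the 25–30 mm range
typical of cortical data, the degree distribution is right-skewed, and the
network is connected. Planted-module networks place cluster centres on a
deterministic Fibonacci sphere lattice — random centres can collide, which
would make planted-partition recovery a test of luck rather than of the
algorithm — with Gaussian scatter around each centre.

What the generator does *not* emulate: tractography biases, hemispheric
asymmetries, the empirical weight–distance correlation, or the exact
cortical degree sequence. Tests passing on these synthetic networks
therefore validate the algorithms and their qualitative orderings
(e.g. random surrogates nearly triple mean connection length while reduced
surrogates shorten it), not any data-specific magnitude.

## Statistical comparison

`run_analysis()` evaluates the metric battery on the source network and
every ensemble member and tests each source value against each ensemble
with a one-sample t-test by default (a signed-rank variant is available),
annotating significance with stars at 0.05 / 0.01 / 0.001 / 0.0001. Tests
default to two-sided; one-sided alternatives are a configuration field
because directional hypotheses differ per metric. An ensemble with zero
variance (e.g. copies of one network) is reported as degenerate rather
than tested. Per-region wiring-length distributions are compared with a
Wilcoxon rank-sum test in `wiring_statistics()`; when the two distributions
are identical to the tie level the test statistic degenerates and the
p-value is reported as 1.

## Problem sizes and determinism

The shipped tests and the reproduction script work at the fixture scale —
500 nodes, 8900 edges, 20 members per surrogate ensemble, 20 seeds for the
planted-module sweeps — sizes chosen so the full analysis of one network
completes in minutes on a single core while keeping every ordering
assertion comfortably away from sampling noise. All randomness flows from
one integer seed: generator networks are reproducible from their spec,
ensemble members from `seed + index`, and a repeated `run_analysis()` with
the same configuration reproduces its report byte for byte.

## Known limitations

* The greedy displacement pairing is an approximation; it can exceed the
  optimal assignment distance (logged comparisons in the test suite show
  it stays close on homogeneous layouts).
* The weighted similarity quotient's min/max kernel is one of several
  constructions satisfying the stated boundary properties.
* Spectral bisection is a heuristic; its $Q$ can trail the global optimum,
  and no consensus/Louvain alternative is provided.
* Reduced surrogates saturate rather than reach the true minimum wiring;
  the DPM baseline can carry more total length than a saturated reduced
  surrogate, so neither dominates the other by construction.
* Strength (weighted degree) is not preserved by rewiring — only the
  degree sequence and the weight multiset are.
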