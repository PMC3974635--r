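# wirecost

Wiring-cost-aware null models for spatially embedded, weighted, undirected
networks.

Physical networks — structural brain connectomes above all — pay for their
connections: edges have Euclidean lengths, long edges are expensive, and
most real connections are short. When such a network looks "special"
against ordinary degree-preserving random surrogates (small-world, modular,
hierarchical, rich-club…), the interesting question is how much of that is
just its wiring budget. `wirecost` answers it by comparison against three
surrogate ensembles that all preserve network size, connection density and
the exact degree sequence, and differ only in their spatial constraint:

| ensemble | swap acceptance rule |
|---|---|
| `random` | every valid degree-preserving swap |
| `spatial` | after the swap, each touched region's total connection length must not exceed its total in the source network |
| `reduced` | each swap must strictly shorten the wiring (per region, or in total) |

A swap replaces connections (r1, r2), (r3, r4) by (r1, r3), (r2, r4),
rejecting self-connections and parallel links; replacement edges inherit
the removed edges' weights. Random and spatial ensembles rewire each
connection 20 times on average (`floor(20 * E / 2)` swaps), reduced
surrogates once (`floor(E / 2)`), since length-reducing swaps run out and
the process saturates.

On top of the ensembles the package provides:

* **minimally wired baselines** — the absolute minimal network (E closest
  pairs; provably optimal total length) and the degree-preserving minimal
  network (greedy shortest-pairs pass capped by source degrees);
* **similarity measures** — binary and weighted similarity quotients
  (intersection-over-union of edge sets), greedy spatial pairing and the
  relative displacement D of rewired neighbourhoods, ensemble
  shared-connection ("skeleton") analysis;
* **a metric battery** — global efficiency (costs 1/w, multi-component
  safe), Onnela weighted clustering, small-world index
  SW = (C/C_rnd)(E/E_rnd), degree–clustering hierarchy curves, degree
  assortativity, k-core/s-core decomposition by iterative peeling, and a
  weighted rich-club density phi_w(k) that divides a club's internal
  weight by the sum of the globally strongest `choose(|club|, 2)` weights;
* **modularity tools** — Newman spectral partitioning of the weighted
  modularity matrix, modularity Q, scaled inclusivity
  |S∩C|²/(|S||C|) for partition consistency across ensembles, and module
  correspondence matrices;
* **a pipeline** — `run_analysis()` evaluates everything on source +
  ensembles, runs one-sample tests with star annotations, and writes
  JSON/TSV reports; a synthetic generator produces cortical-like test
  networks (distance-decay connectivity, right-skewed degrees) so no
  proprietary data is needed.

## Worked example

```r
library(wirecost)

net <- generate_network(synth_spec(120, 700, decay_scale = 12,
                                   propensity_sd = 0.5, seed = 42))
cfg <- analysis_config(n_surrogates = 5,
                       metrics = c("qs_binary", "mean_edge_length",
                                   "clustering", "efficiency",
                                   "small_world", "modularity"),
                       seed = 7)
report <- run_analysis(net, cfg)
tidy(report)
```

```
   metric           surrogate_type source_value ensemble_mean ensemble_sd  stars
 1 qs_binary        random               1            0.0636     0.00995   ****
 2 qs_binary        spatial              1            0.527      0.00962   ****
 3 qs_binary        reduced              1            0.748      0.0104    ****
 4 mean_edge_length random              36.4         93.3        1.74      ****
 5 mean_edge_length spatial             36.4         35.0        0.131     ****
 6 mean_edge_length reduced             36.4         33.6        0.252     ****
 7 clustering       random               0.0187       0.00418    0.000429  ****
 8 clustering       spatial              0.0187       0.0199     0.000297  ***
 9 clustering       reduced              0.0187       0.0220     0.000605  ***
10 efficiency       random               0.875        0.954      0.0108    ****
11 efficiency       spatial              0.875        0.840      0.00706   ***
12 efficiency       reduced              0.875        0.856      0.0124    *
13 small_world      random               4.10         1.00       0.111     ****
14 small_world      spatial              4.10         4.19       0.0689    *
15 small_world      reduced              4.10         4.71       0.129     ***
16 modularity       random               0.552        0.293      0.0201    ****
17 modularity       spatial              0.552        0.546      0.0305
18 modularity       reduced              0.552        0.549      0.0479
```

Reading the table: unconstrained randomisation nearly triples the mean
connection length (36.4 → 93.3 mm), collapses clustering (0.019 → 0.004)
and halves modularity (0.55 → 0.29), while the spatially constrained
ensembles stay close to the source on every metric — here the network's
small-world and modular appearance is largely carried by its wiring
constraints (for modularity the source is statistically indistinguishable
from its spatial and reduced surrogates: no stars). The random ensemble's
small-world index is 1 by construction, since the index is defined
relative to the random-ensemble means.

Each result type also has a plot: `autoplot(report)` draws the bar-chart
summary with significance stars, and `autoplot()` works on hierarchy curves,
core-decomposition profiles and rich-club profiles.

A thin CLI wraps the same functions for shell use:

```sh
inst/scripts/wirecost synth --n 200 --edges 1200 --decay 10 --seed 1 --out-prefix demo
inst/scripts/wirecost surrogates --type spatial --n 20 --seed 1 \
    --nodes demo_nodes.tsv --edges demo_edges.tsv --out-dir surr/
inst/scripts/wirecost modules --nodes demo_nodes.tsv --edges demo_edges.tsv --out partition.tsv
```

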