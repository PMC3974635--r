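#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Degree-preserving edge-swap engine.
//
// Repeatedly proposes replacing a random pair of edges (r1,r2),(r3,r4) by
// (r1,r3),(r2,r4); proposals creating self-loops or parallel links are
// rejected. Acceptance rules by surrogate type:
//   random  - always accept
//   spatial - accept iff after the swap the total Euclidean connection
//             length of each of the four touched nodes does not exceed that
//             node's total in the source network (src_len)
//   reduced - per_region_strict: each touched node's total strictly drops;
//             total_length: summed length of the two new edges is strictly
//             smaller than that of the two removed ones
// Replacement edges inherit the weights of the removed edges:
// (r1,r3) <- w(r1,r2), (r2,r4) <- w(r3,r4). Weight multiset and degree
// sequence are therefore invariant.
//
// edges: E x 2 matrix of 0-based node indices; coords: n x 3 positions;
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
List rewire_engine_cpp(IntegerMatrix edges, NumericVector weights,
                       NumericMatrix coords, int type, int reduced_mode,
                       double required_swaps, double max_consec_reject,
                       double slack) {
  const int E = edges.nrow();
  const int n = coords.nrow();
  std::vector<int> eu(E), ev(E);
  std::vector<double> w(E);
  for (int e = 0; e < E; ++e) {
    eu[e] = edges(e, 0);
    ev[e] = edges(e, 1);
    w[e] = weights[e];
  }
  // dense adjacency flags (n <= a few thousand in intended use)
  std::vector<char> adj((size_t)n * n, 0);
  std::vector<double> totlen(n, 0.0);
  auto dist = [&](int a, int b) {
    double dx = coords(a, 0) - coords(b, 0);
    double dy = coords(a, 1) - coords(b, 1);
    double dz = coords(a, 2) - coords(b, 2);
    return std::sqrt(dx * dx + dy * dy + dz * dz);
  };
  for (int e = 0; e < E; ++e) {
    adj[(size_t)eu[e] * n + ev[e]] = 1;
    adj[(size_t)ev[e] * n + eu[e]] = 1;
    double d = dist(eu[e], ev[e]);
    totlen[eu[e]] += d;
    totlen[ev[e]] += d;
  }
  std::vector<double> src_len(totlen);  // source per-node totals

  double accepted = 0.0, attempted = 0.0, consec = 0.0;
  while (accepted < required_swaps && consec < max_consec_reject) {
    attempted += 1.0;
    consec += 1.0;
    int e1 = (int)(unif_rand() * E);
    int e2 = (int)(unif_rand() * E);
    if (e1 >= E) e1 = E - 1;
    if (e2 >= E) e2 = E - 1;
    if (e1 == e2) continue;
    int r1 = eu[e1], r2 = ev[e1], r3 = eu[e2], r4 = ev[e2];
    if (r1 == r3 || r2 == r4) continue;                    // self-loops
    if (adj[(size_t)r1 * n + r3] || adj[(size_t)r2 * n + r4]) continue;

    // after the checks above r1, r2, r3, r4 are pairwise distinct
    double d12 = dist(r1, r2), d34 = dist(r3, r4);
    double d13 = dist(r1, r3), d24 = dist(r2, r4);
    bool ok = true;
    if (type == 1) {            // spatial: per-node cap at source totals
      ok = (totlen[r1] - d12 + d13 <= src_len[r1] + slack) &&
           (totlen[r2] - d12 + d24 <= src_len[r2] + slack) &&
           (totlen[r3] - d34 + d13 <= src_len[r3] + slack) &&
           (totlen[r4] - d34 + d24 <= src_len[r4] + slack);
    } else if (type == 2) {
      if (reduced_mode == 0) {  // per_region_strict
        ok = (d13 < d12 - slack) && (d24 < d12 - slack) &&
             (d13 < d34 - slack) && (d24 < d34 - slack);
      } else {                  // total_length
        ok = (d13 + d24 < d12 + d34 - slack);
      }
    }
    if (!ok) continue;

    adj[(size_t)r1 * n + r2] = adj[(size_t)r2 * n + r1] = 0;
    adj[(size_t)r3 * n + r4] = adj[(size_t)r4 * n + r3] = 0;
    adj[(size_t)r1 * n + r3] = adj[(size_t)r3 * n + r1] = 1;
    adj[(size_t)r2 * n + r4] = adj[(size_t)r4 * n + r2] = 1;
    totlen[r1] += d13 - d12;
    totlen[r2] += d24 - d12;
    totlen[r3] += d13 - d34;
    totlen[r4] += d24 - d34;
    eu[e1] = r1; ev[e1] = r3;   // inherits w[e1] = w(r1,r2)
    eu[e2] = r2; ev[e2] = r4;   // inherits w[e2] = w(r3,r4)
    accepted += 1.0;
    consec = 0.0;
  }

  IntegerMatrix out(E, 2);
  for (int e = 0; e < E; ++e) {
    out(e, 0) = eu[e];
    out(e, 1) = ev[e];
  }
  return List::create(_["edges"] = out, _["weights"] = NumericVector(w.begin(), w.end()),
                      _["accepted"] = accepted, _["attempted"] = attempted,
                      _["saturated"] = (accepted < required_swaps));
}
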