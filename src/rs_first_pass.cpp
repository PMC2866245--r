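#include <Rcpp.h>
#include <queue>
#include <vector>
#include <utility>
using namespace Rcpp;

// First pass of classical Ruge-Stuben C/F splitting on a symmetric
// strong-connection graph given in compressed-sparse-column form (sp:
// column pointers, si: 0-based row indices; the pattern must be symmetric
// so columns double as rows).  Forced nodes (0-based) are seeded as
// C-points before the greedy loop.  Returns an integer state vector with
// 1 = C-point, 2 = F-point.
//
// Measures start as the strong degree; when a node becomes an F-point the
// measures of its other unassigned strong neighbours are incremented, so
// nodes useful for interpolating many F-points are preferred.  Ties are
// broken towards the lowest node index, making the split deterministic.
// Nodes without strong connections end with measure 0 and are taken as
// C-points (isolated blocks must survive coarsening on their own).
// [[Rcpp::export]]
IntegerVector rs_first_pass_cpp(IntegerVector sp, IntegerVector si, int n,
                                IntegerVector forced) {
  std::vector<int> state(n, 0); // 0 unassigned, 1 C, 2 F
  std::vector<long> lambda(n);
  for (int j = 0; j < n; ++j) lambda[j] = sp[j + 1] - sp[j];

  // seed forced C-points first so they can never be demoted
  for (int t = 0; t < forced.size(); ++t) state[forced[t]] = 1;
  for (int t = 0; t < forced.size(); ++t) {
    int c = forced[t];
    for (int e = sp[c]; e < sp[c + 1]; ++e) {
      int f = si[e];
      if (state[f] != 0) continue;
      state[f] = 2;
      for (int u = sp[f]; u < sp[f + 1]; ++u) {
        int k = si[u];
        if (state[k] == 0) lambda[k] += 1;
      }
    }
  }

  typedef std::pair<long, int> entry; // (measure, -index): max-heap, low index wins ties
  std::priority_queue<entry> pq;
  for (int j = 0; j < n; ++j)
    if (state[j] == 0) pq.push(entry(lambda[j], -j));

  while (!pq.empty()) {
    entry top = pq.top();
    pq.pop();
    int c = -top.second;
    if (state[c] != 0 || lambda[c] != top.first) continue; // stale entry
    state[c] = 1;
    for (int e = sp[c]; e < sp[c + 1]; ++e) {
      int f = si[e];
      if (state[f] != 0) continue;
      state[f] = 2;
      for (int u = sp[f]; u < sp[f + 1]; ++u) {
        int k = si[u];
        if (state[k] == 0) {
          lambda[k] += 1;
          pq.push(entry(lambda[k], -k));
        }
      }
    }
  }
  return IntegerVector(state.begin(), state.end());
}
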