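// Coalescent sampler of independent polarized sites for a four-taxon
// (((P1, P2), P3), O) phylogeny with no migration. Each site carries its
// own gene genealogy (the infinite-sites, one-mutation-per-locus limit),
// so per-site ABBA/BABA terms are independent across sites — the sampling
// regime under which the block-jackknife D test is expected to be
// calibrated. Used for null-calibration experiments.

#include <Rcpp.h>
#include <random>
using namespace Rcpp;

namespace {

struct Node {
  int parent = -1;
  double time = 0.0, blen = 0.0;
};

}  // namespace

// [[Rcpp::export(name = ".quartet_sites_cpp")]]
NumericMatrix quartet_sites_cpp(int n1, int n2, int n3, int no,
                                double ne, double t1, double t2, double t3,
                                int n_sites, int seed) {
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  int n = n1 + n2 + n3 + no;
  NumericMatrix out(n_sites, 3);
  int filled = 0;
  long guard = 0;
  std::vector<Node> nodes;
  std::vector<int> act[4];
  std::vector<int> merged;
  while (filled < n_sites) {
    if (++guard > 200L * n_sites)
      stop("quartet site sampler failed to accept enough sites");
    nodes.assign(2 * n - 1, Node());
    for (int p = 0; p < 4; ++p) act[p].clear();
    int idx = 0;
    for (int i = 0; i < n1; ++i) act[0].push_back(idx++);
    for (int i = 0; i < n2; ++i) act[1].push_back(idx++);
    for (int i = 0; i < n3; ++i) act[2].push_back(idx++);
    for (int i = 0; i < no; ++i) act[3].push_back(idx++);
    int nxt = n;
    double t = 0.0;
    double breaks[4] = {t1, t2, t3, std::numeric_limits<double>::infinity()};
    int n_pops = 4;
    for (int ep = 0; ep < 4; ++ep) {
      double t_end = breaks[ep];
      for (;;) {
        double tot = 0.0;
        for (int p = 0; p < n_pops; ++p) {
          double k = (double)act[p].size();
          tot += k * (k - 1.0) / 2.0 / (2.0 * ne);
        }
        if (tot <= 0.0) break;
        double dt = -std::log(unif(rng)) / tot;
        if (t + dt >= t_end) break;
        t += dt;
        double u = unif(rng) * tot, acc = 0.0;
        int psel = 0;
        for (int p = 0; p < n_pops; ++p) {
          double k = (double)act[p].size();
          acc += k * (k - 1.0) / 2.0 / (2.0 * ne);
          if (u <= acc) { psel = p; break; }
        }
        std::vector<int> &a = act[psel];
        int i = (int)(unif(rng) * a.size());
        int j = (int)(unif(rng) * (a.size() - 1));
        if (j >= i) ++j;
        int ci = a[i], cj = a[j];
        nodes[nxt].time = t;
        nodes[ci].parent = nxt; nodes[ci].blen = t - nodes[ci].time;
        nodes[cj].parent = nxt; nodes[cj].blen = t - nodes[cj].time;
        if (i > j) std::swap(i, j);
        a.erase(a.begin() + j);
        a.erase(a.begin() + i);
        a.push_back(nxt);
        ++nxt;
      }
      if (ep == 3) break;
      t = t_end;
      // merge: epoch 0 end joins P1+P2; epoch 1 end +P3; epoch 2 end +O
      merged = act[0];
      merged.insert(merged.end(), act[1].begin(), act[1].end());
      act[0] = merged;
      for (int p = 1; p < n_pops - 1; ++p) act[p] = act[p + 1];
      act[n_pops - 1].clear();
      --n_pops;
    }
    // single mutation uniform on the genealogy
    double total = 0.0;
    for (int v = 0; v < nxt; ++v) total += nodes[v].blen;
    double u = unif(rng) * total, acc = 0.0;
    int mb = 0;
    for (int v = 0; v < nxt; ++v) {
      acc += nodes[v].blen;
      if (u <= acc) { mb = v; break; }
    }
    // derived carriers: tips descending from mb
    std::vector<bool> derived(n, false);
    for (int tip = 0; tip < n; ++tip) {
      for (int v = tip; v != -1; v = nodes[v].parent) {
        if (v == mb) { derived[tip] = true; break; }
      }
    }
    int c1 = 0, c2 = 0, c3 = 0, co = 0;
    for (int i = 0; i < n1; ++i) c1 += derived[i];
    for (int i = 0; i < n2; ++i) c2 += derived[n1 + i];
    for (int i = 0; i < n3; ++i) c3 += derived[n1 + n2 + i];
    for (int i = 0; i < no; ++i) co += derived[n1 + n2 + n3 + i];
    if (co != 0 && co != no) continue;      // outgroup polymorphic: drop
    bool anc0 = co == 0;                    // outgroup carries the ancestral state
    double p1 = (double)c1 / n1, p2 = (double)c2 / n2, p3 = (double)c3 / n3;
    if (!anc0) { p1 = 1 - p1; p2 = 1 - p2; p3 = 1 - p3; }
    if (p1 == 0 && p2 == 0 && p3 == 0) continue;  // invariant in the ingroup
    out(filled, 0) = p1;
    out(filled, 1) = p2;
    out(filled, 2) = p3;
    ++filled;
  }
  return out;
}
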