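// Forward Wright-Fisher engine for two-population divergence scenarios.
//
// Diploid individuals, discrete non-overlapping generations, multiplicative
// fitness across sites with codominance (h = 0.5), Poisson mutation and
// crossover counts on a finite integer-coordinate chromosome with collision
// resampling. Selected mutations arise only in the two distal thirds of the
// chromosome ("tails"); the central third is always neutral. An ancestral
// population of size N evolves for t_burn generations, splits into two
// daughters of size N, and diverges for t_div generations with optional
// symmetric migration. Haplotypes store mutation ids sorted by position;
// the id table is compacted whenever fixed/lost mutations are purged.

#include <Rcpp.h>
#include <random>
#include <unordered_set>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct Mut {
  int pos;
  double s0, s1;  // selection coefficient in population 0 / 1
};

struct Hap {
  std::vector<int> m;    // all mutation ids, sorted by position
  std::vector<int> sel;  // subset with a nonzero fitness effect
};

enum Scenario { NEUTRAL = 0, BGS = 1, BDMI = 2, POSITIVE = 3,
                BGS_POSITIVE = 4, LOCAL = 5 };

struct Engine {
  int N;
  double L, mu, rec;
  double s_neg, prop_neg, s_pos, prop_pos, mig;
  int scenario;
  bool ancestral_selection;
  double standing_prop;

  std::vector<Mut> muts;
  std::unordered_set<int> used_pos;
  std::vector<Hap> pop[2];
  std::vector<int> fixed_ids[2];  // per-pop fixed mutations removed from haps
  int n_pops = 1;
  std::mt19937_64 rng;

  bool in_tail(int pos) const {
    double third = L / 3.0;
    return pos < third || pos >= 2.0 * third;
  }

  bool selected(int id) const {
    return muts[id].s0 != 0.0 || muts[id].s1 != 0.0;
  }

  // selection assignment for a brand-new mutation
  void assign_effect(Mut &m, bool post_split) {
    m.s0 = m.s1 = 0.0;
    if (!in_tail(m.pos)) return;
    std::uniform_real_distribution<double> u(0.0, 1.0);
    switch (scenario) {
    case NEUTRAL: break;
    case BGS:
      if (u(rng) < prop_neg) m.s0 = m.s1 = s_neg;
      break;
    case BDMI:
      if (!post_split) {
        if (ancestral_selection && u(rng) < prop_neg) m.s0 = m.s1 = s_neg;
      } else if (u(rng) < prop_neg) {
        if (u(rng) < 0.5) m.s0 = s_neg; else m.s1 = s_neg;
      }
      break;
    case POSITIVE:
      if (u(rng) < prop_pos) m.s0 = m.s1 = s_pos;
      break;
    case BGS_POSITIVE: {
      double x = u(rng);
      if (x < prop_neg) m.s0 = m.s1 = s_neg;
      else if (x < prop_neg + prop_pos) m.s0 = m.s1 = s_pos;
      break;
    }
    case LOCAL:
      if (post_split && u(rng) < prop_pos) {
        if (u(rng) < 0.5) m.s0 = s_pos; else m.s1 = s_pos;
      }
      break;
    }
  }

  int new_mutation(bool post_split) {
    std::uniform_int_distribution<int> upos(0, (int)L - 1);
    int pos = upos(rng);
    int tries = 0;
    while (used_pos.count(pos)) {
      pos = upos(rng);
      if (++tries > 1000000) stop("no free mutation positions left");
    }
    used_pos.insert(pos);
    Mut m;
    m.pos = pos;
    assign_effect(m, post_split);
    muts.push_back(m);
    return (int)muts.size() - 1;
  }

  // copy ids from src with position in [lo, hi) into dst
  void copy_range(const std::vector<int> &src, std::vector<int> &dst,
                  double lo, double hi) {
    auto cmp = [this](int id, double p) { return muts[id].pos < p; };
    auto a = std::lower_bound(src.begin(), src.end(), lo, cmp);
    auto b = std::lower_bound(src.begin(), src.end(), hi, cmp);
    dst.insert(dst.end(), a, b);
  }

  void make_gamete(const Hap &h1, const Hap &h2, Hap &out, bool post_split) {
    out.m.clear();
    out.sel.clear();
    std::poisson_distribution<int> pois_x(rec * L);
    int k = pois_x(rng);
    std::uniform_real_distribution<double> upos(0.0, L);
    std::vector<double> cuts(k);
    for (int i = 0; i < k; ++i) cuts[i] = upos(rng);
    std::sort(cuts.begin(), cuts.end());
    cuts.push_back(L + 1.0);
    std::uniform_int_distribution<int> coin(0, 1);
    int cur = coin(rng);
    double lo = 0.0;
    for (double hi : cuts) {
      const Hap &h = cur ? h2 : h1;
      copy_range(h.m, out.m, lo, hi);
      copy_range(h.sel, out.sel, lo, hi);
      lo = hi;
      cur = 1 - cur;
    }
    // new mutations, inserted in position order
    std::poisson_distribution<int> pois_m(mu * L);
    int nm = pois_m(rng);
    for (int i = 0; i < nm; ++i) {
      int id = new_mutation(post_split);
      auto cmp = [this](int a, int b) { return muts[a].pos < muts[b].pos; };
      out.m.insert(std::upper_bound(out.m.begin(), out.m.end(), id, cmp), id);
      if (selected(id))
        out.sel.insert(std::upper_bound(out.sel.begin(), out.sel.end(), id, cmp), id);
    }
  }

  // log fitness of individual (two haplotypes) in population p
  double log_fitness(const Hap &h1, const Hap &h2, int p) const {
    double lw = 0.0;
    size_t i = 0, j = 0;
    const std::vector<int> &a = h1.sel, &b = h2.sel;
    while (i < a.size() || j < b.size()) {
      int id;
      bool hom = false;
      if (i < a.size() && j < b.size() && a[i] == b[j]) {
        id = a[i]; hom = true; ++i; ++j;
      } else if (j >= b.size() ||
                 (i < a.size() && muts[a[i]].pos < muts[b[j]].pos)) {
        id = a[i]; ++i;
      } else {
        id = b[j]; ++j;
      }
      double s = p == 0 ? muts[id].s0 : muts[id].s1;
      if (s != 0.0) lw += hom ? std::log1p(s) : std::log1p(0.5 * s);
    }
    return lw;
  }

  bool has_selection() const {
    if (scenario == NEUTRAL) return false;
    if (scenario == LOCAL && n_pops == 1) return false;
    if (scenario == BDMI && n_pops == 1 && !ancestral_selection) return false;
    return true;
  }

  // one generation; returns realized migrant count
  int step(bool post_split) {
    int migrants = 0;
    std::uniform_real_distribution<double> u(0.0, 1.0);
    std::vector<std::discrete_distribution<int>> pick(n_pops);
    bool sel_on = has_selection();
    for (int p = 0; p < n_pops; ++p) {
      if (!sel_on) continue;
      std::vector<double> w(N);
      double mx = -1e300;
      for (int i = 0; i < N; ++i) {
        w[i] = log_fitness(pop[p][2 * i], pop[p][2 * i + 1], p);
        if (w[i] > mx) mx = w[i];
      }
      if (!(mx > -1e300)) stop("fitness collapse: all individuals inviable");
      for (int i = 0; i < N; ++i) w[i] = std::exp(w[i] - mx);
      pick[p] = std::discrete_distribution<int>(w.begin(), w.end());
    }
    std::uniform_int_distribution<int> uind(0, N - 1);
    std::vector<Hap> next[2];
    for (int p = 0; p < n_pops; ++p) next[p].resize(2 * N);
    for (int p = 0; p < n_pops; ++p) {
      for (int i = 0; i < N; ++i) {
        int src = p;
        if (n_pops == 2 && mig > 0.0 && u(rng) < mig) {
          src = 1 - p;
          ++migrants;
        }
        for (int h = 0; h < 2; ++h) {
          int par = sel_on ? pick[src](rng) : uind(rng);
          make_gamete(pop[src][2 * par], pop[src][2 * par + 1],
                      next[p][2 * i + h], post_split);
        }
      }
    }
    for (int p = 0; p < n_pops; ++p) pop[p].swap(next[p]);
    return migrants;
  }

  // remove lost and fixed mutations, compacting the id table
  void purge() {
    std::vector<int> cnt(muts.size(), 0);
    for (int p = 0; p < n_pops; ++p)
      for (const Hap &h : pop[p])
        for (int id : h.m) cnt[id]++;
    // per-pop counts only needed when per-pop fixation is resolvable
    bool perpop = n_pops == 2 && mig == 0.0;
    std::vector<int> cnt0;
    if (perpop) {
      cnt0.assign(muts.size(), 0);
      for (const Hap &h : pop[0])
        for (int id : h.m) cnt0[id]++;
    }
    int total = 2 * N * n_pops;
    std::vector<int> remap(muts.size(), -1);
    std::vector<Mut> kept;
    std::vector<int> fix_in_pop(muts.size(), -1);
    std::vector<char> in_fixed(muts.size(), 0);
    for (int p = 0; p < 2; ++p)
      for (int id : fixed_ids[p]) in_fixed[id] = 1;
    for (size_t id = 0; id < muts.size(); ++id) {
      bool keep = false;
      if (cnt[id] == 0) {
        // lost everywhere: free the position unless it is a recorded
        // per-pop substitution (then it stays a fixed difference)
        if (!in_fixed[id]) used_pos.erase(muts[id].pos);
        keep = false;
      } else if (cnt[id] == total) {
        // fixed in every population: invariant for all contrasts; drop,
        // keeping the position blocked (substituted sites stay biallelic)
        keep = false;
      } else if (perpop) {
        int c0 = cnt0[id], c1 = cnt[id] - c0;
        if (c0 == 2 * N && c1 < 2 * N) fix_in_pop[id] = 0;
        else if (c1 == 2 * N && c0 < 2 * N) fix_in_pop[id] = 1;
        keep = true;
      } else {
        keep = true;
      }
      if (keep) {
        remap[id] = (int)kept.size();
        kept.push_back(muts[id]);
      }
    }
    // previously recorded fixed ids must survive the remap too
    for (int p = 0; p < 2; ++p) {
      for (int &id : fixed_ids[p]) {
        if (remap[id] < 0) {
          remap[id] = (int)kept.size();
          kept.push_back(muts[id]);
        }
      }
    }
    for (int p = 0; p < n_pops; ++p) {
      bool drop_fixed_here = perpop;
      for (Hap &h : pop[p]) {
        size_t o = 0;
        for (int id : h.m) {
          if (remap[id] < 0) continue;
          if (drop_fixed_here && fix_in_pop[id] == p) continue;
          h.m[o++] = remap[id];
        }
        h.m.resize(o);
        o = 0;
        for (int id : h.sel) {
          if (remap[id] < 0) continue;
          if (drop_fixed_here && fix_in_pop[id] == p) continue;
          h.sel[o++] = remap[id];
        }
        h.sel.resize(o);
      }
    }
    for (int p = 0; p < 2; ++p)
      for (int &id : fixed_ids[p]) id = remap[id];
    if (perpop) {
      for (size_t id = 0; id < muts.size(); ++id) {
        if (fix_in_pop[id] >= 0)
          fixed_ids[fix_in_pop[id]].push_back(remap[id]);
      }
    }
    muts.swap(kept);
    // note: used positions of dropped mutations stay blocked; substituted
    // sites cannot mutate back to a second biallelic state
  }

  // recruit standing neutral tail variation at the split (local adaptation)
  void recruit_standing() {
    std::uniform_real_distribution<double> u(0.0, 1.0);
    for (size_t id = 0; id < muts.size(); ++id) {
      if (selected((int)id) || !in_tail(muts[id].pos)) continue;
      if (u(rng) < standing_prop) {
        if (u(rng) < 0.5) muts[id].s0 = s_pos; else muts[id].s1 = s_pos;
      }
    }
    // rebuild sel lists to include the recruits
    for (int p = 0; p < n_pops; ++p) {
      for (Hap &h : pop[p]) {
        h.sel.clear();
        for (int id : h.m)
          if (selected(id)) h.sel.push_back(id);
      }
    }
  }

  // genotype sample: n_sample diploids per population
  List sample_pops(int n_sample) {
    std::vector<std::vector<int>> ids_per_ind;
    int np = n_pops;
    for (int p = 0; p < np; ++p) {
      std::vector<int> perm(N);
      for (int i = 0; i < N; ++i) perm[i] = i;
      std::shuffle(perm.begin(), perm.end(), rng);
      for (int i = 0; i < n_sample; ++i) {
        for (int h = 0; h < 2; ++h) {
          std::vector<int> v = pop[p][2 * perm[i] + h].m;
          v.insert(v.end(), fixed_ids[p].begin(), fixed_ids[p].end());
          std::sort(v.begin(), v.end());
          ids_per_ind.push_back(v);
        }
      }
    }
    int n_hap = (int)ids_per_ind.size();
    // union of carried ids, dropping those carried by every haplotype
    std::vector<int> carry(muts.size(), 0);
    for (auto &v : ids_per_ind)
      for (int id : v) carry[id]++;
    std::vector<int> site_ids;
    for (size_t id = 0; id < muts.size(); ++id)
      if (carry[id] > 0 && carry[id] < n_hap) site_ids.push_back((int)id);
    std::sort(site_ids.begin(), site_ids.end(),
              [this](int a, int b) { return muts[a].pos < muts[b].pos; });
    std::vector<int> col(muts.size(), -1);
    for (size_t j = 0; j < site_ids.size(); ++j) col[site_ids[j]] = (int)j;
    int n_ind = n_hap / 2;
    IntegerMatrix dosage((int)site_ids.size(), n_ind);
    std::fill(dosage.begin(), dosage.end(), 0);
    for (int hp = 0; hp < n_hap; ++hp) {
      int ind = hp / 2;
      for (int id : ids_per_ind[hp])
        if (col[id] >= 0) dosage(col[id], ind) += 1;
    }
    IntegerVector positions((int)site_ids.size());
    for (size_t j = 0; j < site_ids.size(); ++j)
      positions[j] = muts[site_ids[j]].pos;
    return List::create(_["positions"] = positions, _["dosage"] = dosage,
                        _["n_pops"] = np);
  }
};

}  // namespace

// [[Rcpp::export(name = ".wf_simulate_cpp")]]
List wf_simulate_cpp(int N, double L, double mu, double rec,
                     double s_neg, double prop_neg,
                     double s_pos, double prop_pos,
                     double mig, int scenario, bool ancestral_selection,
                     double standing_prop, int t_burn, int t_div,
                     IntegerVector sample_times, int n_sample, int seed,
                     int purge_every = 50) {
  Engine e;
  e.N = N; e.L = L; e.mu = mu; e.rec = rec;
  e.s_neg = s_neg; e.prop_neg = prop_neg;
  e.s_pos = s_pos; e.prop_pos = prop_pos;
  e.mig = mig; e.scenario = scenario;
  e.ancestral_selection = ancestral_selection;
  e.standing_prop = standing_prop;
  e.rng.seed((uint64_t)seed);
  e.n_pops = 1;
  e.pop[0].assign(2 * N, Hap());

  for (int g = 1; g <= t_burn; ++g) {
    e.step(false);
    if (g % purge_every == 0) e.purge();
    if (g % 500 == 0) Rcpp::checkUserInterrupt();
  }
  e.purge();
  // split: daughters start as copies of the ancestor
  e.pop[1] = e.pop[0];
  e.n_pops = 2;
  if (e.scenario == LOCAL && standing_prop > 0.0) e.recruit_standing();

  std::vector<int> times(sample_times.begin(), sample_times.end());
  List samples(times.size());
  CharacterVector names(times.size());
  IntegerVector migrants(t_div);
  size_t ti = 0;
  while (ti < times.size() && times[ti] <= 0) {
    samples[ti] = e.sample_pops(n_sample);
    names[ti] = std::to_string(times[ti]);
    ++ti;
  }
  for (int g = 1; g <= t_div; ++g) {
    migrants[g - 1] = e.step(true);
    if (g % purge_every == 0) e.purge();
    if (g % 500 == 0) Rcpp::checkUserInterrupt();
    while (ti < times.size() && times[ti] == g) {
      e.purge();
      samples[ti] = e.sample_pops(n_sample);
      names[ti] = std::to_string(times[ti]);
      ++ti;
    }
  }
  samples.attr("names") = names;
  return List::create(_["samples"] = samples, _["migrants"] = migrants);
}
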