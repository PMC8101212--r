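// Multi-population continuous-time coalescent with demographic events, and
// generalised stepwise mutation (geometric step sizes, +/- 1 bp
// single-nucleotide indels) on the resulting genealogy. Uses R's RNG so that
// set.seed() governs all draws.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// events matrix columns: time, kind (1 merge, 2 admix, 3 size change),
// p1, p2, p3 (1-based pop indices, 0 if unused), x (rate or new size).
// Samples are taken at time 0.

// [[Rcpp::export]]
List cpp_sim_genealogy(IntegerVector sample_sizes, NumericVector pop_sizes,
                       NumericMatrix events) {
  const int npop = sample_sizes.size();
  std::vector<double> N(pop_sizes.begin(), pop_sizes.end());
  int n = 0;
  for (int p = 0; p < npop; ++p) n += sample_sizes[p];
  if (n < 1) stop("need at least one sampled gene copy");
  const int ntot = 2 * n - 1;
  IntegerVector parent(ntot, 0);      // 0 = no parent (root)
  NumericVector node_time(ntot, 0.0);
  IntegerVector leaf_pop(n);

  // active lineages per population (1-based node ids)
  std::vector< std::vector<int> > act(npop);
  int id = 0;
  for (int p = 0; p < npop; ++p)
    for (int i = 0; i < sample_sizes[p]; ++i) {
      act[p].push_back(id + 1);
      leaf_pop[id] = p + 1;
      ++id;
    }

  int next_node = n + 1;
  double t = 0.0;
  int ev = 0;
  const int nev = events.nrow();
  int alive = n;

  while (alive > 1) {
    double t_next = (ev < nev) ? events(ev, 0) : R_PosInf;
    // candidate coalescence: minimum of per-pop exponentials
    double best = R_PosInf;
    int best_p = -1;
    for (int p = 0; p < npop; ++p) {
      const int k = (int)act[p].size();
      if (k < 2) continue;
      double rate = (double)k * (k - 1) / (4.0 * N[p]);
      double dt = R::rexp(1.0 / rate);
      if (dt < best) { best = dt; best_p = p; }
    }
    if (t + best < t_next) {
      // coalesce a random pair in pop best_p
      t += best;
      std::vector<int>& v = act[best_p];
      int k = (int)v.size();
      int i = (int)(R::unif_rand() * k); if (i >= k) i = k - 1;
      int j = (int)(R::unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
      if (j >= i) ++j;
      int a = v[i], b = v[j];
      int u = next_node++;
      parent[a - 1] = u;
      parent[b - 1] = u;
      node_time[u - 1] = t;
      // remove higher index first
      if (i < j) std::swap(i, j);
      v.erase(v.begin() + i);
      v.erase(v.begin() + j);
      v.push_back(u);
      --alive;
    } else {
      if (ev >= nev) {
        // no coalescence possible and no events left
        bool multi = false; int with = -1;
        for (int p = 0; p < npop; ++p)
          if (!act[p].empty()) { if (with >= 0) multi = true; with = p; }
        if (multi) stop("lineages stranded in separate populations with no remaining events");
        continue;
      }
      t = t_next;
      int kind = (int)events(ev, 1);
      int p1 = (int)events(ev, 2) - 1;
      int p2 = (int)events(ev, 3) - 1;
      int p3 = (int)events(ev, 4) - 1;
      double x = events(ev, 5);
      if (kind == 1) {              // merge: p1 lineages join p2
        for (size_t i = 0; i < act[p1].size(); ++i) act[p2].push_back(act[p1][i]);
        act[p1].clear();
      } else if (kind == 2) {       // admixture: p1 -> p2 w.p. x else p3
        for (size_t i = 0; i < act[p1].size(); ++i) {
          if (R::unif_rand() < x) act[p2].push_back(act[p1][i]);
          else act[p3].push_back(act[p1][i]);
        }
        act[p1].clear();
      } else if (kind == 3) {       // size change
        N[p1] = x;
      } else stop("unknown event kind");
      ++ev;
    }
  }
  return List::create(_["parent"] = parent, _["time"] = node_time,
                      _["leaf_pop"] = leaf_pop, _["n_leaves"] = n);
}

static inline int reflect_state(int s, int n_states) {
  while (s < 0 || s > n_states - 1) {
    if (s < 0) s = -s;
    else s = 2 * (n_states - 1) - s;
  }
  return s;
}

// [[Rcpp::export]]
List cpp_mutate_gsm(IntegerVector parent, NumericVector node_time,
                    int n_leaves, double mu, double P, double mu_sni,
                    int n_states, int root_state) {
  const int ntot = parent.size();
  std::vector<int> state(ntot), offset(ntot, 0);
  state[ntot - 1] = root_state;           // root is the last-created node
  int n_mut = 0, n_sni = 0;
  for (int i = ntot - 2; i >= 0; --i) {
    int pa = parent[i] - 1;
    double len = node_time[pa] - node_time[i];
    int s = state[pa];
    int off = offset[pa];
    int nm = (int)R::rpois(mu * len);
    for (int m = 0; m < nm; ++m) {
      int step = 1 + (int)R::rgeom(1.0 - P);
      if (R::unif_rand() < 0.5) step = -step;
      s = reflect_state(s + step, n_states);
    }
    n_mut += nm;
    int ns = (int)R::rpois(mu_sni * len);
    for (int m = 0; m < ns; ++m) {
      off += (R::unif_rand() < 0.5) ? 1 : -1;
      if (off > 2) off = 2;
      if (off < -2) off = -2;
    }
    n_sni += ns;
    state[i] = s;
    offset[i] = off;
  }
  IntegerVector rep(n_leaves), offs(n_leaves);
  for (int i = 0; i < n_leaves; ++i) { rep[i] = state[i]; offs[i] = offset[i]; }
  return List::create(_["repeats"] = rep, _["offsets"] = offs,
                      _["n_mutations"] = n_mut, _["n_sni"] = n_sni);
}

// Simulate all loci of a dataset in one call: genealogy + GSM mutation per
// locus. Returns an n_copies x n_loci matrix of repeat states and a matching
// offsets matrix. Wrapping locus loops here avoids R call overhead in ABC
// reference-table construction.
// [[Rcpp::export]]
List cpp_sim_dataset(IntegerVector sample_sizes, NumericVector pop_sizes,
                     NumericMatrix events, NumericVector locus_rates,
                     double P, double mu_sni, int n_states) {
  int n = 0;
  for (int p = 0; p < sample_sizes.size(); ++p) n += sample_sizes[p];
  const int L = locus_rates.size();
  IntegerMatrix repeats(n, L), offsets(n, L);
  for (int j = 0; j < L; ++j) {
    List g = cpp_sim_genealogy(sample_sizes, pop_sizes, events);
    List m = cpp_mutate_gsm(g["parent"], g["time"], n, locus_rates[j], P,
                            mu_sni, n_states, n_states / 2);
    IntegerVector rep = m["repeats"], off = m["offsets"];
    for (int i = 0; i < n; ++i) { repeats(i, j) = rep[i]; offsets(i, j) = off[i]; }
  }
  return List::create(_["repeats"] = repeats, _["offsets"] = offsets);
}

// Draw one GSM step magnitude distribution sample set (test helper).
// [[Rcpp::export]]
IntegerVector cpp_gsm_steps(int n, double P) {
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = 1 + (int)R::rgeom(1.0 - P);
  return out;
}
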