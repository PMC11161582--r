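// Coalescent simulation of microsatellite loci under stepwise mutation
// models, used by the heterozygosity-excess bottleneck test. A genealogy of
// n gene copies is simulated under the standard neutral coalescent;
// mutations are Poisson(theta/2 * branch length) and change the allele
// state by +-1 step (SMM) or, with probability 1 - p_smm, by a +-geometric
// multi-step jump (TPM).

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

static inline int sample_step(double p_smm, double q_geom) {
  int mag = 1;
  if (p_smm < 1.0 && R::unif_rand() > p_smm)
    mag = 1 + (int) R::rgeom(q_geom);
  return (R::unif_rand() < 0.5) ? -mag : mag;
}

// one locus: fills tip allele states (length n). Population size is
// piecewise constant: relative size 1 more recently than t_change (time in
// units of 2N_present generations), anc_ratio beyond it (1/1/0 = constant).
static void sim_states_demo(int n, double theta, double p_smm,
                            double q_geom, double anc_ratio,
                            double t_change, std::vector<int> &tips) {
  int total = 2 * n - 1;
  std::vector<int> parent(total, -1);
  std::vector<double> blen(total, 0.0);
  std::vector<int> active(n);
  for (int i = 0; i < n; i++) active[i] = i;
  int next_node = n;
  int j = n;
  double t_now = 0.0;
  while (j > 1) {
    double size_now = (t_now < t_change) ? 1.0 : anc_ratio;
    double rate = j * (j - 1) / 2.0 / size_now;
    double t = R::exp_rand() / rate;
    if (t_now < t_change && t_now + t > t_change) {
      // epoch boundary: accumulate time up to it and redraw
      for (int a = 0; a < j; a++) blen[active[a]] += t_change - t_now;
      t_now = t_change;
      continue;
    }
    for (int a = 0; a < j; a++) blen[active[a]] += t;
    t_now += t;
    int i1 = (int)(R::unif_rand() * j);
    if (i1 >= j) i1 = j - 1;
    int i2 = (int)(R::unif_rand() * (j - 1));
    if (i2 >= j - 1) i2 = j - 2;
    if (i2 >= i1) i2++;
    int c1 = active[i1], c2 = active[i2];
    parent[c1] = next_node;
    parent[c2] = next_node;
    // replace the smaller index with the new node, drop the larger
    int lo = i1 < i2 ? i1 : i2, hi = i1 < i2 ? i2 : i1;
    active[lo] = next_node;
    active[hi] = active[j - 1];
    next_node++;
    j--;
  }
  // nodes are created children-first, so parent index > child index;
  // propagate states root-down by descending index
  std::vector<int> state(total, 0);
  for (int v = total - 2; v >= 0; v--) {
    int nm = (int) R::rpois(theta / 2.0 * blen[v]);
    int s = state[parent[v]];
    for (int m = 0; m < nm; m++) s += sample_step(p_smm, q_geom);
    state[v] = s;
  }
  tips.assign(state.begin(), state.begin() + n);
}

static void sim_states(int n, double theta, double p_smm, double q_geom,
                       std::vector<int> &tips) {
  sim_states_demo(n, theta, p_smm, q_geom, 1.0, 0.0, tips);
}

static void k_and_he(const std::vector<int> &tips, int *k, double *he) {
  std::unordered_map<int, int> cnt;
  for (size_t i = 0; i < tips.size(); i++) cnt[tips[i]]++;
  double n = (double) tips.size();
  double s2 = 0.0;
  for (std::unordered_map<int, int>::iterator it = cnt.begin();
       it != cnt.end(); ++it) {
    double p = it->second / n;
    s2 += p * p;
  }
  *k = (int) cnt.size();
  *he = n / (n - 1.0) * (1.0 - s2);  // unbiased gene diversity
}

// [[Rcpp::export]]
IntegerVector cpp_sim_locus(int n_genes, double theta, double p_smm,
                            double q_geom) {
  std::vector<int> tips;
  sim_states(n_genes, theta, p_smm, q_geom, tips);
  return wrap(tips);
}

// [[Rcpp::export]]
IntegerVector cpp_sim_locus_demo(int n_genes, double theta, double p_smm,
                                 double q_geom, double anc_ratio,
                                 double t_change) {
  std::vector<int> tips;
  sim_states_demo(n_genes, theta, p_smm, q_geom, anc_ratio, t_change, tips);
  return wrap(tips);
}

// [[Rcpp::export]]
double cpp_mean_k(int n_genes, double theta, double p_smm, double q_geom,
                  int n_reps) {
  std::vector<int> tips;
  double acc = 0.0;
  int k; double he;
  for (int r = 0; r < n_reps; r++) {
    sim_states(n_genes, theta, p_smm, q_geom, tips);
    k_and_he(tips, &k, &he);
    acc += k;
  }
  return acc / n_reps;
}

// Heq values of replicates retained conditional on k == k_obs. Each
// attempt draws theta log-uniformly in [theta_lo, theta_hi] (equal bounds =
// fixed theta), so the retained sample integrates the uncertainty of the
// mutation parameter given the observed allele count.
// [[Rcpp::export]]
NumericVector cpp_heq_conditional(int n_genes, int k_obs, double theta_lo,
                                  double theta_hi, double p_smm,
                                  double q_geom, int n_keep,
                                  int max_tries) {
  std::vector<double> kept;
  kept.reserve(n_keep);
  std::vector<int> tips;
  int k; double he;
  double llo = log(theta_lo), lhi = log(theta_hi);
  for (int t = 0; t < max_tries && (int) kept.size() < n_keep; t++) {
    double theta = (theta_lo == theta_hi)
      ? theta_lo : exp(llo + R::unif_rand() * (lhi - llo));
    sim_states(n_genes, theta, p_smm, q_geom, tips);
    k_and_he(tips, &k, &he);
    if (k == k_obs) kept.push_back(he);
  }
  return wrap(kept);
}
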