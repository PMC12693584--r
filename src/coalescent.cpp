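// Neutral two-epoch coalescent simulator used as an independent
// cross-validation oracle for the diffusion solver. Returns the mean total
// branch length subtending i leaves (i = 1..n-1), in units of 2*N_a
// generations; E[SFS_i] = (theta/2) * E[T_i].

#include <Rcpp.h>
#include <random>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export(name = ".coal_branch_lengths")]]
NumericVector coal_branch_lengths(int n, double nu, double T, int n_trees,
                                  int seed) {
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  NumericVector acc(n - 1);

  for (int tree = 0; tree < n_trees; ++tree) {
    std::vector<int> leaves(n, 1);  // subtended leaf count per lineage
    int k = n;
    double t = 0.0;
    while (k > 1) {
      // pairwise coalescence rate: 1/nu while t < T, 1 afterwards
      double rate_scale = (t < T) ? 1.0 / nu : 1.0;
      double total_rate = 0.5 * k * (k - 1) * rate_scale;
      double wait = -std::log(unif(rng)) / total_rate;
      double t_next = t + wait;
      if (t < T && t_next > T) {
        // epoch boundary crossed: credit branch length up to T, redraw in
        // the ancestral epoch using the memoryless property
        for (int j = 0; j < k; ++j) {
          int lv = leaves[j];
          if (lv >= 1 && lv <= n - 1) acc[lv - 1] += T - t;
        }
        t = T;
        continue;
      }
      for (int j = 0; j < k; ++j) {
        int lv = leaves[j];
        if (lv >= 1 && lv <= n - 1) acc[lv - 1] += wait;
      }
      t = t_next;
      // merge a uniform random pair
      int a = static_cast<int>(unif(rng) * k);
      int b = static_cast<int>(unif(rng) * (k - 1));
      if (b >= a) ++b;
      leaves[a] += leaves[b];
      leaves[b] = leaves[k - 1];
      --k;
      leaves.resize(k);
    }
  }
  for (int i = 0; i < n - 1; ++i) acc[i] /= n_trees;
  return acc;
}
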