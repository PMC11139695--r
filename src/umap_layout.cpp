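#include <Rcpp.h>
#include <random>
#include <cmath>

using namespace Rcpp;

static inline double clip4(double x) {
  if (x > 4.0) return 4.0;
  if (x < -4.0) return -4.0;
  return x;
}

// Stochastic-gradient layout of a fuzzy topological graph into 2D.
// Edges are sampled proportionally to membership strength via the
// epochs_per_sample schedule; repulsion uses negative sampling. The RNG is a
// private mt19937 seeded from R so the layout is bit-reproducible.
// [[Rcpp::export]]
NumericMatrix umap_layout_cpp(NumericMatrix init,
                              IntegerVector head, IntegerVector tail,
                              NumericVector epochs_per_sample,
                              double a, double b, double gamma,
                              double initial_alpha, int n_epochs,
                              double negative_sample_rate, int seed) {
  const int n = init.nrow();
  const int d = init.ncol();
  const int n_edges = head.size();
  NumericMatrix emb = clone(init);

  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::uniform_int_distribution<int> pick(0, n - 1);

  std::vector<double> epoch_next(n_edges), epoch_next_neg(n_edges),
      eps_neg(n_edges);
  for (int e = 0; e < n_edges; ++e) {
    epoch_next[e] = epochs_per_sample[e];
    eps_neg[e] = epochs_per_sample[e] / negative_sample_rate;
    epoch_next_neg[e] = eps_neg[e];
  }

  for (int epoch = 0; epoch < n_epochs; ++epoch) {
    double alpha = initial_alpha * (1.0 - (double)epoch / (double)n_epochs);
    for (int e = 0; e < n_edges; ++e) {
      if (epoch_next[e] > epoch) continue;
      int i = head[e], j = tail[e];
      double dist2 = 0.0;
      for (int c = 0; c < d; ++c) {
        double diff = emb(i, c) - emb(j, c);
        dist2 += diff * diff;
      }
      if (dist2 > 0.0) {
        double grad_coeff = (-2.0 * a * b * std::pow(dist2, b - 1.0)) /
                            (a * std::pow(dist2, b) + 1.0);
        for (int c = 0; c < d; ++c) {
          double g = clip4(grad_coeff * (emb(i, c) - emb(j, c)));
          emb(i, c) += g * alpha;
          emb(j, c) -= g * alpha;
        }
      }
      epoch_next[e] += epochs_per_sample[e];

      int n_neg = (int)((epoch - epoch_next_neg[e] + eps_neg[e]) / eps_neg[e]);
      for (int p = 0; p < n_neg; ++p) {
        int k = pick(rng);
        if (k == i) continue;
        double dist2n = 0.0;
        for (int c = 0; c < d; ++c) {
          double diff = emb(i, c) - emb(k, c);
          dist2n += diff * diff;
        }
        double grad_coeff;
        if (dist2n > 0.0) {
          grad_coeff = (2.0 * gamma * b) /
                       ((0.001 + dist2n) * (a * std::pow(dist2n, b) + 1.0));
        } else {
          grad_coeff = 0.0;
        }
        for (int c = 0; c < d; ++c) {
          double g = (grad_coeff > 0.0)
                         ? clip4(grad_coeff * (emb(i, c) - emb(k, c)))
                         : 4.0;
          emb(i, c) += g * alpha;
        }
      }
      epoch_next_neg[e] += n_neg * eps_neg[e];
    }
  }
  return emb;
}
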