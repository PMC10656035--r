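#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Discrete-time binomial-GLM spiking network.
//
// At every 1-ms bin t the membrane drive of neuron i is
//   x_i(t) = sum_l r(l) * M_i(t-l) + sum_j W_ij sum_l c(l) * M_j(t-l)
//            - b + common(t) + gain_i * stim(t)
// and a spike is drawn Bernoulli(sigma(x)).  r and c are the refractory
// and coupling kernels indexed by lag l >= 1 (bins since the spike).
// History before the first bin is silent.  Spike events are sparse, so
// the coupling term is accumulated per presynaptic spike using a
// column-compressed copy of W.
//
// [[Rcpp::export]]
List simulate_glm_cpp(int n_neurons, int n_steps,
                      NumericMatrix W,
                      NumericVector coup_kernel,
                      NumericVector refr_kernel,
                      NumericVector common_drive,
                      NumericVector stim_series,
                      NumericVector gains,
                      double bias) {
  const int Lc = coup_kernel.size();
  const int H = refr_kernel.size();
  const int ring = std::max(std::max(Lc, H), 1);

  // column-compressed W: for presynaptic j, rows with nonzero weight
  std::vector<std::vector<int> > col_idx(n_neurons);
  std::vector<std::vector<double> > col_val(n_neurons);
  for (int j = 0; j < n_neurons; ++j) {
    for (int i = 0; i < n_neurons; ++i) {
      double w = W(i, j);
      if (w != 0.0) {
        col_idx[j].push_back(i);
        col_val[j].push_back(w);
      }
    }
  }

  std::vector<std::vector<int> > ringbuf(ring);
  std::vector<std::vector<int> > out(n_neurons);
  std::vector<double> x(n_neurons);
  const bool has_common = common_drive.size() > 0;
  const bool has_stim = stim_series.size() > 0;

  for (int t = 0; t < n_steps; ++t) {
    // external input enters the conditional intensity with a one-bin
    // lag: U at bin t drives the spike probability of bin t+1
    const double cd = (has_common && t > 0) ? common_drive[t - 1] : 0.0;
    const double st = (has_stim && t > 0) ? stim_series[t - 1] : 0.0;
    for (int i = 0; i < n_neurons; ++i)
      x[i] = cd + (st != 0.0 ? st * gains[i] : 0.0) - bias;

    const int maxlag = t < ring ? t : ring;
    for (int l = 1; l <= maxlag; ++l) {
      const std::vector<int>& sp = ringbuf[(t - l) % ring];
      if (sp.empty()) continue;
      const double ck = (l <= Lc) ? coup_kernel[l - 1] : 0.0;
      const double rk = (l <= H) ? refr_kernel[l - 1] : 0.0;
      for (size_t s = 0; s < sp.size(); ++s) {
        const int j = sp[s];
        if (rk != 0.0) x[j] += rk;
        if (ck != 0.0 && !col_idx[j].empty()) {
          const std::vector<int>& ci = col_idx[j];
          const std::vector<double>& cv = col_val[j];
          for (size_t k = 0; k < ci.size(); ++k) x[ci[k]] += cv[k] * ck;
        }
      }
    }

    std::vector<int>& cur = ringbuf[t % ring];
    cur.clear();
    for (int i = 0; i < n_neurons; ++i) {
      const double p = 1.0 / (1.0 + std::exp(-x[i]));
      if (unif_rand() < p) {
        cur.push_back(i);
        out[i].push_back(t + 1);  // 1-based bin index
      }
    }
  }

  List res(n_neurons);
  for (int i = 0; i < n_neurons; ++i) res[i] = wrap(out[i]);
  return res;
}

// Pairwise lag counts between two sorted integer spike trains:
// counts[m + max_lag] = #{(s_pre, s_post) : s_post - s_pre = m}.
//
// [[Rcpp::export]]
IntegerVector lag_counts_cpp(IntegerVector pre, IntegerVector post, int max_lag) {
  IntegerVector counts(2 * max_lag + 1);
  const int np = post.size();
  int lo = 0;
  for (int a = 0; a < pre.size(); ++a) {
    const int tp = pre[a];
    while (lo < np && post[lo] < tp - max_lag) ++lo;
    for (int b = lo; b < np && post[b] <= tp + max_lag; ++b)
      counts[post[b] - tp + max_lag] += 1;
  }
  return counts;
}
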