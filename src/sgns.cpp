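// Skip-gram negative-sampling trainer.
//
// Mini-batch gradient ascent on the per-pair objective
//   L = log sigmoid(u_o . v_c) + sum_i log sigmoid(-u_{n_i} . v_c)
// with noise tokens drawn from the unigram distribution raised to 0.75.
// Single-threaded with an internal counter-free RNG so runs are bit-identical
// for a fixed seed.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// splitmix64: small, fast, full-period 64-bit generator
static inline uint64_t next_u64(uint64_t &state) {
  uint64_t z = (state += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

static inline double next_unif(uint64_t &state) {
  return (next_u64(state) >> 11) * (1.0 / 9007199254740992.0);
}

static inline double sigmoid(double x) {
  if (x > 30.0) return 1.0;
  if (x < -30.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Gradients of the per-pair objective w.r.t. v_c, u_o and each u_n, written
// into caller-provided buffers (gun is nneg*dim, row-major). Returns the
// objective value. This one routine is the arithmetic used both by the full
// trainer and by the exported single-pair helper, so tests of the helper
// cover the trainer's math.
static double pair_grad(const double *vc, const double *uo,
                        const std::vector<const double *> &un, int dim,
                        double *gvc, double *guo, double *gun) {
  double dot_o = 0.0;
  for (int d = 0; d < dim; ++d) dot_o += uo[d] * vc[d];
  double s = sigmoid(dot_o);
  double g = 1.0 - s; // d log sigmoid(x) / dx = 1 - sigmoid(x)
  double obj = std::log(std::max(sigmoid(dot_o), 1e-300));
  for (int d = 0; d < dim; ++d) {
    gvc[d] = g * uo[d];
    guo[d] = g * vc[d];
  }
  for (size_t i = 0; i < un.size(); ++i) {
    double dot_n = 0.0;
    for (int d = 0; d < dim; ++d) dot_n += un[i][d] * vc[d];
    double sn = sigmoid(dot_n);
    obj += std::log(std::max(sigmoid(-dot_n), 1e-300));
    double *g_i = gun + i * dim;
    for (int d = 0; d < dim; ++d) {
      g_i[d] = -sn * vc[d];
      gvc[d] -= sn * un[i][d];
    }
  }
  return obj;
}

// Cumulative table for the noise distribution (unigram^0.75)
static std::vector<double> noise_cdf(const NumericVector &counts) {
  std::vector<double> cdf(counts.size());
  double acc = 0.0;
  for (int i = 0; i < counts.size(); ++i) {
    acc += std::pow((double)counts[i], 0.75);
    cdf[i] = acc;
  }
  return cdf;
}

static inline int sample_noise(const std::vector<double> &cdf, uint64_t &state) {
  double u = next_unif(state) * cdf.back();
  int lo = 0, hi = (int)cdf.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cdf[mid] < u) lo = mid + 1; else hi = mid;
  }
  return lo;
}

// dense per-batch accumulation of parameter deltas: a full-width delta
// buffer plus the list of touched rows (cheap because V is modest and only
// touched rows are swept on apply)
struct DeltaBuf {
  std::vector<double> delta;
  std::vector<int> touched;
  std::vector<char> is_touched;
  int dim;
  DeltaBuf(int V, int d) : delta((size_t)V * d, 0.0), is_touched(V, 0), dim(d) {
    touched.reserve(256);
  }
  inline void add(int row, const double *g, double lr) {
    if (!is_touched[row]) {
      is_touched[row] = 1;
      touched.push_back(row);
    }
    double *d = &delta[(size_t)row * dim];
    for (int k = 0; k < dim; ++k) d[k] += lr * g[k];
  }
  void apply(std::vector<double> &params) {
    for (size_t i = 0; i < touched.size(); ++i) {
      int row = touched[i];
      double *d = &delta[(size_t)row * dim];
      double *p = &params[(size_t)row * dim];
      for (int k = 0; k < dim; ++k) {
        p[k] += d[k];
        d[k] = 0.0;
      }
      is_touched[row] = 0;
    }
    touched.clear();
  }
};

// [[Rcpp::export(name = ".sgns_train_cpp")]]
List sgns_train_cpp(List docs, NumericVector counts, int window, int dim,
                    int negatives, int batch_size, int epochs, double lr,
                    double subsample, bool dynamic_window, double seed) {
  const int V = counts.size();
  uint64_t rng = (uint64_t)seed * 0x9e3779b97f4a7c15ULL + 0x243f6a8885a308d3ULL;

  // init: input uniform in [-0.5/dim, 0.5/dim], output zero
  std::vector<double> in_vec((size_t)V * dim), out_vec((size_t)V * dim, 0.0);
  for (size_t i = 0; i < in_vec.size(); ++i)
    in_vec[i] = (next_unif(rng) - 0.5) / dim;

  std::vector<double> cdf = noise_cdf(counts);
  double total_count = 0.0;
  for (int i = 0; i < V; ++i) total_count += counts[i];

  // total pair budget for linear learning-rate decay (upper bound when the
  // dynamic window or subsampling discards some pairs)
  double total_pairs = 0.0;
  for (int d = 0; d < docs.size(); ++d) {
    int n = ((IntegerVector)docs[d]).size();
    for (int i = 0; i < n; ++i) {
      int lo = std::max(0, i - window), hi = std::min(n - 1, i + window);
      total_pairs += hi - lo; // excludes the center itself
    }
  }
  total_pairs *= epochs;
  if (total_pairs < 1.0) total_pairs = 1.0;

  std::vector<double> gvc(dim), guo(dim), gun((size_t)negatives * dim);
  std::vector<const double *> un(negatives);
  std::vector<int> neg_idx(negatives);
  DeltaBuf din(V, dim), dout(V, dim);
  NumericVector epoch_loss(epochs);

  double pairs_done = 0.0;
  for (int ep = 0; ep < epochs; ++ep) {
    double loss = 0.0;
    double npairs = 0.0;
    int in_batch = 0;
    for (int d = 0; d < docs.size(); ++d) {
      IntegerVector doc = docs[d];
      int n = doc.size();
      for (int i = 0; i < n; ++i) {
        int c = doc[i];
        if (subsample > 0.0) {
          double f = counts[c] / total_count;
          double keep = std::sqrt(subsample / f) + subsample / f;
          if (keep < 1.0 && next_unif(rng) > keep) continue;
        }
        int w = window;
        if (dynamic_window) w = 1 + (int)(next_unif(rng) * window);
        int lo = std::max(0, i - w), hi = std::min(n - 1, i + w);
        for (int j = lo; j <= hi; ++j) {
          if (j == i) continue;
          int o = doc[j];
          double alpha = lr * std::max(1.0 - pairs_done / total_pairs, 1e-4);
          pairs_done += 1.0;
          for (int s = 0; s < negatives; ++s) {
            int nidx = sample_noise(cdf, rng);
            for (int tries = 0; tries < 100 && nidx == o && V > 1; ++tries)
              nidx = sample_noise(cdf, rng);
            neg_idx[s] = nidx;
            un[s] = &out_vec[(size_t)nidx * dim];
          }
          double obj = pair_grad(&in_vec[(size_t)c * dim],
                                 &out_vec[(size_t)o * dim], un, dim,
                                 gvc.data(), guo.data(), gun.data());
          loss -= obj;
          npairs += 1.0;
          din.add(c, gvc.data(), alpha);
          dout.add(o, guo.data(), alpha);
          for (int s = 0; s < negatives; ++s)
            dout.add(neg_idx[s], gun.data() + (size_t)s * dim, alpha);
          if (++in_batch >= batch_size) {
            din.apply(in_vec);
            dout.apply(out_vec);
            in_batch = 0;
          }
        }
      }
    }
    din.apply(in_vec);
    dout.apply(out_vec);
    epoch_loss[ep] = npairs > 0 ? loss / npairs : 0.0;
  }

  NumericMatrix input(V, dim), output(V, dim);
  for (int i = 0; i < V; ++i)
    for (int k = 0; k < dim; ++k) {
      input(i, k) = in_vec[(size_t)i * dim + k];
      output(i, k) = out_vec[(size_t)i * dim + k];
    }
  return List::create(_["input"] = input, _["output"] = output,
                      _["epoch_loss"] = epoch_loss);
}

// Single-pair gradient exposed for oracle tests: returns the objective and
// the analytic gradients for (v_c, u_o, U_neg), computed by the same routine
// the trainer uses.
// [[Rcpp::export(name = ".sgns_pair_grad_cpp")]]
List sgns_pair_grad_cpp(NumericVector vc, NumericVector uo, NumericMatrix uneg) {
  int dim = vc.size();
  int nneg = uneg.nrow();
  std::vector<double> gvc(dim), guo(dim), gun((size_t)std::max(nneg, 1) * dim);
  std::vector<double> negflat((size_t)std::max(nneg, 1) * dim);
  std::vector<const double *> un(nneg);
  for (int i = 0; i < nneg; ++i) {
    for (int d = 0; d < dim; ++d) negflat[(size_t)i * dim + d] = uneg(i, d);
    un[i] = &negflat[(size_t)i * dim];
  }
  double obj = pair_grad(REAL(vc), REAL(uo), un, dim, gvc.data(), guo.data(),
                         gun.data());
  NumericMatrix grad_neg(nneg, dim);
  for (int i = 0; i < nneg; ++i)
    for (int d = 0; d < dim; ++d) grad_neg(i, d) = gun[(size_t)i * dim + d];
  return List::create(_["objective"] = obj,
                      _["grad_center"] = NumericVector(gvc.begin(), gvc.end()),
                      _["grad_context"] = NumericVector(guo.begin(), guo.end()),
                      _["grad_negatives"] = grad_neg);
}
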