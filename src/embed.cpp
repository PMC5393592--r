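// Seeded, single-threaded trainers for the prediction-based models:
// continuous bag-of-words with negative sampling, and a GloVe-style
// weighted least-squares factorization of log co-occurrence counts.
// Both use an internal xorshift64* RNG so that identical seeds give
// bitwise-identical vectors independently of R's RNG state.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 88172645463325252ULL) {}
  uint64_t next() {
    s ^= s << 13;
    s ^= s >> 7;
    s ^= s << 17;
    return s;
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, n)
  uint64_t below(uint64_t n) { return next() % n; }
};

inline double sigmoid_clamped(double x) {
  if (x > 6.0) return 1.0 - 1e-8;
  if (x < -6.0) return 1e-8;
  return 1.0 / (1.0 + std::exp(-x));
}

} // namespace

// [[Rcpp::export]]
NumericMatrix cpp_train_cbow(List docs, int vocab_size,
                             NumericVector counts, int dim, int window,
                             int epochs, int negative, double alpha,
                             int seed) {
  const int V = vocab_size;
  XorShift rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);

  std::vector<double> syn0(static_cast<size_t>(V) * dim);
  std::vector<double> syn1(static_cast<size_t>(V) * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  // cumulative table over counts^0.75 for negative sampling
  std::vector<double> cum(V);
  double acc = 0.0;
  for (int i = 0; i < V; ++i) {
    acc += std::pow(counts[i], 0.75);
    cum[i] = acc;
  }
  if (acc <= 0.0) stop("negative-sampling table is empty");

  auto sample_neg = [&](int avoid) {
    for (int tries = 0; tries < 16; ++tries) {
      double u = rng.unif() * acc;
      int lo = 0, hi = V - 1;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (cum[mid] < u) lo = mid + 1; else hi = mid;
      }
      if (lo != avoid) return lo;
    }
    return (avoid + 1) % V;
  };

  // total training positions, for linear learning-rate decay
  double total = 0.0;
  for (int d = 0; d < docs.size(); ++d)
    total += Rf_length(VECTOR_ELT(docs, d));
  total *= epochs;
  if (total <= 0.0) stop("empty corpus");

  std::vector<double> hidden(dim), grad(dim);
  double processed = 0.0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int d = 0; d < docs.size(); ++d) {
      IntegerVector doc = docs[d];
      const int n = doc.size();
      for (int t = 0; t < n; ++t) {
        processed += 1.0;
        const int w = doc[t] - 1; // 1-based ids from R
        if (w < 0) continue;
        double lr = alpha * (1.0 - processed / (total + 1.0));
        if (lr < alpha * 1e-4) lr = alpha * 1e-4;

        int lo = t - window < 0 ? 0 : t - window;
        int hi = t + window >= n ? n - 1 : t + window;
        int cn = 0;
        std::fill(hidden.begin(), hidden.end(), 0.0);
        for (int c = lo; c <= hi; ++c) {
          if (c == t || doc[c] <= 0) continue;
          const double* v = &syn0[static_cast<size_t>(doc[c] - 1) * dim];
          for (int k = 0; k < dim; ++k) hidden[k] += v[k];
          ++cn;
        }
        if (cn == 0) continue;
        const double inv = 1.0 / cn;
        for (int k = 0; k < dim; ++k) hidden[k] *= inv;

        std::fill(grad.begin(), grad.end(), 0.0);
        for (int s = 0; s <= negative; ++s) {
          int target;
          double label;
          if (s == 0) { target = w; label = 1.0; }
          else { target = sample_neg(w); label = 0.0; }
          double* out = &syn1[static_cast<size_t>(target) * dim];
          double dot = 0.0;
          for (int k = 0; k < dim; ++k) dot += hidden[k] * out[k];
          const double g = (label - sigmoid_clamped(dot)) * lr;
          for (int k = 0; k < dim; ++k) {
            grad[k] += g * out[k];
            out[k] += g * hidden[k];
          }
        }
        for (int c = lo; c <= hi; ++c) {
          if (c == t || doc[c] <= 0) continue;
          double* v = &syn0[static_cast<size_t>(doc[c] - 1) * dim];
          for (int k = 0; k < dim; ++k) v[k] += grad[k];
        }
      }
    }
  }

  NumericMatrix out(V, dim);
  for (int i = 0; i < V; ++i)
    for (int k = 0; k < dim; ++k)
      out(i, k) = syn0[static_cast<size_t>(i) * dim + k];
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_train_glove(IntegerVector ia, IntegerVector ja,
                              NumericVector xv, int vocab_size, int dim,
                              int epochs, double x_max, double alpha,
                              double eta, int seed) {
  const int V = vocab_size;
  const R_xlen_t nnz = ia.size();
  if (nnz == 0) stop("empty co-occurrence input");
  XorShift rng(static_cast<uint64_t>(seed) * 6364136223846793005ULL + 3ULL);

  std::vector<double> W(static_cast<size_t>(V) * dim);
  std::vector<double> C(static_cast<size_t>(V) * dim);
  std::vector<double> bW(V, 0.0), bC(V, 0.0);
  for (size_t i = 0; i < W.size(); ++i) W[i] = (rng.unif() - 0.5) / dim;
  for (size_t i = 0; i < C.size(); ++i) C[i] = (rng.unif() - 0.5) / dim;
  std::vector<double> gW(static_cast<size_t>(V) * dim, 1.0);
  std::vector<double> gC(static_cast<size_t>(V) * dim, 1.0);
  std::vector<double> gbW(V, 1.0), gbC(V, 1.0);

  std::vector<R_xlen_t> order(nnz);
  for (R_xlen_t i = 0; i < nnz; ++i) order[i] = i;

  std::vector<double> logx(nnz), fwt(nnz);
  for (R_xlen_t i = 0; i < nnz; ++i) {
    logx[i] = std::log(xv[i]);
    fwt[i] = xv[i] < x_max ? std::pow(xv[i] / x_max, alpha) : 1.0;
  }

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle with the internal RNG
    for (R_xlen_t i = nnz - 1; i > 0; --i) {
      R_xlen_t j = static_cast<R_xlen_t>(rng.below(static_cast<uint64_t>(i + 1)));
      std::swap(order[i], order[j]);
    }
    for (R_xlen_t q = 0; q < nnz; ++q) {
      const R_xlen_t p = order[q];
      const int i = ia[p] - 1, j = ja[p] - 1;
      double* wi = &W[static_cast<size_t>(i) * dim];
      double* cj = &C[static_cast<size_t>(j) * dim];
      double diff = bW[i] + bC[j] - logx[p];
      for (int k = 0; k < dim; ++k) diff += wi[k] * cj[k];
      double fd = fwt[p] * diff;
      if (fd > 100.0) fd = 100.0; else if (fd < -100.0) fd = -100.0;
      double* gwi = &gW[static_cast<size_t>(i) * dim];
      double* gcj = &gC[static_cast<size_t>(j) * dim];
      for (int k = 0; k < dim; ++k) {
        const double tw = fd * cj[k];
        const double tc = fd * wi[k];
        wi[k] -= eta * tw / std::sqrt(gwi[k]);
        cj[k] -= eta * tc / std::sqrt(gcj[k]);
        gwi[k] += tw * tw;
        gcj[k] += tc * tc;
      }
      bW[i] -= eta * fd / std::sqrt(gbW[i]);
      bC[j] -= eta * fd / std::sqrt(gbC[j]);
      gbW[i] += fd * fd;
      gbC[j] += fd * fd;
    }
  }

  NumericMatrix out(V, dim);
  for (int i = 0; i < V; ++i)
    for (int k = 0; k < dim; ++k)
      out(i, k) = W[static_cast<size_t>(i) * dim + k] +
                  C[static_cast<size_t>(i) * dim + k];
  return out;
}
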