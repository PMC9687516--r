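#include <Rcpp.h>
using namespace Rcpp;

// All kernels take windows as a K x P matrix (one window per column, so the
// inner distance loop walks contiguous memory).

// Number of unordered window pairs (i < j) whose Chebyshev distance is <= r.
// [[Rcpp::export]]
double chebyshev_pairs_within(const NumericMatrix& W, double r) {
  const int K = W.nrow(), P = W.ncol();
  const double* w = REAL(W);
  double cnt = 0.0;
  for (int i = 0; i < P; ++i) {
    const double* wi = w + (size_t)i * K;
    for (int j = i + 1; j < P; ++j) {
      const double* wj = w + (size_t)j * K;
      bool ok = true;
      for (int k = 0; k < K; ++k) {
        double d = wi[k] - wj[k];
        if (d < 0) d = -d;
        if (d > r) { ok = false; break; }
      }
      if (ok) cnt += 1.0;
    }
  }
  return cnt;
}

// Mean exponential similarity exp(-d^nf / r) over unordered window pairs,
// d being the Chebyshev distance. Equals the mean over ordered pairs.
// [[Rcpp::export]]
double fuzzy_similarity_mean(const NumericMatrix& W, double r, double nf) {
  const int K = W.nrow(), P = W.ncol();
  const double* w = REAL(W);
  const bool nf1 = (nf == 1.0), nf2 = (nf == 2.0);
  double acc = 0.0, npairs = 0.0;
  for (int i = 0; i < P; ++i) {
    const double* wi = w + (size_t)i * K;
    for (int j = i + 1; j < P; ++j) {
      const double* wj = w + (size_t)j * K;
      double dmax = 0.0;
      for (int k = 0; k < K; ++k) {
        double d = wi[k] - wj[k];
        if (d < 0) d = -d;
        if (d > dmax) dmax = d;
      }
      double dn = nf2 ? dmax * dmax : (nf1 ? dmax : std::pow(dmax, nf));
      acc += std::exp(-dn / r);
      npairs += 1.0;
    }
  }
  return npairs > 0 ? acc / npairs : NA_REAL;
}

// Histogram of pairwise Chebyshev distances over unordered pairs, binned into
// M equal-width bins spanning [0, max distance]. Distances are computed once
// and buffered, then binned after the maximum is known.
// Returns counts (length M) and the maximum distance.
// [[Rcpp::export]]
List chebyshev_distance_hist(const NumericMatrix& W, int M) {
  const int K = W.nrow(), P = W.ncol();
  const double* w = REAL(W);
  const size_t npairs = (size_t)P * (P - 1) / 2;
  std::vector<double> dist;
  dist.reserve(npairs);
  double dmax_all = 0.0;
  for (int i = 0; i < P; ++i) {
    const double* wi = w + (size_t)i * K;
    for (int j = i + 1; j < P; ++j) {
      const double* wj = w + (size_t)j * K;
      double dmax = 0.0;
      for (int k = 0; k < K; ++k) {
        double d = wi[k] - wj[k];
        if (d < 0) d = -d;
        if (d > dmax) dmax = d;
      }
      dist.push_back(dmax);
      if (dmax > dmax_all) dmax_all = dmax;
    }
  }
  NumericVector counts(M);
  if (dmax_all > 0) {
    const double scale = (double)M / dmax_all;
    for (size_t p = 0; p < dist.size(); ++p) {
      int b = (int)(dist[p] * scale);
      if (b >= M) b = M - 1;
      counts[b] += 1.0;
    }
  } else if (npairs > 0) {
    counts[0] = (double)npairs;
  }
  return List::create(_["counts"] = counts, _["dmax"] = dmax_all,
                      _["n_pairs"] = (double)npairs);
}
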