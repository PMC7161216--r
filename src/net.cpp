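// Residual convolutional policy network: fused forward / backward passes
// plus a batched pointing decoder.
//
// Feature maps for a batch of B square N x N single-channel inputs are held
// as arma::mat of shape (N*N*B, C): rows run column-major over the spatial
// grid within a sample, then sample-major over the batch; columns are
// channels.  Convolutions are 3x3 (or any odd k) with zero padding of width
// (k-1)/2 implemented by im2col + GEMM.  Batch normalization is the plain
// centering/scaling transform (no learned affine), with per-channel
// statistics taken over batch x spatial elements.
//
// The backward pass needs large intermediates (the im2col matrices); they
// are kept on the C++ side behind an external pointer and freed by the
// backward pass, so nothing big is ever copied into R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct NetCache {
  arma::mat col0, Z1, colL, Yflat;
  std::vector<arma::mat> cols, Zn;
  std::vector<arma::rowvec> sd;
  int N = 0, B = 0, k = 3;
  bool valid = false;
  void release() {
    col0.reset(); Z1.reset(); colL.reset(); Yflat.reset();
    cols.clear(); Zn.clear(); sd.clear();
    valid = false;
  }
};

// Zero the entries of a flattened (N x N spatial, B samples) column whose
// source pixel for kernel offset (dr, dc) falls outside the zero-padded
// image: grid rows with r + dr outside [0, N) and grid columns with c + dc
// outside [0, N).  Sample-boundary crossings of the linear shift are grid-
// column overflows, so they are covered by the dc masking.
static void mask_edges(double* x, int N, int B, int dr, int dc) {
  const arma::uword NN = (arma::uword)N * N;
  const arma::uword total = NN * B;
  if (dr > 0) {
    for (arma::uword base = N - dr; base < total; base += N)
      std::memset(x + base, 0, (size_t)dr * sizeof(double));
  } else if (dr < 0) {
    for (arma::uword base = 0; base < total; base += N)
      std::memset(x + base, 0, (size_t)(-dr) * sizeof(double));
  }
  if (dc > 0) {
    for (int b = 0; b < B; ++b)
      std::memset(x + (arma::uword)b * NN + (arma::uword)(N - dc) * N, 0,
                  (size_t)dc * N * sizeof(double));
  } else if (dc < 0) {
    for (int b = 0; b < B; ++b)
      std::memset(x + (arma::uword)b * NN, 0,
                  (size_t)(-dc) * N * sizeof(double));
  }
}

// gather: out(:, kk*C + c) = channel c shifted by kernel offset kk.
// Implemented as one linear shifted copy per (offset, channel) followed by
// edge masking, instead of per-pixel-column copies.
static arma::mat im2col_sq(const arma::mat& in, int N, int B, int k) {
  const int C = in.n_cols;
  const int half = (k - 1) / 2;
  const arma::uword NN = (arma::uword)N * N;
  const arma::uword total = NN * B;
  arma::mat out(total, (arma::uword)k * k * C);
  for (int kk = 0; kk < k * k; ++kk) {
    const int dr = kk / k - half;
    const int dc = kk % k - half;
    const long s = dr + (long)dc * N;
    for (int ch = 0; ch < C; ++ch) {
      const double* src = in.colptr(ch);
      double* dst = out.colptr((arma::uword)kk * C + ch);
      const long lo = s > 0 ? 0 : -s;
      const long hi = s > 0 ? (long)total - s : (long)total;
      if (hi <= lo) {
        std::memset(dst, 0, (size_t)total * sizeof(double));
        continue;
      }
      if (lo > 0) std::memset(dst, 0, (size_t)lo * sizeof(double));
      if (hi < (long)total)
        std::memset(dst + hi, 0, (size_t)((long)total - hi) * sizeof(double));
      std::memcpy(dst + lo, src + lo + s, (size_t)(hi - lo) * sizeof(double));
      mask_edges(dst, N, B, dr, dc);
    }
  }
  return out;
}

// scatter-accumulate transpose of im2col: din[p + s] += masked dcol_k[p]
static arma::mat col2im_sq(const arma::mat& dcol, int N, int B, int C, int k) {
  const int half = (k - 1) / 2;
  const arma::uword NN = (arma::uword)N * N;
  const arma::uword total = NN * B;
  arma::mat din(total, C, arma::fill::zeros);
  std::vector<double> tmp(total);
  for (int kk = 0; kk < k * k; ++kk) {
    const int dr = kk / k - half;
    const int dc = kk % k - half;
    const long s = dr + (long)dc * N;
    for (int ch = 0; ch < C; ++ch) {
      const long lo = s > 0 ? 0 : -s;
      const long hi = s > 0 ? (long)total - s : (long)total;
      if (hi <= lo) continue;
      const double* src = dcol.colptr((arma::uword)kk * C + ch);
      std::memcpy(tmp.data(), src, (size_t)total * sizeof(double));
      mask_edges(tmp.data(), N, B, dr, dc);
      double* dst = din.colptr(ch);
      const double* t = tmp.data();
      for (long p = lo; p < hi; ++p) dst[p + s] += t[p];
    }
  }
  return din;
}

// Forward pass; X is (N*N, B), one column per sample, already normalized.
// with_cache = true keeps intermediates for net_backward_cpp.
// [[Rcpp::export(name = ".net_forward_cpp")]]
List net_forward_cpp(const arma::mat& X, int N, int B,
                     const arma::mat& W1, const arma::vec& b1,
                     const List& Wmid,
                     const arma::mat& Wlast, double blast,
                     const List& bn_mean, const List& bn_var,
                     bool training, double eps, int k, bool with_cache) {
  const arma::uword NN = (arma::uword)N * N;
  arma::mat Xs(const_cast<double*>(X.memptr()), NN * B, 1, false, true);

  NetCache* cache = with_cache ? new NetCache() : nullptr;

  arma::mat col0 = im2col_sq(Xs, N, B, k);
  arma::mat Z1 = col0 * W1;
  Z1.each_row() += b1.t();
  arma::mat A = Z1;
  A.elem(arma::find(A < 0)).zeros();
  if (cache) { cache->col0 = std::move(col0); cache->Z1 = Z1; }

  const int nb = Wmid.size();
  List bm_list(nb), bv_list(nb);
  for (int l = 0; l < nb; ++l) {
    arma::mat cl = im2col_sq(A, N, B, k);
    arma::mat Wl = Wmid[l];
    arma::mat Z = cl * Wl;
    arma::rowvec m, v;
    if (training) {
      m = arma::mean(Z, 0);
      v = arma::var(Z, 1, 0);  // population variance
    } else {
      m = as<arma::rowvec>(bn_mean[l]);
      v = as<arma::rowvec>(bn_var[l]);
    }
    arma::rowvec sd = arma::sqrt(v + eps);
    arma::mat Zn = Z.each_row() - m;
    Zn.each_row() /= sd;
    bm_list[l] = NumericVector(m.begin(), m.end());
    bv_list[l] = NumericVector(v.begin(), v.end());
    A = Zn;
    A.elem(arma::find(A < 0)).zeros();
    if (cache) {
      cache->cols.push_back(std::move(cl));
      cache->Zn.push_back(std::move(Zn));
      cache->sd.push_back(sd);
    }
  }

  arma::mat colL = im2col_sq(A, N, B, k);
  arma::mat r = colL * Wlast + blast;
  arma::mat Ypre = Xs - r;
  arma::mat Y = arma::tanh(Ypre);

  SEXP cache_sexp = R_NilValue;
  if (cache) {
    cache->colL = std::move(colL);
    cache->Yflat = Y;
    cache->N = N; cache->B = B; cache->k = k;
    cache->valid = true;
    cache_sexp = XPtr<NetCache>(cache, true);
  }
  return List::create(
    _["Y"] = arma::mat(Y.memptr(), NN, B),
    _["cache"] = cache_sexp,
    _["batch_mean"] = bm_list, _["batch_var"] = bv_list);
}

// Backward pass for a training-mode cache (the BN backward includes the
// dependence of the batch statistics on the input).  Consumes the cache.
// [[Rcpp::export(name = ".net_backward_cpp")]]
List net_backward_cpp(SEXP cache_sexp, const arma::mat& dY,
                      const arma::mat& W1, const List& Wmid,
                      const arma::mat& Wlast) {
  XPtr<NetCache> cache(cache_sexp);
  if (!cache->valid) stop("net_backward: cache already consumed");
  const int N = cache->N, B = cache->B, k = cache->k;
  const arma::uword NN = (arma::uword)N * N;
  const int nb = Wmid.size();
  const int F = W1.n_cols;

  arma::mat dYf(const_cast<double*>(dY.memptr()), NN * B, 1, false, true);
  arma::mat dpre = dYf % (1.0 - arma::square(cache->Yflat));  // tanh'
  arma::mat dr = -dpre;

  arma::mat dWlast = cache->colL.t() * dr;
  double dblast = arma::accu(dr);
  arma::mat dA = col2im_sq(dr * Wlast.t(), N, B, F, k);

  List dWmid(nb);
  for (int l = nb - 1; l >= 0; --l) {
    const arma::mat& Zn = cache->Zn[l];
    const arma::rowvec& sd = cache->sd[l];
    arma::mat dZn = dA;                                      // ReLU'
    dZn.elem(arma::find(Zn <= 0)).zeros();
    // BN backward (no affine): dZ = (dZn - mean(dZn) - Zn*mean(dZn%Zn))/sd
    arma::rowvec mu_d = arma::mean(dZn, 0);
    arma::rowvec mu_dz = arma::mean(dZn % Zn, 0);
    arma::mat dZ = dZn.each_row() - mu_d;
    arma::mat zterm = Zn;
    zterm.each_row() %= mu_dz;
    dZ -= zterm;
    dZ.each_row() /= sd;
    const arma::mat& Wl_c = cache->cols[l];
    const arma::mat& Wl = Wmid[l];
    dWmid[l] = Wl_c.t() * dZ;
    dA = col2im_sq(dZ * Wl.t(), N, B, F, k);
  }

  arma::mat dZ1 = dA;
  dZ1.elem(arma::find(cache->Z1 <= 0)).zeros();
  arma::mat dW1 = cache->col0.t() * dZ1;
  arma::rowvec db1 = arma::sum(dZ1, 0);
  cache->release();

  return List::create(_["W1"] = dW1, _["b1"] = db1.t(),
                      _["Wmid"] = dWmid,
                      _["Wlast"] = dWlast, _["blast"] = dblast);
}

// Batched sequential pointing decoder.  Y is (N*N, B); rows of each sample
// are processed in ascending order, claimed columns are masked, remaining
// logits (divided by the temperature) are softmax-normalized, and a column
// is chosen by argmax (greedy) or sampled via R's RNG.  Returns 1-based
// permutations (N x B) and per-sample log-probabilities.
// [[Rcpp::export(name = ".decode_batch_cpp")]]
List decode_batch_cpp(const arma::mat& Y, int N, int B, double temperature,
                      bool greedy) {
  IntegerMatrix perms(N, B);
  NumericVector logps(B);
  std::vector<int> idx;
  std::vector<double> w;
  for (int b = 0; b < B; ++b) {
    const double* y = Y.colptr(b);
    std::vector<bool> avail(N, true);
    double logp = 0.0;
    for (int i = 0; i < N; ++i) {
      idx.clear();
      for (int j = 0; j < N; ++j) if (avail[j]) idx.push_back(j);
      const int m = (int)idx.size();
      double mx = -std::numeric_limits<double>::infinity();
      for (int t = 0; t < m; ++t) {
        mx = std::max(mx, y[(arma::uword)idx[t] * N + i] / temperature);
      }
      w.assign(m, 0.0);
      double Zs = 0.0;
      for (int t = 0; t < m; ++t) {
        w[t] = std::exp(y[(arma::uword)idx[t] * N + i] / temperature - mx);
        Zs += w[t];
      }
      int pick = 0;
      if (greedy) {
        for (int t = 1; t < m; ++t) if (w[t] > w[pick]) pick = t;
      } else {
        double u = unif_rand() * Zs;
        double acc = 0.0;
        pick = m - 1;
        for (int t = 0; t < m; ++t) {
          acc += w[t];
          if (u <= acc) { pick = t; break; }
        }
      }
      logp += std::log(w[pick] / Zs);
      perms(i, b) = idx[pick] + 1;
      avail[idx[pick]] = false;
    }
    logps[b] = logp;
  }
  return List::create(_["permutations"] = perms, _["log_probabilities"] = logps);
}

// Gradient of sum_b coef[b] * log p(pi_b | Y_b) with respect to Y.
// [[Rcpp::export(name = ".dlogp_batch_cpp")]]
arma::mat dlogp_batch_cpp(const arma::mat& Y, const IntegerMatrix& perms,
                          const arma::vec& coef, int N, int B,
                          double temperature) {
  arma::mat dY((arma::uword)N * N, B, arma::fill::zeros);
  std::vector<int> idx;
  std::vector<double> w;
  for (int b = 0; b < B; ++b) {
    if (coef[b] == 0.0) continue;
    const double* y = Y.colptr(b);
    double* g = dY.colptr(b);
    std::vector<bool> avail(N, true);
    for (int i = 0; i < N; ++i) {
      idx.clear();
      for (int j = 0; j < N; ++j) if (avail[j]) idx.push_back(j);
      const int m = (int)idx.size();
      double mx = -std::numeric_limits<double>::infinity();
      for (int t = 0; t < m; ++t) {
        mx = std::max(mx, y[(arma::uword)idx[t] * N + i] / temperature);
      }
      w.assign(m, 0.0);
      double Zs = 0.0;
      for (int t = 0; t < m; ++t) {
        w[t] = std::exp(y[(arma::uword)idx[t] * N + i] / temperature - mx);
        Zs += w[t];
      }
      const int chosen = perms(i, b) - 1;
      for (int t = 0; t < m; ++t) {
        const double p = w[t] / Zs;
        const double ind = (idx[t] == chosen) ? 1.0 : 0.0;
        g[(arma::uword)idx[t] * N + i] = coef[b] * (ind - p) / temperature;
      }
      avail[chosen] = false;
    }
  }
  return dY;
}
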