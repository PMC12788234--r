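// Native kernels for the sEMG encoder/decoder stack.
//
// Conventions: batched tensors arrive as flat NumericVectors in column-major
// order with the TIME axis fastest, i.e. dim = (T, K, C, B) for the band-wise
// convolution stages (K = frequency bands, C = muscle channels, B = batch) and
// dim = (L, D, S) for attention token blocks (S = flattened sequence count).
// All kernels are single-threaded; heavy linear algebra goes through BLAS via
// Armadillo.

#include <RcppArmadillo.h>
#include <map>
#include <vector>
#include <cmath>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Radix-2 FFT with cached plans (power-of-two lengths only)
// ---------------------------------------------------------------------------

struct FFTPlan {
  int n;
  std::vector<int> rev;
  std::vector<double> wr, wi; // forward twiddles e^{-2*pi*i*k/n}
};

static FFTPlan &fft_plan(int n) {
  static std::map<int, FFTPlan> plans;
  auto it = plans.find(n);
  if (it != plans.end()) return it->second;
  FFTPlan p;
  p.n = n;
  p.rev.assign(n, 0);
  int lg = 0;
  while ((1 << lg) < n) ++lg;
  for (int i = 0; i < n; ++i) {
    int r = 0;
    for (int b = 0; b < lg; ++b)
      if (i & (1 << b)) r |= 1 << (lg - 1 - b);
    p.rev[i] = r;
  }
  p.wr.assign(n, 0.0);
  p.wi.assign(n, 0.0);
  for (int k = 0; k < n; ++k) {
    p.wr[k] = std::cos(-2.0 * M_PI * k / n);
    p.wi[k] = std::sin(-2.0 * M_PI * k / n);
  }
  plans[n] = std::move(p);
  return plans[n];
}

static void fft_inplace(double *re, double *im, const FFTPlan &p, bool inverse) {
  const int n = p.n;
  for (int i = 0; i < n; ++i) {
    int j = p.rev[i];
    if (j > i) {
      std::swap(re[i], re[j]);
      std::swap(im[i], im[j]);
    }
  }
  for (int len = 2; len <= n; len <<= 1) {
    const int half = len >> 1;
    const int step = n / len;
    for (int i = 0; i < n; i += len) {
      for (int k = 0; k < half; ++k) {
        const int tw = k * step;
        const double twr = p.wr[tw];
        const double twi = inverse ? -p.wi[tw] : p.wi[tw];
        const double xr = re[i + k + half], xi = im[i + k + half];
        const double vr = xr * twr - xi * twi;
        const double vi = xr * twi + xi * twr;
        const double ur = re[i + k], ui = im[i + k];
        re[i + k] = ur + vr;
        im[i + k] = ui + vi;
        re[i + k + half] = ur - vr;
        im[i + k + half] = ui - vi;
      }
    }
  }
  if (inverse) {
    const double s = 1.0 / n;
    for (int i = 0; i < n; ++i) {
      re[i] *= s;
      im[i] *= s;
    }
  }
}

// Continuous wavelet magnitudes for a batch of windows.
// x: (nt, ncol) real windows, one column per (channel, window) pair.
// wspec: (nfft, nscales) real wavelet spectra already including the sqrt(scale)
// L2 factor. Returns (nt, nscales, ncol).
// [[Rcpp::export]]
NumericVector cpp_cwt_batch(NumericMatrix x, NumericMatrix wspec) {
  const int nt = x.nrow(), ncol = x.ncol();
  const int nfft = wspec.nrow(), nsc = wspec.ncol();
  const FFTPlan &plan = fft_plan(nfft);
  NumericVector out((R_xlen_t)nt * nsc * ncol);
  out.attr("dim") = IntegerVector::create(nt, nsc, ncol);
  std::vector<double> re(nfft), im(nfft), yr(nfft), yi(nfft);
  double *op = REAL(out);
  for (int c = 0; c < ncol; ++c) {
    std::fill(re.begin(), re.end(), 0.0);
    std::fill(im.begin(), im.end(), 0.0);
    for (int t = 0; t < nt; ++t) re[t] = x(t, c);
    fft_inplace(re.data(), im.data(), plan, false);
    for (int s = 0; s < nsc; ++s) {
      const double *w = &wspec(0, s);
      for (int k = 0; k < nfft; ++k) {
        yr[k] = re[k] * w[k];
        yi[k] = im[k] * w[k];
      }
      fft_inplace(yr.data(), yi.data(), plan, true);
      double *dst = op + ((R_xlen_t)c * nsc + s) * nt;
      for (int t = 0; t < nt; ++t)
        dst[t] = std::sqrt(yr[t] * yr[t] + yi[t] * yi[t]);
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Band-wise temporal convolution (kernel 3, one filter per band)
// ---------------------------------------------------------------------------

// x: (T, K, C, B); w: (3, K); b: K. Returns (T-2, K, C, B).
// [[Rcpp::export]]
NumericVector cpp_band_conv_fwd(NumericVector x, NumericMatrix w,
                                NumericVector b, int T, int K, int C, int B) {
  const int To = T - 2;
  NumericVector y((R_xlen_t)To * K * C * B);
  y.attr("dim") = IntegerVector::create(To, K, C, B);
  const double *xp = REAL(x);
  double *yp = REAL(y);
  for (int n = 0; n < B; ++n)
    for (int c = 0; c < C; ++c)
      for (int k = 0; k < K; ++k) {
        const double w0 = w(0, k), w1 = w(1, k), w2 = w(2, k), bk = b[k];
        const double *xs = xp + (R_xlen_t)T * (k + (R_xlen_t)K * (c + (R_xlen_t)C * n));
        double *ys = yp + (R_xlen_t)To * (k + (R_xlen_t)K * (c + (R_xlen_t)C * n));
        for (int t = 0; t < To; ++t)
          ys[t] = w0 * xs[t] + w1 * xs[t + 1] + w2 * xs[t + 2] + bk;
      }
  return y;
}

// [[Rcpp::export]]
List cpp_band_conv_bwd(NumericVector x, NumericMatrix w, NumericVector dy,
                       int T, int K, int C, int B) {
  const int To = T - 2;
  NumericVector dx((R_xlen_t)T * K * C * B);
  dx.attr("dim") = IntegerVector::create(T, K, C, B);
  NumericMatrix dw(3, K);
  NumericVector db(K);
  const double *xp = REAL(x), *dyp = REAL(dy);
  double *dxp = REAL(dx);
  for (int n = 0; n < B; ++n)
    for (int c = 0; c < C; ++c)
      for (int k = 0; k < K; ++k) {
        const double w0 = w(0, k), w1 = w(1, k), w2 = w(2, k);
        const double *xs = xp + (R_xlen_t)T * (k + (R_xlen_t)K * (c + (R_xlen_t)C * n));
        const double *ds = dyp + (R_xlen_t)To * (k + (R_xlen_t)K * (c + (R_xlen_t)C * n));
        double *gs = dxp + (R_xlen_t)T * (k + (R_xlen_t)K * (c + (R_xlen_t)C * n));
        double s0 = 0, s1 = 0, s2 = 0, sb = 0;
        for (int t = 0; t < To; ++t) {
          const double d = ds[t];
          gs[t] += w0 * d;
          gs[t + 1] += w1 * d;
          gs[t + 2] += w2 * d;
          s0 += xs[t] * d;
          s1 += xs[t + 1] * d;
          s2 += xs[t + 2] * d;
          sb += d;
        }
        dw(0, k) += s0;
        dw(1, k) += s1;
        dw(2, k) += s2;
        db[k] += sb;
      }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// ---------------------------------------------------------------------------
// Pooling along the leading (time) axis, remaining axes collapsed
// ---------------------------------------------------------------------------

static inline int pool_out_len(int T, int size, int stride) {
  return (T - size) / stride + 1;
}

// [[Rcpp::export]]
List cpp_pool_max_fwd(NumericVector x, int T, int size, int stride) {
  const R_xlen_t M = x.size() / T;
  const int To = pool_out_len(T, size, stride);
  NumericVector y((R_xlen_t)To * M);
  IntegerVector idx((R_xlen_t)To * M);
  const double *xp = REAL(x);
  double *yp = REAL(y);
  int *ip = INTEGER(idx);
  for (R_xlen_t m = 0; m < M; ++m) {
    const double *xs = xp + m * T;
    for (int t = 0; t < To; ++t) {
      const int o = t * stride;
      int best = o;
      double v = xs[o];
      for (int j = 1; j < size; ++j)
        if (xs[o + j] > v) {
          v = xs[o + j];
          best = o + j;
        }
      yp[m * To + t] = v;
      ip[m * To + t] = best;
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_pool_max_bwd(NumericVector dy, IntegerVector idx, int T,
                               int To) {
  const R_xlen_t M = dy.size() / To;
  NumericVector dx((R_xlen_t)T * M);
  const double *dp = REAL(dy);
  const int *ip = INTEGER(idx);
  double *xp = REAL(dx);
  for (R_xlen_t m = 0; m < M; ++m)
    for (int t = 0; t < To; ++t)
      xp[m * T + ip[m * To + t]] += dp[m * To + t];
  return dx;
}

// ---------------------------------------------------------------------------
// Multi-head scaled dot-product self-attention over short token sequences
// ---------------------------------------------------------------------------

// tok: (L, D, S). Projections D -> dm, H heads, outputs for the first Lkeep
// tokens projected back to D. Returns output plus caches for the backward
// pass (Q, K, V, O as (L, dm, S); A as (L, L, H, S)).
// [[Rcpp::export]]
List cpp_attn_fwd(NumericVector tok, int L, int D, int S, arma::mat Wq,
                  arma::rowvec bq, arma::mat Wk, arma::rowvec bk, arma::mat Wv,
                  arma::rowvec bv, arma::mat Wo, arma::rowvec bo, int H,
                  int Lkeep) {
  const int dm = Wq.n_cols, dh = dm / H;
  const double sc = 1.0 / std::sqrt((double)dh);
  NumericVector out((R_xlen_t)Lkeep * D * S), Qs((R_xlen_t)L * dm * S),
      Ks((R_xlen_t)L * dm * S), Vs((R_xlen_t)L * dm * S),
      Os((R_xlen_t)L * dm * S), As((R_xlen_t)L * L * H * S);
  out.attr("dim") = IntegerVector::create(Lkeep, D, S);
  for (int s = 0; s < S; ++s) {
    const arma::mat T(const_cast<double *>(REAL(tok)) + (R_xlen_t)L * D * s, L,
                      D, false, true);
    arma::mat Q = T * Wq;
    Q.each_row() += bq;
    arma::mat K = T * Wk;
    K.each_row() += bk;
    arma::mat V = T * Wv;
    V.each_row() += bv;
    arma::mat O(L, dm);
    for (int h = 0; h < H; ++h) {
      arma::mat Qh = Q.cols(h * dh, (h + 1) * dh - 1);
      arma::mat Kh = K.cols(h * dh, (h + 1) * dh - 1);
      arma::mat Sc = Qh * Kh.t() * sc;
      // row-wise softmax
      arma::vec mx = arma::max(Sc, 1);
      Sc.each_col() -= mx;
      arma::mat A = arma::exp(Sc);
      arma::vec rs = arma::sum(A, 1);
      A.each_col() /= rs;
      O.cols(h * dh, (h + 1) * dh - 1) = A * V.cols(h * dh, (h + 1) * dh - 1);
      std::memcpy(REAL(As) + ((R_xlen_t)s * H + h) * L * L, A.memptr(),
                  sizeof(double) * L * L);
    }
    arma::mat Out = O.rows(0, Lkeep - 1) * Wo;
    Out.each_row() += bo;
    std::memcpy(REAL(out) + (R_xlen_t)Lkeep * D * s, Out.memptr(),
                sizeof(double) * Lkeep * D);
    std::memcpy(REAL(Qs) + (R_xlen_t)L * dm * s, Q.memptr(), sizeof(double) * L * dm);
    std::memcpy(REAL(Ks) + (R_xlen_t)L * dm * s, K.memptr(), sizeof(double) * L * dm);
    std::memcpy(REAL(Vs) + (R_xlen_t)L * dm * s, V.memptr(), sizeof(double) * L * dm);
    std::memcpy(REAL(Os) + (R_xlen_t)L * dm * s, O.memptr(), sizeof(double) * L * dm);
  }
  return List::create(_["out"] = out, _["Q"] = Qs, _["K"] = Ks, _["V"] = Vs,
                      _["O"] = Os, _["A"] = As);
}

// [[Rcpp::export]]
List cpp_attn_bwd(NumericVector tok, NumericVector dout, NumericVector Qs,
                  NumericVector Ks, NumericVector Vs, NumericVector Os,
                  NumericVector As, int L, int D, int S, arma::mat Wq,
                  arma::mat Wk, arma::mat Wv, arma::mat Wo, int H, int Lkeep) {
  const int dm = Wq.n_cols, dh = dm / H;
  const double sc = 1.0 / std::sqrt((double)dh);
  NumericVector dtok((R_xlen_t)L * D * S);
  dtok.attr("dim") = IntegerVector::create(L, D, S);
  arma::mat dWq(D, dm, arma::fill::zeros), dWk(D, dm, arma::fill::zeros),
      dWv(D, dm, arma::fill::zeros), dWo(dm, D, arma::fill::zeros);
  arma::rowvec dbq(dm, arma::fill::zeros), dbk(dm, arma::fill::zeros),
      dbv(dm, arma::fill::zeros), dbo(D, arma::fill::zeros);
  for (int s = 0; s < S; ++s) {
    const arma::mat T(const_cast<double *>(REAL(tok)) + (R_xlen_t)L * D * s, L,
                      D, false, true);
    const arma::mat dO_out(const_cast<double *>(REAL(dout)) +
                               (R_xlen_t)Lkeep * D * s,
                           Lkeep, D, false, true);
    const arma::mat Q(const_cast<double *>(REAL(Qs)) + (R_xlen_t)L * dm * s, L,
                      dm, false, true);
    const arma::mat K(const_cast<double *>(REAL(Ks)) + (R_xlen_t)L * dm * s, L,
                      dm, false, true);
    const arma::mat V(const_cast<double *>(REAL(Vs)) + (R_xlen_t)L * dm * s, L,
                      dm, false, true);
    const arma::mat O(const_cast<double *>(REAL(Os)) + (R_xlen_t)L * dm * s, L,
                      dm, false, true);
    dWo += O.rows(0, Lkeep - 1).t() * dO_out;
    dbo += arma::sum(dO_out, 0);
    arma::mat dO(L, dm, arma::fill::zeros);
    dO.rows(0, Lkeep - 1) = dO_out * Wo.t();
    arma::mat dQ(L, dm), dK(L, dm), dV(L, dm);
    for (int h = 0; h < H; ++h) {
      const arma::mat A(const_cast<double *>(REAL(As)) +
                            ((R_xlen_t)s * H + h) * L * L,
                        L, L, false, true);
      arma::mat dOh = dO.cols(h * dh, (h + 1) * dh - 1);
      arma::mat Vh = V.cols(h * dh, (h + 1) * dh - 1);
      arma::mat dA = dOh * Vh.t();
      dV.cols(h * dh, (h + 1) * dh - 1) = A.t() * dOh;
      arma::vec rowdot = arma::sum(dA % A, 1);
      arma::mat dS = A % (dA.each_col() - rowdot);
      dQ.cols(h * dh, (h + 1) * dh - 1) =
          dS * K.cols(h * dh, (h + 1) * dh - 1) * sc;
      dK.cols(h * dh, (h + 1) * dh - 1) =
          dS.t() * Q.cols(h * dh, (h + 1) * dh - 1) * sc;
    }
    arma::mat dT = dQ * Wq.t() + dK * Wk.t() + dV * Wv.t();
    std::memcpy(REAL(dtok) + (R_xlen_t)L * D * s, dT.memptr(),
                sizeof(double) * L * D);
    dWq += T.t() * dQ;
    dbq += arma::sum(dQ, 0);
    dWk += T.t() * dK;
    dbk += arma::sum(dK, 0);
    dWv += T.t() * dV;
    dbv += arma::sum(dV, 0);
  }
  return List::create(_["dtok"] = dtok, _["dWq"] = dWq, _["dbq"] = dbq,
                      _["dWk"] = dWk, _["dbk"] = dbk, _["dWv"] = dWv,
                      _["dbv"] = dbv, _["dWo"] = dWo, _["dbo"] = dbo);
}

// ---------------------------------------------------------------------------
// Fused band conv (kernel 3) + average pool (non-overlapping) stages
// ---------------------------------------------------------------------------

// x: (T, K, C, B); w: (3, K); b: K. Conv to T-2 then average pool
// size/stride `pool`. Returns (To, K, C, B), To = (T-2-pool)/pool + 1.
// [[Rcpp::export]]
NumericVector cpp_band_stage_fwd(NumericVector x, NumericMatrix w,
                                 NumericVector b, int T, int K, int C, int B,
                                 int pool) {
  const int Tc = T - 2;
  const int To = (Tc - pool) / pool + 1;
  NumericVector y((R_xlen_t)To * K * C * B);
  y.attr("dim") = IntegerVector::create(To, K, C, B);
  const double *xp = REAL(x);
  double *yp = REAL(y);
  const double inv = 1.0 / pool;
  for (int n = 0; n < B; ++n)
    for (int c = 0; c < C; ++c)
      for (int k = 0; k < K; ++k) {
        const double w0 = w(0, k), w1 = w(1, k), w2 = w(2, k), bk = b[k];
        const double *xs = xp + (R_xlen_t)T * (k + (R_xlen_t)K * (c + (R_xlen_t)C * n));
        double *ys = yp + (R_xlen_t)To * (k + (R_xlen_t)K * (c + (R_xlen_t)C * n));
        for (int t = 0; t < To; ++t) {
          const int o = t * pool;
          double s = 0;
          for (int j = 0; j < pool; ++j)
            s += w0 * xs[o + j] + w1 * xs[o + j + 1] + w2 * xs[o + j + 2];
          ys[t] = s * inv + bk;
        }
      }
  return y;
}

// [[Rcpp::export]]
List cpp_band_stage_bwd(NumericVector x, NumericMatrix w, NumericVector dy,
                        int T, int K, int C, int B, int pool, bool want_dx) {
  const int Tc = T - 2;
  const int To = (Tc - pool) / pool + 1;
  NumericVector dx(want_dx ? (R_xlen_t)T * K * C * B : 0);
  if (want_dx) dx.attr("dim") = IntegerVector::create(T, K, C, B);
  NumericMatrix dw(3, K);
  NumericVector db(K);
  const double *xp = REAL(x), *dyp = REAL(dy);
  double *dxp = want_dx ? REAL(dx) : nullptr;
  const double inv = 1.0 / pool;
  for (int n = 0; n < B; ++n)
    for (int c = 0; c < C; ++c)
      for (int k = 0; k < K; ++k) {
        const double w0 = w(0, k), w1 = w(1, k), w2 = w(2, k);
        const R_xlen_t base = (R_xlen_t)(k + (R_xlen_t)K * (c + (R_xlen_t)C * n));
        const double *xs = xp + (R_xlen_t)T * base;
        const double *ds = dyp + (R_xlen_t)To * base;
        double *gs = want_dx ? dxp + (R_xlen_t)T * base : nullptr;
        double s0 = 0, s1 = 0, s2 = 0, sb = 0;
        for (int t = 0; t < To; ++t) {
          const double d = ds[t] * inv;
          const int o = t * pool;
          for (int j = 0; j < pool; ++j) {
            const int u = o + j;
            if (want_dx) {
              gs[u] += w0 * d;
              gs[u + 1] += w1 * d;
              gs[u + 2] += w2 * d;
            }
            s0 += xs[u] * d;
            s1 += xs[u + 1] * d;
            s2 += xs[u + 2] * d;
          }
          sb += ds[t];
        }
        dw(0, k) += s0;
        dw(1, k) += s1;
        dw(2, k) += s2;
        db[k] += sb;
      }
  if (want_dx)
    return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
  return List::create(_["dw"] = dw, _["db"] = db);
}

// ---------------------------------------------------------------------------
// uint16-quantised feature cache (per-item-per-band scale factors)
// ---------------------------------------------------------------------------

// x: (nt, K, C, B) nonnegative magnitudes. Stores round(x / scale) per
// (band, item) where scale = max/65535, writing B items starting at item
// index `item0`. scales: (K, n_items) matrix filled in place.
// [[Rcpp::export]]
void cpp_qcache_store(RawVector cache, NumericVector x, NumericMatrix scales,
                      int nt, int K, int C, int B, double item0) {
  uint16_t *p = reinterpret_cast<uint16_t *>(RAW(cache));
  const double *xp = REAL(x);
  const R_xlen_t per_item = (R_xlen_t)nt * K * C;
  for (int n = 0; n < B; ++n) {
    const size_t it = (size_t)item0 + n;
    for (int k = 0; k < K; ++k) {
      double mx = 0;
      for (int c = 0; c < C; ++c) {
        const double *xs = xp + (R_xlen_t)nt * (k + (R_xlen_t)K * (c + (R_xlen_t)C * n));
        for (int t = 0; t < nt; ++t)
          if (xs[t] > mx) mx = xs[t];
      }
      const double sc = mx > 0 ? mx / 65535.0 : 1.0;
      scales(k, it) = sc;
      const double isc = 1.0 / sc;
      for (int c = 0; c < C; ++c) {
        const double *xs = xp + (R_xlen_t)nt * (k + (R_xlen_t)K * (c + (R_xlen_t)C * n));
        uint16_t *dst = p + it * per_item + ((R_xlen_t)c * K + k) * nt;
        for (int t = 0; t < nt; ++t)
          dst[t] = (uint16_t)(xs[t] * isc + 0.5);
      }
    }
  }
}

// Fetch items idx0 (0-based) into a (nt, K, C, B) double array.
// [[Rcpp::export]]
NumericVector cpp_qcache_fetch(RawVector cache, NumericMatrix scales,
                               NumericVector idx0, int nt, int K, int C) {
  const uint16_t *p = reinterpret_cast<const uint16_t *>(RAW(cache));
  const R_xlen_t per_item = (R_xlen_t)nt * K * C;
  const int B = idx0.size();
  NumericVector out(per_item * B);
  out.attr("dim") = IntegerVector::create(nt, K, C, B);
  double *op = REAL(out);
  for (int n = 0; n < B; ++n) {
    const size_t it = (size_t)idx0[n];
    for (int c = 0; c < C; ++c)
      for (int k = 0; k < K; ++k) {
        const uint16_t *src = p + it * per_item + ((R_xlen_t)c * K + k) * nt;
        double *dst = op + (R_xlen_t)nt * (k + (R_xlen_t)K * (c + (R_xlen_t)C * n));
        const double sc = scales(k, it);
        for (int t = 0; t < nt; ++t) dst[t] = src[t] * sc;
      }
  }
  return out;
}

// ---------------------------------------------------------------------------
// causal dilated conv (kernel 3) over sequences (T, Cin, B) via BLAS
// ---------------------------------------------------------------------------

// Returns list(y (T, Cout, B), xcol (3*Cin, T*B)) with causal left padding
// of 2*dil (the padding overhang is never produced).
// [[Rcpp::export]]
List cpp_tcn_conv_fwd(NumericVector x, arma::mat W, arma::vec b, int T,
                      int Cin, int B, int dil) {
  const int Cout = W.n_rows;
  arma::mat Xcol(3 * Cin, (R_xlen_t)T * B, arma::fill::zeros);
  const double *xp = REAL(x);
  for (int n = 0; n < B; ++n)
    for (int ci = 0; ci < Cin; ++ci) {
      const double *xs = xp + (R_xlen_t)T * (ci + (R_xlen_t)Cin * n);
      for (int j = 0; j < 3; ++j) {
        const int shift = (2 - j) * dil; // input time = t - shift
        double *col0 = Xcol.memptr() + (R_xlen_t)(j * Cin + ci);
        const R_xlen_t ldc = 3 * Cin;
        for (int t = shift; t < T; ++t)
          col0[((R_xlen_t)n * T + t) * ldc] = xs[t - shift];
      }
    }
  arma::mat Y = W * Xcol;
  Y.each_col() += b;
  NumericVector y((R_xlen_t)T * Cout * B);
  y.attr("dim") = IntegerVector::create(T, Cout, B);
  double *yp = REAL(y);
  // Y is (Cout, T*B): transpose into (T, Cout, B)
  for (int n = 0; n < B; ++n)
    for (int t = 0; t < T; ++t) {
      const double *src = Y.colptr((R_xlen_t)n * T + t);
      for (int co = 0; co < Cout; ++co)
        yp[t + (R_xlen_t)T * (co + (R_xlen_t)Cout * n)] = src[co];
    }
  return List::create(_["y"] = y, _["xcol"] = Xcol);
}

// [[Rcpp::export]]
List cpp_tcn_conv_bwd(NumericVector dy, arma::mat Xcol, arma::mat W, int T,
                      int Cin, int B, int dil) {
  const int Cout = W.n_rows;
  arma::mat dY(Cout, (R_xlen_t)T * B);
  const double *dp = REAL(dy);
  for (int n = 0; n < B; ++n)
    for (int t = 0; t < T; ++t) {
      double *dst = dY.colptr((R_xlen_t)n * T + t);
      for (int co = 0; co < Cout; ++co)
        dst[co] = dp[t + (R_xlen_t)T * (co + (R_xlen_t)Cout * n)];
    }
  arma::mat dW = dY * Xcol.t();
  arma::vec db = arma::sum(dY, 1);
  arma::mat dXcol = W.t() * dY; // (3*Cin, T*B)
  NumericVector dx((R_xlen_t)T * Cin * B);
  dx.attr("dim") = IntegerVector::create(T, Cin, B);
  double *xp = REAL(dx);
  const R_xlen_t ldc = 3 * Cin;
  for (int n = 0; n < B; ++n)
    for (int ci = 0; ci < Cin; ++ci) {
      double *xs = xp + (R_xlen_t)T * (ci + (R_xlen_t)Cin * n);
      for (int j = 0; j < 3; ++j) {
        const int shift = (2 - j) * dil;
        const double *col0 = dXcol.memptr() + (R_xlen_t)(j * Cin + ci);
        for (int t = shift; t < T; ++t)
          xs[t - shift] += col0[((R_xlen_t)n * T + t) * ldc];
      }
    }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// ---------------------------------------------------------------------------
// Stage-1 band conv+pool running directly on the uint16 cache
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_band_stage_fwd_u16(RawVector cache, NumericMatrix scales,
                                     NumericVector idx0, NumericMatrix w,
                                     NumericVector b, int T, int K, int C,
                                     int pool) {
  const uint16_t *p = reinterpret_cast<const uint16_t *>(RAW(cache));
  const R_xlen_t per_item = (R_xlen_t)T * K * C;
  const int B = idx0.size();
  const int Tc = T - 2;
  const int To = (Tc - pool) / pool + 1;
  NumericVector y((R_xlen_t)To * K * C * B);
  y.attr("dim") = IntegerVector::create(To, K, C, B);
  double *yp = REAL(y);
  const double inv = 1.0 / pool;
  for (int n = 0; n < B; ++n) {
    const size_t it = (size_t)idx0[n];
    for (int c = 0; c < C; ++c)
      for (int k = 0; k < K; ++k) {
        const double sc = scales(k, it);
        const double w0 = w(0, k) * sc, w1 = w(1, k) * sc, w2 = w(2, k) * sc;
        const double bk = b[k];
        const uint16_t *xs = p + it * per_item + ((R_xlen_t)c * K + k) * T;
        double *ys = yp + (R_xlen_t)To * (k + (R_xlen_t)K * (c + (R_xlen_t)C * n));
        for (int t = 0; t < To; ++t) {
          const int o = t * pool;
          double s = 0;
          for (int j = 0; j < pool; ++j)
            s += w0 * xs[o + j] + w1 * xs[o + j + 1] + w2 * xs[o + j + 2];
          ys[t] = s * inv + bk;
        }
      }
  }
  return y;
}

// weight/bias gradients only (the input gradient of the first stage is
// never consumed).
// [[Rcpp::export]]
List cpp_band_stage_bwd_u16(RawVector cache, NumericMatrix scales,
                            NumericVector idx0, NumericVector dy, int T,
                            int K, int C, int pool) {
  const uint16_t *p = reinterpret_cast<const uint16_t *>(RAW(cache));
  const R_xlen_t per_item = (R_xlen_t)T * K * C;
  const int B = idx0.size();
  const int Tc = T - 2;
  const int To = (Tc - pool) / pool + 1;
  NumericMatrix dw(3, K);
  NumericVector db(K);
  const double *dyp = REAL(dy);
  const double inv = 1.0 / pool;
  for (int n = 0; n < B; ++n) {
    const size_t it = (size_t)idx0[n];
    for (int c = 0; c < C; ++c)
      for (int k = 0; k < K; ++k) {
        const double sc = scales(k, it);
        const uint16_t *xs = p + it * per_item + ((R_xlen_t)c * K + k) * T;
        const double *ds = dyp + (R_xlen_t)To *
          (k + (R_xlen_t)K * (c + (R_xlen_t)C * n));
        double s0 = 0, s1 = 0, s2 = 0, sb = 0;
        for (int t = 0; t < To; ++t) {
          const double d = ds[t] * inv;
          const int o = t * pool;
          for (int j = 0; j < pool; ++j) {
            const int u = o + j;
            s0 += xs[u] * d;
            s1 += xs[u + 1] * d;
            s2 += xs[u + 2] * d;
          }
          sb += ds[t];
        }
        dw(0, k) += s0 * sc;
        dw(1, k) += s1 * sc;
        dw(2, k) += s2 * sc;
        db[k] += sb;
      }
  }
  return List::create(_["dw"] = dw, _["db"] = db);
}

// ---------------------------------------------------------------------------
// allocator hygiene
// ---------------------------------------------------------------------------

#ifdef __GLIBC__
#include <malloc.h>
#endif

// Return freed heap pages to the OS (no-op on non-glibc platforms). Large
// batched tensors otherwise keep the resident footprint at its high-water
// mark between training runs.
// [[Rcpp::export]]
void cpp_release_memory() {
#ifdef __GLIBC__
  malloc_trim(0);
#endif
}
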