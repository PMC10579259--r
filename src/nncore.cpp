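// Core numerical kernels for the convolutional autoencoder models.
//
// Tensors use the R array layout (N, H, W, C) in column-major order, so the
// same memory block is simultaneously an (N*H*W) x C matrix (one column per
// feature map) and an N x (H*W*C) matrix (one row per batch item).  H is the
// time axis (samples), W the channel axis of the EEG montage, C the feature
// maps.  Convolutions are "same"-padded with stride 1; for even kernel extents
// the padding is split floor((k-1)/2) before / remainder after, i.e. a 3x2
// kernel pads one row above and below and one column on the right.
//
// Everything is templated on the element type: the exported layer primitives
// run in double precision (they are the contract checked against brute-force
// oracles), while the training engine instantiates the same code in single
// precision for speed.  The engine's elementwise steps are fused manual loops:
// on a single CPU the large intermediate tensors make memory traffic, not
// GEMM, the limiting factor.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#ifdef __GLIBC__
#include <malloc.h>
#endif

using Rcpp::List;
using Rcpp::NumericVector;
using Rcpp::IntegerVector;
using Rcpp::Named;
using Rcpp::stop;

// Large scratch blocks (im2col patch matrices, activation tensors) are
// allocated and freed every training step; keeping them inside the heap
// arena instead of per-call mmap/munmap avoids re-faulting hundreds of MB
// of pages on every batch.
// [[Rcpp::export]]
void cpp_tune_malloc() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 1 << 30);
  mallopt(M_TRIM_THRESHOLD, 1 << 30);
#endif
}

template <typename T>
struct Ten {
  int N = 0, H = 0, W = 0, C = 0;
  arma::Mat<T> m;  // (N*H*W) x C
  Ten() = default;
  Ten(int n, int h, int w, int c)
      : N(n), H(h), W(w), C(c),
        m(n * h * w, c, arma::fill::none) {}
  T* col(int c_) { return m.colptr(c_); }
  const T* col(int c_) const { return m.colptr(c_); }
  inline int sp(int h, int w) const { return N * (h + H * w); }
};

// ---------------------------------------------------------------------------
// im2col / col2im

template <typename T>
static void im2col(const Ten<T>& x, int kh, int kw, arma::Mat<T>& P) {
  const int N = x.N, H = x.H, W = x.W, C = x.C;
  const int pt = (kh - 1) / 2, pl = (kw - 1) / 2;
  P.set_size((arma::uword)N * H * W, (arma::uword)kh * kw * C);
  for (int c = 0; c < C; ++c) {
    const T* src = x.col(c);
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        T* dst = P.colptr(dh + kh * (dw + kw * c));
        for (int w = 0; w < W; ++w) {
          const int ws = w + dw - pl;
          const bool wok = ws >= 0 && ws < W;
          for (int h = 0; h < H; ++h) {
            const int hs = h + dh - pt;
            T* d = dst + x.sp(h, w);
            if (wok && hs >= 0 && hs < H)
              std::memcpy(d, src + x.sp(hs, ws), N * sizeof(T));
            else
              std::memset(d, 0, N * sizeof(T));
          }
        }
      }
    }
  }
}

template <typename T>
static void col2im_add(const arma::Mat<T>& dP, int kh, int kw, Ten<T>& dx) {
  const int N = dx.N, H = dx.H, W = dx.W, C = dx.C;
  const int pt = (kh - 1) / 2, pl = (kw - 1) / 2;
  for (int c = 0; c < C; ++c) {
    T* dst = dx.col(c);
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const T* src = dP.colptr(dh + kh * (dw + kw * c));
        for (int w = 0; w < W; ++w) {
          const int ws = w + dw - pl;
          if (ws < 0 || ws >= W) continue;
          for (int h = 0; h < H; ++h) {
            const int hs = h + dh - pt;
            if (hs < 0 || hs >= H) continue;
            T* d = dst + dx.sp(hs, ws);
            const T* s = src + dx.sp(h, w);
            for (int n = 0; n < N; ++n) d[n] += s[n];
          }
        }
      }
    }
  }
}

// ---------------------------------------------------------------------------
// Convolution (same padding, stride 1)
//
// Two equivalent routes: the classic im2col + one GEMM (used when the input
// has few feature maps, where patch extraction is cheap), and a direct
// decomposition into kh*kw shifted GEMMs on contiguous (n, h) blocks per
// channel-column, which skips the patch matrix entirely and roughly halves
// memory traffic for deep inputs.

extern "C" {
void dgemm_(const char*, const char*, const int*, const int*, const int*,
            const double*, const double*, const int*, const double*,
            const int*, const double*, double*, const int*);
}

// FLOAT_GEMM_BEGIN (single-precision BLAS entry for the training engine)
extern "C" {
void sgemm_(const char*, const char*, const int*, const int*, const int*,
            const float*, const float*, const int*, const float*, const int*,
            const float*, float*, const int*);
}
static inline void gemm_blas(char ta, char tb, int m, int n, int k,
                             float alpha, const float* A, int lda,
                             const float* B, int ldb, float beta, float* C,
                             int ldc) {
  sgemm_(&ta, &tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C, &ldc);
}
// FLOAT_GEMM_END
static inline void gemm_blas(char ta, char tb, int m, int n, int k,
                             double alpha, const double* A, int lda,
                             const double* B, int ldb, double beta, double* C,
                             int ldc) {
  dgemm_(&ta, &tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C, &ldc);
}

// Weight sub-matrix (C x F) for one kernel offset (dh, dw).
template <typename T>
static std::vector<arma::Mat<T>> split_kernel(const arma::Mat<T>& Wm, int kh,
                                              int kw, int C) {
  const int F = (int)Wm.n_cols;
  std::vector<arma::Mat<T>> Wsub(kh * kw);
  for (int dw = 0; dw < kw; ++dw)
    for (int dh = 0; dh < kh; ++dh) {
      arma::Mat<T> s(C, F, arma::fill::none);
      for (int c = 0; c < C; ++c) s.row(c) = Wm.row(dh + kh * (dw + kw * c));
      Wsub[dh + kh * dw] = std::move(s);
    }
  return Wsub;
}

// act: 0 = linear, 1 = ReLU, 2 = sigmoid; the bias add and activation are a
// single fused pass over the output.
template <typename T>
static Ten<T> conv_fwd(const Ten<T>& x, const arma::Mat<T>& Wm,
                       const arma::Col<T>& b, int kh, int kw, int act = 0) {
  if ((int)Wm.n_rows != kh * kw * x.C)
    stop("conv2d: weight rows (%d) do not match kernel*channels (%d)",
         (int)Wm.n_rows, kh * kw * x.C);
  const int N = x.N, H = x.H, W = x.W, C = x.C;
  const int F = (int)Wm.n_cols;
  const int pt = (kh - 1) / 2, pl = (kw - 1) / 2;
  Ten<T> out(N, H, W, F);
  if (C >= 8) {
    std::vector<arma::Mat<T>> Wsub = split_kernel(Wm, kh, kw, C);
    out.m.zeros();
    const int ldx = (int)x.m.n_rows, ldo = (int)out.m.n_rows;
    for (int w = 0; w < W; ++w)
      for (int dw = 0; dw < kw; ++dw) {
        const int ws = w + dw - pl;
        if (ws < 0 || ws >= W) continue;
        for (int dh = 0; dh < kh; ++dh) {
          const int sh = dh - pt;
          const int a = std::max(0, -sh), e = std::min(H, H - sh);
          gemm_blas('N', 'N', N * (e - a), F, C, (T)1,
                    x.m.memptr() + (size_t)N * (a + sh + (size_t)H * ws), ldx,
                    Wsub[dh + kh * dw].memptr(), C, (T)1,
                    out.m.memptr() + (size_t)N * (a + (size_t)H * w), ldo);
        }
      }
  } else {
    arma::Mat<T> P;
    im2col(x, kh, kw, P);
    out.m = P * Wm;
  }
  const arma::uword M = out.m.n_rows;
  for (int f = 0; f < F; ++f) {
    T* p = out.col(f);
    const T bf = b[f];
    if (act == 1) {
      for (arma::uword i = 0; i < M; ++i) {
        const T v = p[i] + bf;
        p[i] = v > (T)0 ? v : (T)0;
      }
    } else if (act == 2) {
      for (arma::uword i = 0; i < M; ++i) {
        const T v = p[i] + bf;
        if (v >= (T)0) p[i] = (T)1 / ((T)1 + std::exp(-v));
        else { const T e = std::exp(v); p[i] = e / ((T)1 + e); }
      }
    } else {
      for (arma::uword i = 0; i < M; ++i) p[i] += bf;
    }
  }
  return out;
}

template <typename T>
static void conv_bwd(const Ten<T>& x, const arma::Mat<T>& Wm, int kh, int kw,
                     const Ten<T>& dout, arma::Mat<T>& dW, arma::Col<T>& db,
                     Ten<T>* dx) {
  const int N = x.N, H = x.H, W = x.W, C = x.C;
  const int F = (int)Wm.n_cols;
  const int pt = (kh - 1) / 2, pl = (kw - 1) / 2;
  db = arma::sum(dout.m, 0).t();
  if (C >= 8) {
    const int ldx = (int)x.m.n_rows, ldo = (int)dout.m.n_rows;
    std::vector<arma::Mat<T>> G(kh * kw);
    for (auto& g : G) g.zeros(C, F);
    if (dx) {
      dx->N = N; dx->H = H; dx->W = W; dx->C = C;
      dx->m.zeros(x.m.n_rows, x.m.n_cols);
    }
    std::vector<arma::Mat<T>> Wsub =
        dx ? split_kernel(Wm, kh, kw, C) : std::vector<arma::Mat<T>>();
    for (int w = 0; w < W; ++w)
      for (int dw = 0; dw < kw; ++dw) {
        const int ws = w + dw - pl;
        if (ws < 0 || ws >= W) continue;
        for (int dh = 0; dh < kh; ++dh) {
          const int sh = dh - pt;
          const int a = std::max(0, -sh), e = std::min(H, H - sh);
          const int M = N * (e - a);
          const T* xs = x.m.memptr() + (size_t)N * (a + sh + (size_t)H * ws);
          const T* gs = dout.m.memptr() + (size_t)N * (a + (size_t)H * w);
          gemm_blas('T', 'N', C, F, M, (T)1, xs, ldx, gs, ldo, (T)1,
                    G[dh + kh * dw].memptr(), C);
          if (dx)
            gemm_blas('N', 'T', M, C, F, (T)1, gs, ldo,
                      Wsub[dh + kh * dw].memptr(), C, (T)1,
                      dx->m.memptr() + (size_t)N * (a + sh + (size_t)H * ws),
                      ldx);
        }
      }
    dW.set_size(kh * kw * C, F);
    for (int dw = 0; dw < kw; ++dw)
      for (int dh = 0; dh < kh; ++dh)
        for (int c = 0; c < C; ++c)
          dW.row(dh + kh * (dw + kw * c)) = G[dh + kh * dw].row(c);
  } else {
    arma::Mat<T> P;
    im2col(x, kh, kw, P);
    dW = P.t() * dout.m;
    if (dx) {
      P = dout.m * Wm.t();
      dx->N = N; dx->H = H; dx->W = W; dx->C = C;
      dx->m.zeros(x.m.n_rows, x.m.n_cols);
      col2im_add(P, kh, kw, *dx);
    }
  }
}

// ---------------------------------------------------------------------------
// Max pooling (ceil mode: partial boundary windows are kept)

template <typename T>
static Ten<T> pool_fwd(const Ten<T>& x, int ph, int pw,
                       arma::Mat<arma::s32>* arg) {
  const int N = x.N, H = x.H, W = x.W, C = x.C;
  const int Ho = (H + ph - 1) / ph, Wo = (W + pw - 1) / pw;
  Ten<T> out(N, Ho, Wo, C);
  if (arg) arg->set_size(out.m.n_rows, out.m.n_cols);
  for (int c = 0; c < C; ++c) {
    const T* src = x.col(c);
    T* dst = out.col(c);
    arma::s32* am = arg ? arg->colptr(c) : nullptr;
    for (int wo = 0; wo < Wo; ++wo) {
      const int w0 = wo * pw, w1 = std::min(W, w0 + pw);
      for (int ho = 0; ho < Ho; ++ho) {
        const int h0 = ho * ph, h1 = std::min(H, h0 + ph);
        const int o = out.sp(ho, wo);
        for (int n = 0; n < N; ++n) {
          T best = src[n + x.sp(h0, w0)];
          int besti = n + x.sp(h0, w0);
          for (int w = w0; w < w1; ++w)
            for (int h = h0; h < h1; ++h) {
              const int i = n + x.sp(h, w);
              if (src[i] > best) { best = src[i]; besti = i; }
            }
          dst[o + n] = best;
          if (am) am[o + n] = besti;
        }
      }
    }
  }
  return out;
}

template <typename T>
static Ten<T> pool_bwd(const Ten<T>& dout, const arma::Mat<arma::s32>& arg,
                       int N, int H, int W, int C) {
  Ten<T> dx(N, H, W, C);
  dx.m.zeros();
  for (int c = 0; c < C; ++c) {
    const T* g = dout.col(c);
    const arma::s32* am = arg.colptr(c);
    T* dst = dx.col(c);
    const arma::uword n_el = dout.m.n_rows;
    for (arma::uword i = 0; i < n_el; ++i) dst[am[i]] += g[i];
  }
  return dx;
}

// ---------------------------------------------------------------------------
// Nearest-neighbour upsampling (each cell repeated fh x fw times)

template <typename T>
static Ten<T> upsample_fwd(const Ten<T>& x, int fh, int fw) {
  const int N = x.N, H = x.H, W = x.W, C = x.C;
  Ten<T> out(N, H * fh, W * fw, C);
  for (int c = 0; c < C; ++c) {
    const T* src = x.col(c);
    T* dst = out.col(c);
    for (int w = 0; w < W * fw; ++w)
      for (int h = 0; h < H * fh; ++h)
        std::memcpy(dst + out.sp(h, w), src + x.sp(h / fh, w / fw),
                    N * sizeof(T));
  }
  return out;
}

template <typename T>
static Ten<T> upsample_bwd(const Ten<T>& dout, int fh, int fw) {
  const int N = dout.N, H = dout.H / fh, W = dout.W / fw, C = dout.C;
  Ten<T> dx(N, H, W, C);
  dx.m.zeros();
  for (int c = 0; c < C; ++c) {
    const T* g = dout.col(c);
    T* dst = dx.col(c);
    for (int w = 0; w < dout.W; ++w)
      for (int h = 0; h < dout.H; ++h) {
        T* d = dst + dx.sp(h / fh, w / fw);
        const T* s = g + dout.sp(h, w);
        for (int n = 0; n < N; ++n) d[n] += s[n];
      }
  }
  return dx;
}

// ---------------------------------------------------------------------------
// Elementwise activations (fused manual loops)

template <typename T>
static inline void relu_inplace(arma::Mat<T>& m) {
  T* p = m.memptr();
  const arma::uword n = m.n_elem;
  for (arma::uword i = 0; i < n; ++i)
    if (p[i] < (T)0) p[i] = (T)0;
}

template <typename T>
static inline void sigmoid_inplace(arma::Mat<T>& m) {
  T* p = m.memptr();
  const arma::uword n = m.n_elem;
  for (arma::uword i = 0; i < n; ++i) {
    const T v = p[i];
    if (v >= (T)0) p[i] = (T)1 / ((T)1 + std::exp(-v));
    else { const T e = std::exp(v); p[i] = e / ((T)1 + e); }
  }
}

// grad[i] <- grad[i] if ref[i] > 0 else 0   (ReLU backward)
template <typename T>
static inline void relu_mask(arma::Mat<T>& grad, const arma::Mat<T>& ref) {
  T* g = grad.memptr();
  const T* r = ref.memptr();
  const arma::uword n = grad.n_elem;
  for (arma::uword i = 0; i < n; ++i)
    if (r[i] <= (T)0) g[i] = (T)0;
}

// grad[i] <- grad[i] * a[i] * (1 - a[i])    (sigmoid backward)
template <typename T>
static inline void sigmoid_mask(arma::Mat<T>& grad, const arma::Mat<T>& a) {
  T* g = grad.memptr();
  const T* p = a.memptr();
  const arma::uword n = grad.n_elem;
  for (arma::uword i = 0; i < n; ++i) g[i] *= p[i] * ((T)1 - p[i]);
}

// ---------------------------------------------------------------------------
// Batch normalization (per feature map over batch and spatial axes)

template <typename T>
struct BNCache {
  arma::Mat<T> xhat;
  arma::Col<T> invstd, mean, var;
};

// In-place train-mode forward; xhat kept for the backward pass.  Mean and
// variance use the single-pass sum / sum-of-squares form (values are O(1)
// after input normalization, so cancellation is not a concern).
template <typename T>
static void bn_train_fwd(Ten<T>& x, const arma::Col<T>& gamma,
                         const arma::Col<T>& beta, T eps, BNCache<T>& cache) {
  const arma::uword M = x.m.n_rows;
  const int C = (int)x.m.n_cols;
  cache.mean.set_size(C); cache.var.set_size(C); cache.invstd.set_size(C);
  cache.xhat.set_size(M, C);
  for (int c = 0; c < C; ++c) {
    const arma::Col<T> pc(const_cast<T*>(x.col(c)), M, false, true);
    const double s = arma::accu(pc), s2 = arma::dot(pc, pc);
    const double mu = s / M;
    const double var = std::max(0.0, s2 / M - mu * mu);
    cache.mean[c] = (T)mu;
    cache.var[c] = (T)var;
    cache.invstd[c] = (T)(1.0 / std::sqrt(var + (double)eps));
    const T m_ = cache.mean[c], is_ = cache.invstd[c];
    const T g_ = gamma[c], b_ = beta[c];
    T* xh = cache.xhat.colptr(c);
    T* y = x.col(c);
    for (arma::uword i = 0; i < M; ++i) {
      const T v = (y[i] - m_) * is_;
      xh[i] = v;
      y[i] = g_ * v + b_;
    }
  }
}

template <typename T>
static void bn_infer_fwd(Ten<T>& x, const arma::Col<T>& gamma,
                         const arma::Col<T>& beta, const arma::Col<T>& rmean,
                         const arma::Col<T>& rvar, T eps) {
  const arma::uword M = x.m.n_rows;
  for (int c = 0; c < (int)x.m.n_cols; ++c) {
    const T is_ = (T)(1.0 / std::sqrt((double)rvar[c] + (double)eps));
    const T a = gamma[c] * is_;
    const T b = beta[c] - a * rmean[c];
    T* y = x.col(c);
    for (arma::uword i = 0; i < M; ++i) y[i] = a * y[i] + b;
  }
}

// In-place backward: dy is overwritten with dx.
// dx = (gamma * invstd) * (dy - mean(dy) - xhat * mean(dy * xhat))
// When fuse_relu is set, the preceding ReLU's backward mask is applied in the
// same pass: the pre-BN activation was zero exactly where
// xhat == (0 - mean) * invstd, so the mask is a per-channel threshold on xhat.
template <typename T>
static void bn_bwd_inplace(arma::Mat<T>& dy, const arma::Col<T>& gamma,
                           const BNCache<T>& cache, arma::Col<T>& dgamma,
                           arma::Col<T>& dbeta, bool fuse_relu) {
  const arma::uword M = dy.n_rows;
  const int C = (int)dy.n_cols;
  dgamma.set_size(C); dbeta.set_size(C);
  for (int c = 0; c < C; ++c) {
    T* g = dy.colptr(c);
    const T* xh = cache.xhat.colptr(c);
    const arma::Col<T> gc(g, M, false, true);
    const arma::Col<T> xc(const_cast<T*>(xh), M, false, true);
    const double sdy = arma::accu(gc), sdyx = arma::dot(gc, xc);
    dgamma[c] = (T)sdyx;
    dbeta[c] = (T)sdy;
    const T a = gamma[c] * cache.invstd[c];
    const T mdy = (T)(sdy / M), mdyx = (T)(sdyx / M);
    if (fuse_relu) {
      const T thr = ((T)0 - cache.mean[c]) * cache.invstd[c];
      for (arma::uword i = 0; i < M; ++i)
        g[i] = xh[i] <= thr ? (T)0 : a * (g[i] - mdy - xh[i] * mdyx);
    } else {
      for (arma::uword i = 0; i < M; ++i)
        g[i] = a * (g[i] - mdy - xh[i] * mdyx);
    }
  }
}

// ---------------------------------------------------------------------------
// LSTM (gate order in the packed weight matrix: forget, input, output,
// candidate; the weight acts on the concatenation [h_prev, y_t])

template <typename T>
struct LSTMCache {
  std::vector<arma::Mat<T>> Z;  // per step: N x (Hd + F)
  std::vector<arma::Mat<T>> j, k, l, cand, c, tanh_c;
};

template <typename T>
static std::vector<arma::Mat<T>> lstm_fwd(const std::vector<arma::Mat<T>>& Y,
                                          const arma::Mat<T>& Wm,
                                          const arma::Col<T>& b, int Hd,
                                          LSTMCache<T>* cache) {
  const int Tn = (int)Y.size();
  const int N = (int)Y[0].n_rows;
  std::vector<arma::Mat<T>> out(Tn);
  arma::Mat<T> h(N, Hd, arma::fill::zeros), c(N, Hd, arma::fill::zeros);
  if (cache) {
    cache->Z.resize(Tn); cache->j.resize(Tn); cache->k.resize(Tn);
    cache->l.resize(Tn); cache->cand.resize(Tn); cache->c.resize(Tn);
    cache->tanh_c.resize(Tn);
  }
  for (int t = 0; t < Tn; ++t) {
    arma::Mat<T> Z = arma::join_rows(h, Y[t]);
    arma::Mat<T> G = Z * Wm;
    G.each_row() += b.t();
    arma::Mat<T> j = G.cols(0, Hd - 1);
    arma::Mat<T> k = G.cols(Hd, 2 * Hd - 1);
    arma::Mat<T> l = G.cols(2 * Hd, 3 * Hd - 1);
    arma::Mat<T> cand = G.cols(3 * Hd, 4 * Hd - 1);
    sigmoid_inplace(j); sigmoid_inplace(k); sigmoid_inplace(l);
    cand = arma::tanh(cand);
    c = j % c + k % cand;
    arma::Mat<T> tc = arma::tanh(c);
    h = l % tc;
    out[t] = h;
    if (cache) {
      cache->Z[t] = std::move(Z); cache->j[t] = j; cache->k[t] = k;
      cache->l[t] = l; cache->cand[t] = cand; cache->c[t] = c;
      cache->tanh_c[t] = tc;
    }
  }
  return out;
}

// dHs: upstream gradient on each step's hidden output.  Returns dY per step;
// accumulates dW, db.
template <typename T>
static std::vector<arma::Mat<T>> lstm_bwd(const std::vector<arma::Mat<T>>& dHs,
                                          const arma::Mat<T>& Wm, int Hd,
                                          const LSTMCache<T>& cache,
                                          arma::Mat<T>& dW, arma::Col<T>& db) {
  const int Tn = (int)dHs.size();
  const int N = (int)dHs[0].n_rows;
  const int F = (int)cache.Z[0].n_cols - Hd;
  dW.zeros(Hd + F, 4 * Hd);
  db.zeros(4 * Hd);
  std::vector<arma::Mat<T>> dY(Tn);
  arma::Mat<T> dh_next(N, Hd, arma::fill::zeros), dc(N, Hd, arma::fill::zeros);
  for (int t = Tn - 1; t >= 0; --t) {
    arma::Mat<T> dh = dHs[t] + dh_next;
    const arma::Mat<T>&j = cache.j[t], &k = cache.k[t], &l = cache.l[t],
        &cand = cache.cand[t], &tc = cache.tanh_c[t];
    arma::Mat<T> dl = dh % tc % l % ((T)1 - l);
    dc += dh % l % ((T)1 - arma::square(tc));
    arma::Mat<T> c_prev = t > 0 ? cache.c[t - 1]
                                : arma::Mat<T>(N, Hd, arma::fill::zeros);
    arma::Mat<T> dj = dc % c_prev % j % ((T)1 - j);
    arma::Mat<T> dk = dc % cand % k % ((T)1 - k);
    arma::Mat<T> dcand = dc % k % ((T)1 - arma::square(cand));
    arma::Mat<T> dG = arma::join_rows(arma::join_rows(dj, dk),
                                      arma::join_rows(dl, dcand));
    dW += cache.Z[t].t() * dG;
    db += arma::sum(dG, 0).t();
    arma::Mat<T> dZ = dG * Wm.t();
    dh_next = dZ.cols(0, Hd - 1);
    dY[t] = dZ.cols(Hd, Hd + F - 1);
    dc = dc % j;
  }
  return dY;
}

// ---------------------------------------------------------------------------
// R <-> internal conversion helpers

template <typename T>
static Ten<T> ten_from_r(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  int N, H, W, C;
  if (d.size() == 4) { N = d[0]; H = d[1]; W = d[2]; C = d[3]; }
  else if (d.size() == 3) { N = 1; H = d[0]; W = d[1]; C = d[2]; }
  else stop("expected a 3- or 4-dimensional array");
  Ten<T> t(N, H, W, C);
  const double* p = x.begin();
  T* q = t.m.memptr();
  const arma::uword n = t.m.n_elem;
  for (arma::uword i = 0; i < n; ++i) q[i] = (T)p[i];
  return t;
}

template <typename T>
static NumericVector ten_to_r(const Ten<T>& t, bool batched) {
  NumericVector out(t.m.n_elem);
  const T* q = t.m.memptr();
  for (arma::uword i = 0; i < t.m.n_elem; ++i) out[i] = (double)q[i];
  if (batched)
    out.attr("dim") = IntegerVector::create(t.N, t.H, t.W, t.C);
  else
    out.attr("dim") = IntegerVector::create(t.H, t.W, t.C);
  return out;
}

template <typename T>
static arma::Mat<T> mat_from_r(const NumericVector& x, int nr, int nc) {
  if ((int)x.size() != nr * nc) stop("weight block has unexpected size");
  arma::Mat<T> m(nr, nc, arma::fill::none);
  const double* p = x.begin();
  T* q = m.memptr();
  for (int i = 0; i < nr * nc; ++i) q[i] = (T)p[i];
  return m;
}

template <typename T>
static arma::Col<T> vec_from_r(const NumericVector& x) {
  arma::Col<T> v(x.size(), arma::fill::none);
  for (int i = 0; i < (int)x.size(); ++i) v[i] = (T)x[i];
  return v;
}

static NumericVector mat_to_r(const arma::Mat<float>& m, SEXP dim_like) {
  NumericVector out(m.n_elem);
  const float* q = m.memptr();
  for (arma::uword i = 0; i < m.n_elem; ++i) out[i] = (double)q[i];
  if (dim_like != R_NilValue) out.attr("dim") = dim_like;
  return out;
}

static NumericVector vec_to_r(const arma::Col<float>& v) {
  NumericVector out(v.n_elem);
  for (arma::uword i = 0; i < v.n_elem; ++i) out[i] = (double)v[i];
  return out;
}

// ---------------------------------------------------------------------------
// Exported double-precision layer primitives (module surface of neural_core)

// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim");
  bool batched = xd.size() == 4;
  Ten<double> t = ten_from_r<double>(x);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4) stop("conv2d weights must be a (kh, kw, in, out) array");
  int kh = wd[0], kw = wd[1], cin = wd[2], f = wd[3];
  if (cin != t.C) stop("conv2d: input has %d channels but weights expect %d",
                       t.C, cin);
  if (kh - (kh - 1) / 2 > t.H + 1 || kw - (kw - 1) / 2 > t.W + 1)
    stop("conv2d: kernel larger than padded input");
  arma::Mat<double> Wm = mat_from_r<double>(w, kh * kw * cin, f);
  arma::Col<double> bv = vec_from_r<double>(b);
  Ten<double> out = conv_fwd(t, Wm, bv, kh, kw);
  return ten_to_r(out, batched);
}

// [[Rcpp::export]]
NumericVector cpp_max_pool(NumericVector x, int ph, int pw) {
  IntegerVector xd = x.attr("dim");
  bool batched = xd.size() == 4;
  Ten<double> t = ten_from_r<double>(x);
  Ten<double> out = pool_fwd<double>(t, ph, pw, nullptr);
  return ten_to_r(out, batched);
}

// [[Rcpp::export]]
NumericVector cpp_upsample(NumericVector x, int fh, int fw) {
  IntegerVector xd = x.attr("dim");
  bool batched = xd.size() == 4;
  Ten<double> t = ten_from_r<double>(x);
  Ten<double> out = upsample_fwd<double>(t, fh, fw);
  return ten_to_r(out, batched);
}

// ---------------------------------------------------------------------------
// Model engine (single precision)
//
// Parameter list layout (flat named list of R arrays/vectors):
//   ec<i>_W (3,2,cin,f), ec<i>_b, bn<i>_gamma/beta/mean/var   i = 1..4
//   dc<i>_W, dc<i>_b                                          i = 1..4 (DCAE)
//   MLP head:    fc1_W, fc1_b, fc2_W, fc2_b, fc3_W, fc3_b
//   BiLSTM head: lstm_fw_W, lstm_fw_b, lstm_bw_W, lstm_bw_b, out_W, out_b

struct EncCache {
  Ten<float> in[4];  // input of each conv stage (moved in, not copied)
  BNCache<float> bn[4];
  arma::Mat<arma::s32> argmax[4];
  int act_dims[4][3];  // H, W, C of the conv/BN activation grid
};

struct ConvPar {
  arma::Mat<float> W;
  arma::Col<float> b;
  int kh, kw, cin, f;
};

static ConvPar get_conv(const List& params, const std::string& name) {
  NumericVector w = params[name + "_W"];
  NumericVector b = params[name + "_b"];
  IntegerVector wd = w.attr("dim");
  ConvPar cp;
  cp.kh = wd[0]; cp.kw = wd[1]; cp.cin = wd[2]; cp.f = wd[3];
  cp.W = mat_from_r<float>(w, cp.kh * cp.kw * cp.cin, cp.f);
  cp.b = vec_from_r<float>(b);
  return cp;
}

// Encoder forward; latent left in `x`.  In train mode the stage inputs are
// moved into the cache and the ReLU mask is later recovered from the batch
// norm's xhat (the value 0 maps exactly to -mean * invstd).
static void encoder_fwd(Ten<float>& x, const List& params, const List& spec,
                        bool train, EncCache* cache) {
  IntegerVector ph = spec["pool_h"], pw = spec["pool_w"];
  const float eps = (float)Rcpp::as<double>(spec["bn_eps"]);
  for (int i = 0; i < 4; ++i) {
    std::string ec = "ec" + std::to_string(i + 1);
    std::string bn = "bn" + std::to_string(i + 1);
    ConvPar cp = get_conv(params, ec);
    Ten<float> z;
    if (cache) {
      cache->in[i] = std::move(x);
      z = conv_fwd(cache->in[i], cp.W, cp.b, cp.kh, cp.kw, 1);
    } else {
      z = conv_fwd(x, cp.W, cp.b, cp.kh, cp.kw, 1);
    }
    arma::Col<float> gamma = vec_from_r<float>(params[bn + "_gamma"]);
    arma::Col<float> beta = vec_from_r<float>(params[bn + "_beta"]);
    if (train) {
      bn_train_fwd(z, gamma, beta, eps, cache->bn[i]);
      cache->act_dims[i][0] = z.H; cache->act_dims[i][1] = z.W;
      cache->act_dims[i][2] = z.C;
    } else {
      arma::Col<float> rmean = vec_from_r<float>(params[bn + "_mean"]);
      arma::Col<float> rvar = vec_from_r<float>(params[bn + "_var"]);
      bn_infer_fwd(z, gamma, beta, rmean, rvar, eps);
    }
    x = pool_fwd<float>(z, ph[i], pw[i], cache ? &cache->argmax[i] : nullptr);
  }
}

struct DecCache {
  Ten<float> in[4];   // input of each conv stage (moved)
  Ten<float> act[4];  // activation output before upsample (moved)
  int up_dims[2];     // H, W after final upsample (before crop)
};

// Decoder forward: four (conv -> activation -> upsample) stages, final output
// cropped back to the input grid (trailing rows/columns dropped).
static Ten<float> decoder_fwd(const Ten<float>& latent, const List& params,
                              const List& spec, int Hout, int Wout,
                              DecCache* cache) {
  IntegerVector fh = spec["up_h"], fw = spec["up_w"];
  Ten<float> x = latent;
  for (int i = 0; i < 4; ++i) {
    ConvPar cp = get_conv(params, "dc" + std::to_string(i + 1));
    Ten<float> z = conv_fwd(x, cp.W, cp.b, cp.kh, cp.kw, i < 3 ? 1 : 2);
    if (cache) cache->in[i] = std::move(x);
    x = upsample_fwd(z, fh[i], fw[i]);
    if (cache) cache->act[i] = std::move(z);
  }
  if (cache) { cache->up_dims[0] = x.H; cache->up_dims[1] = x.W; }
  if (x.H < Hout || x.W < Wout)
    stop("decoder output (%dx%d) smaller than input grid (%dx%d)",
         x.H, x.W, Hout, Wout);
  Ten<float> out(x.N, Hout, Wout, x.C);
  for (int c = 0; c < x.C; ++c)
    for (int w = 0; w < Wout; ++w)
      std::memcpy(out.col(c) + out.sp(0, w), x.col(c) + x.sp(0, w),
                  (size_t)x.N * Hout * sizeof(float));
  return out;
}

struct HeadCache {
  // MLP
  arma::Mat<float> h1, h2;
  // BiLSTM
  std::vector<arma::Mat<float>> Y;
  LSTMCache<float> fw, bw;
  std::vector<arma::Mat<float>> hf, hb;
  arma::Mat<float> hbar;
  arma::Mat<float> dropmask;
  // shared
  arma::Mat<float> prob;  // N x 1, sigmoid output
};

// Latent sequence: time axis is the sequence axis, trailing (W x C) axes
// flatten to the per-step feature vector.
static std::vector<arma::Mat<float>> latent_to_seq(const Ten<float>& latent) {
  const int N = latent.N, Tn = latent.H, F = latent.W * latent.C;
  std::vector<arma::Mat<float>> Y(Tn);
  for (int t = 0; t < Tn; ++t) {
    arma::Mat<float> yt(N, F, arma::fill::none);
    for (int f = 0; f < F; ++f) {
      const int w = f % latent.W, c = f / latent.W;
      std::memcpy(yt.colptr(f), latent.col(c) + latent.sp(t, w),
                  N * sizeof(float));
    }
    Y[t] = std::move(yt);
  }
  return Y;
}

static arma::Mat<float> head_fwd(const Ten<float>& latent, const List& params,
                                 const std::string& head, double dropout,
                                 bool train, int drop_seed, HeadCache* cache) {
  const int N = latent.N;
  arma::Mat<float> logit;
  if (head == "mlp") {
    arma::Mat<float> flat(const_cast<float*>(latent.m.memptr()), N,
                          latent.H * latent.W * latent.C, false, true);
    arma::Mat<float> W1 = mat_from_r<float>(
        params["fc1_W"], flat.n_cols,
        ((NumericVector)params["fc1_b"]).size());
    arma::Mat<float> h1 = flat * W1;
    h1.each_row() += vec_from_r<float>(params["fc1_b"]).t();
    relu_inplace(h1);
    arma::Mat<float> W2 = mat_from_r<float>(
        params["fc2_W"], h1.n_cols, ((NumericVector)params["fc2_b"]).size());
    arma::Mat<float> h2 = h1 * W2;
    h2.each_row() += vec_from_r<float>(params["fc2_b"]).t();
    relu_inplace(h2);
    arma::Mat<float> W3 = mat_from_r<float>(params["fc3_W"], h2.n_cols, 1);
    logit = h2 * W3 + (float)Rcpp::as<NumericVector>(params["fc3_b"])[0];
    if (cache) { cache->h1 = std::move(h1); cache->h2 = std::move(h2); }
  } else {
    std::vector<arma::Mat<float>> Y = latent_to_seq(latent);
    const int Tn = (int)Y.size();
    const int F = (int)Y[0].n_cols;
    const int Hd = ((NumericVector)params["lstm_fw_b"]).size() / 4;
    arma::Mat<float> Wf = mat_from_r<float>(params["lstm_fw_W"], F + Hd, 4 * Hd);
    arma::Col<float> bf = vec_from_r<float>(params["lstm_fw_b"]);
    arma::Mat<float> Wb = mat_from_r<float>(params["lstm_bw_W"], F + Hd, 4 * Hd);
    arma::Col<float> bb = vec_from_r<float>(params["lstm_bw_b"]);
    std::vector<arma::Mat<float>> hf =
        lstm_fwd(Y, Wf, bf, Hd, cache ? &cache->fw : nullptr);
    std::vector<arma::Mat<float>> Yr(Tn);
    for (int t = 0; t < Tn; ++t) Yr[t] = Y[Tn - 1 - t];
    std::vector<arma::Mat<float>> hbr =
        lstm_fwd(Yr, Wb, bb, Hd, cache ? &cache->bw : nullptr);
    // hbr[t] corresponds to original step Tn-1-t
    arma::Mat<float> hbar(N, 2 * Hd, arma::fill::zeros);
    for (int t = 0; t < Tn; ++t) {
      hbar.cols(0, Hd - 1) += hf[t];
      hbar.cols(Hd, 2 * Hd - 1) += hbr[Tn - 1 - t];
    }
    hbar /= (float)Tn;
    if (dropout > 0 && train) {
      std::mt19937 rng((unsigned)drop_seed);
      std::bernoulli_distribution keep(1.0 - dropout);
      arma::Mat<float> mask(N, 2 * Hd);
      for (arma::uword i = 0; i < mask.n_elem; ++i)
        mask[i] = keep(rng) ? (float)(1.0 / (1.0 - dropout)) : 0.0f;
      hbar %= mask;
      if (cache) cache->dropmask = std::move(mask);
    }
    arma::Mat<float> Wo = mat_from_r<float>(params["out_W"], 2 * Hd, 1);
    logit = hbar * Wo + (float)Rcpp::as<NumericVector>(params["out_b"])[0];
    if (cache) {
      cache->Y = std::move(Y); cache->hf = std::move(hf);
      cache->hb = std::move(hbr); cache->hbar = std::move(hbar);
    }
  }
  sigmoid_inplace(logit);
  if (cache) cache->prob = logit;
  return logit;
}

// [[Rcpp::export]]
List cpp_model_forward(NumericVector x, List params, List spec,
                       bool return_recon = true) {
  Ten<float> t = ten_from_r<float>(x);
  const int Hin = t.H, Win = t.W;
  const bool has_decoder = Rcpp::as<bool>(spec["has_decoder"]);
  const std::string head = Rcpp::as<std::string>(spec["head"]);
  encoder_fwd(t, params, spec, false, nullptr);
  List out;
  out["latent_dim"] = IntegerVector::create(t.H, t.W, t.C);
  arma::Mat<float> prob = head_fwd(t, params, head, 0.0, false, 0, nullptr);
  out["prob"] = vec_to_r(prob.col(0));
  if (has_decoder && return_recon) {
    Ten<float> recon = decoder_fwd(t, params, spec, Hin, Win, nullptr);
    out["recon"] = ten_to_r(recon, true);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_model_latent(NumericVector x, List params, List spec) {
  Ten<float> t = ten_from_r<float>(x);
  encoder_fwd(t, params, spec, false, nullptr);
  return List::create(Named("latent") = ten_to_r(t, true));
}

// Full training step gradient: forward (train-mode batch norm), loss, and
// backward through head, decoder and encoder.  Returns gradients for every
// trainable block, the updated running statistics, the loss components and
// the batch's predicted probabilities.
// [[Rcpp::export]]
List cpp_model_grad(NumericVector x, NumericVector labels, List params,
                    List spec) {
  Ten<float> t = ten_from_r<float>(x);
  const int N = t.N, Hin = t.H, Win = t.W;
  const bool has_decoder = Rcpp::as<bool>(spec["has_decoder"]);
  const std::string head = Rcpp::as<std::string>(spec["head"]);
  const float wcl = (float)Rcpp::as<double>(spec["weight_cl"]);
  const float wrlc = (float)Rcpp::as<double>(spec["weight_rlc"]);
  const double dropout = Rcpp::as<double>(spec["dropout"]);
  const int drop_seed = Rcpp::as<int>(spec["drop_seed"]);
  const float bn_mom = (float)Rcpp::as<double>(spec["bn_momentum"]);
  if ((int)labels.size() != N) stop("labels do not match batch size");

  EncCache enc;
  encoder_fwd(t, params, spec, true, &enc);
  Ten<float> latent = std::move(t);

  HeadCache hc;
  arma::Mat<float> prob = head_fwd(latent, params, head, dropout, true,
                                   drop_seed, &hc);

  // --- losses ---------------------------------------------------------------
  const float clamp = 1e-7f;
  double cl = 0.0;
  arma::Mat<float> dlogit(N, 1);
  for (int n = 0; n < N; ++n) {
    float p = prob(n, 0);
    float pc = std::min(1.0f - clamp, std::max(clamp, p));
    float y = (float)labels[n];
    cl -= y * std::log((double)pc) + (1.0 - y) * std::log(1.0 - (double)pc);
    dlogit(n, 0) = (p > clamp && p < 1.0f - clamp) ? (p - y) / (float)N : 0.0f;
  }
  cl /= N;

  List grads;
  double rcl = NA_REAL, tl;
  DecCache dec;
  Ten<float> dlatent_dec;
  if (has_decoder) {
    const Ten<float>& x_orig = enc.in[0];  // the untouched input batch
    Ten<float> recon = decoder_fwd(latent, params, spec, Hin, Win, &dec);
    const float qr = (float)(Hin * Win * recon.C);
    // dRC/drecon (scaled by the reconstruction weight), fused with the loss
    const double mse_scale = 1.0 / ((double)N * qr);
    double acc = 0;
    {
      float* r = recon.m.memptr();
      const float* o = x_orig.m.memptr();
      const float k = 2.0f * wrlc / ((float)N * qr);
      const arma::uword n_el = recon.m.n_elem;
      for (arma::uword i = 0; i < n_el; ++i) {
        const float d_ = r[i] - o[i];
        acc += (double)d_ * d_;
        r[i] = k * d_;  // recon now holds the gradient
      }
    }
    rcl = acc * mse_scale;
    tl = wcl * cl + wrlc * rcl;
    // pad crop back to the final upsample grid
    IntegerVector fh = spec["up_h"], fw = spec["up_w"];
    Ten<float> dup(N, dec.up_dims[0], dec.up_dims[1], recon.C);
    dup.m.zeros();
    for (int c = 0; c < recon.C; ++c)
      for (int w = 0; w < Win; ++w)
        std::memcpy(dup.col(c) + dup.sp(0, w), recon.col(c) + recon.sp(0, w),
                    (size_t)N * Hin * sizeof(float));
    Ten<float> d = std::move(dup);
    for (int i = 3; i >= 0; --i) {
      d = upsample_bwd(d, fh[i], fw[i]);
      if (i == 3) sigmoid_mask(d.m, dec.act[i].m);
      else relu_mask(d.m, dec.act[i].m);
      ConvPar cp = get_conv(params, "dc" + std::to_string(i + 1));
      arma::Mat<float> dW;
      arma::Col<float> db;
      Ten<float> dx;
      conv_bwd(dec.in[i], cp.W, cp.kh, cp.kw, d, dW, db, &dx);
      std::string nm = "dc" + std::to_string(i + 1);
      grads[nm + "_W"] = mat_to_r(
          dW, Rcpp::as<NumericVector>(params[nm + "_W"]).attr("dim"));
      grads[nm + "_b"] = vec_to_r(db);
      d = std::move(dx);
    }
    dlatent_dec = std::move(d);
  } else {
    tl = cl;
  }

  // --- head backward --------------------------------------------------------
  // For the joint model the classification branch is weighted by weight_cl;
  // a classifier-only model trains on the plain cross-entropy.
  arma::Mat<float> dlg = dlogit * (has_decoder ? wcl : 1.0f);
  Ten<float> dlatent_head(latent.N, latent.H, latent.W, latent.C);
  dlatent_head.m.zeros();
  if (head == "mlp") {
    arma::Mat<float> W3 = mat_from_r<float>(params["fc3_W"], hc.h2.n_cols, 1);
    arma::Mat<float> dh2 = dlg * W3.t();
    relu_mask(dh2, hc.h2);
    grads["fc3_W"] = mat_to_r(
        hc.h2.t() * dlg, Rcpp::as<NumericVector>(params["fc3_W"]).attr("dim"));
    grads["fc3_b"] = vec_to_r(arma::Col<float>(arma::sum(dlg, 0).t()));
    arma::Mat<float> W2 = mat_from_r<float>(params["fc2_W"], hc.h1.n_cols,
                                            hc.h2.n_cols);
    arma::Mat<float> dh1 = dh2 * W2.t();
    relu_mask(dh1, hc.h1);
    grads["fc2_W"] = mat_to_r(
        hc.h1.t() * dh2, Rcpp::as<NumericVector>(params["fc2_W"]).attr("dim"));
    grads["fc2_b"] = vec_to_r(arma::Col<float>(arma::sum(dh2, 0).t()));
    arma::Mat<float> flat(latent.m.memptr(), N,
                          latent.H * latent.W * latent.C, false, true);
    arma::Mat<float> W1 = mat_from_r<float>(params["fc1_W"], flat.n_cols,
                                            hc.h1.n_cols);
    grads["fc1_W"] = mat_to_r(
        flat.t() * dh1, Rcpp::as<NumericVector>(params["fc1_W"]).attr("dim"));
    grads["fc1_b"] = vec_to_r(arma::Col<float>(arma::sum(dh1, 0).t()));
    arma::Mat<float> dflat = dh1 * W1.t();  // N x (H*W*C)
    std::memcpy(dlatent_head.m.memptr(), dflat.memptr(),
                dflat.n_elem * sizeof(float));
  } else {
    const int Tn = latent.H;
    const int Hd = (int)hc.hbar.n_cols / 2;
    arma::Mat<float> Wo = mat_from_r<float>(params["out_W"], 2 * Hd, 1);
    grads["out_W"] = mat_to_r(
        hc.hbar.t() * dlg, Rcpp::as<NumericVector>(params["out_W"]).attr("dim"));
    grads["out_b"] = vec_to_r(arma::Col<float>(arma::sum(dlg, 0).t()));
    arma::Mat<float> dhbar = dlg * Wo.t();
    if (hc.dropmask.n_elem > 0) dhbar %= hc.dropmask;
    dhbar /= (float)Tn;
    std::vector<arma::Mat<float>> dHf(Tn), dHb(Tn);
    for (int t_ = 0; t_ < Tn; ++t_) {
      dHf[t_] = dhbar.cols(0, Hd - 1);
      dHb[Tn - 1 - t_] = dhbar.cols(Hd, 2 * Hd - 1);
    }
    arma::Mat<float> Wf = mat_from_r<float>(params["lstm_fw_W"],
                                            hc.Y[0].n_cols + Hd, 4 * Hd);
    arma::Mat<float> Wb = mat_from_r<float>(params["lstm_bw_W"],
                                            hc.Y[0].n_cols + Hd, 4 * Hd);
    arma::Mat<float> dWf, dWb;
    arma::Col<float> dbf, dbb;
    std::vector<arma::Mat<float>> dYf = lstm_bwd(dHf, Wf, Hd, hc.fw, dWf, dbf);
    std::vector<arma::Mat<float>> dYb = lstm_bwd(dHb, Wb, Hd, hc.bw, dWb, dbb);
    grads["lstm_fw_W"] = mat_to_r(
        dWf, Rcpp::as<NumericVector>(params["lstm_fw_W"]).attr("dim"));
    grads["lstm_fw_b"] = vec_to_r(dbf);
    grads["lstm_bw_W"] = mat_to_r(
        dWb, Rcpp::as<NumericVector>(params["lstm_bw_W"]).attr("dim"));
    grads["lstm_bw_b"] = vec_to_r(dbb);
    // scatter per-step input gradients back onto the latent tensor
    const int F = (int)hc.Y[0].n_cols;
    for (int t_ = 0; t_ < Tn; ++t_) {
      arma::Mat<float> dY = dYf[t_] + dYb[Tn - 1 - t_];
      for (int f = 0; f < F; ++f) {
        const int w = f % latent.W, c = f / latent.W;
        float* dst = dlatent_head.col(c) + dlatent_head.sp(t_, w);
        const float* s = dY.colptr(f);
        for (int n = 0; n < N; ++n) dst[n] += s[n];
      }
    }
  }

  // --- encoder backward -----------------------------------------------------
  Ten<float> d = std::move(dlatent_head);
  if (has_decoder) d.m += dlatent_dec.m;
  IntegerVector ph = spec["pool_h"], pw = spec["pool_w"];
  List bn_updates;
  for (int i = 3; i >= 0; --i) {
    std::string ec = "ec" + std::to_string(i + 1);
    std::string bn = "bn" + std::to_string(i + 1);
    // pool backward
    Ten<float> dz = pool_bwd(d, enc.argmax[i], N, enc.act_dims[i][0],
                             enc.act_dims[i][1], enc.act_dims[i][2]);
    // batch norm + ReLU backward (fused, in place over dz)
    arma::Col<float> gamma = vec_from_r<float>(params[bn + "_gamma"]);
    arma::Col<float> dgamma, dbeta;
    bn_bwd_inplace(dz.m, gamma, enc.bn[i], dgamma, dbeta, true);
    grads[bn + "_gamma"] = vec_to_r(dgamma);
    grads[bn + "_beta"] = vec_to_r(dbeta);
    // running statistics update
    arma::Col<float> rmean = vec_from_r<float>(params[bn + "_mean"]);
    arma::Col<float> rvar = vec_from_r<float>(params[bn + "_var"]);
    rmean = bn_mom * rmean + (1.0f - bn_mom) * enc.bn[i].mean;
    rvar = bn_mom * rvar + (1.0f - bn_mom) * enc.bn[i].var;
    bn_updates[bn + "_mean"] = vec_to_r(rmean);
    bn_updates[bn + "_var"] = vec_to_r(rvar);
    // conv backward
    ConvPar cp = get_conv(params, ec);
    arma::Mat<float> dW;
    arma::Col<float> db;
    Ten<float> dx;
    conv_bwd(enc.in[i], cp.W, cp.kh, cp.kw, dz, dW, db, i > 0 ? &dx : nullptr);
    grads[ec + "_W"] = mat_to_r(
        dW, Rcpp::as<NumericVector>(params[ec + "_W"]).attr("dim"));
    grads[ec + "_b"] = vec_to_r(db);
    if (i > 0) d = std::move(dx);
  }

  return List::create(
      Named("grads") = grads, Named("bn_updates") = bn_updates,
      Named("cl") = cl, Named("rcl") = rcl, Named("tl") = tl,
      Named("prob") = vec_to_r(prob.col(0)));
}
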