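#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
#include <vector>
using namespace Rcpp;

// Tensors are R arrays with dim c(N, C, H, W), column-major, so the batch
// index varies fastest.  All convolutions are cross-correlations (deep
// learning convention) with square kernels, implemented as im2col + GEMM.

static inline int out_size(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// Patch matrix P: (N*Ho*Wo) x (Ci*k*k), column-major.
// P[n + N*(io + Ho*jo), ci + Ci*(u + k*v)] = x[n, ci, io*s-p+u, jo*s-p+v] (0 outside).
static void im2col(const double *px, int N, int Ci, int H, int W,
                   int kh, int kw, int s, int p, int Ho, int Wo, double *P) {
  const size_t rows = (size_t)N * Ho * Wo;
  std::fill(P, P + rows * (size_t)Ci * kh * kw, 0.0);
  for (int v = 0; v < kw; ++v) {
    for (int u = 0; u < kh; ++u) {
      for (int ci = 0; ci < Ci; ++ci) {
        double *Pc = P + rows * (ci + (size_t)Ci * (u + (size_t)kh * v));
        for (int jo = 0; jo < Wo; ++jo) {
          int jx = jo * s - p + v;
          if (jx < 0 || jx >= W) continue;
          for (int io = 0; io < Ho; ++io) {
            int ix = io * s - p + u;
            if (ix < 0 || ix >= H) continue;
            const double *src = px + (size_t)N * (ci + (size_t)Ci * (ix + (size_t)H * jx));
            double *dst = Pc + (size_t)N * (io + (size_t)Ho * jo);
            for (int n = 0; n < N; ++n) dst[n] = src[n];
          }
        }
      }
    }
  }
}

// Adjoint of im2col: accumulate the patch matrix back into the image.
static void col2im(const double *P, int N, int Ci, int H, int W,
                   int kh, int kw, int s, int p, int Ho, int Wo, double *px) {
  const size_t rows = (size_t)N * Ho * Wo;
  std::fill(px, px + (size_t)N * Ci * H * W, 0.0);
  for (int v = 0; v < kw; ++v) {
    for (int u = 0; u < kh; ++u) {
      for (int ci = 0; ci < Ci; ++ci) {
        const double *Pc = P + rows * (ci + (size_t)Ci * (u + (size_t)kh * v));
        for (int jo = 0; jo < Wo; ++jo) {
          int jx = jo * s - p + v;
          if (jx < 0 || jx >= W) continue;
          for (int io = 0; io < Ho; ++io) {
            int ix = io * s - p + u;
            if (ix < 0 || ix >= H) continue;
            double *dst = px + (size_t)N * (ci + (size_t)Ci * (ix + (size_t)H * jx));
            const double *src = Pc + (size_t)N * (io + (size_t)Ho * jo);
            for (int n = 0; n < N; ++n) dst[n] += src[n];
          }
        }
      }
    }
  }
}

// Reshape weights [Co, Ci, k, k] -> Wm (Ci*k*k) x Co, column-major.
static void weight_mat(const double *pw, int Co, int Ci, int kh, int kw, double *Wm) {
  const size_t rows = (size_t)Ci * kh * kw;
  for (int co = 0; co < Co; ++co)
    for (size_t r = 0; r < rows; ++r)
      Wm[r + rows * co] = pw[co + (size_t)Co * r];
}

static void gemm(char ta, char tb, int m, int n, int kk,
                 const double *A, int lda, const double *B, int ldb,
                 double beta, double *C, int ldc) {
  const double one = 1.0;
  F77_CALL(dgemm)(&ta, &tb, &m, &n, &kk, &one, A, &lda, B, &ldb,
                  &beta, C, &ldc FCONE FCONE);
}

// Forward convolution.
// x: [N, Cin, H, W], w: [Cout, Cin, k, k], b: [Cout] (may be length 0).
// [[Rcpp::export]]
NumericVector conv_fwd(NumericVector x, NumericVector w, NumericVector b,
                       int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int N = xd[0], Ci = xd[1], H = xd[2], W = xd[3];
  const int Co = wd[0], kh = wd[2], kw = wd[3];
  if (wd[1] != Ci) stop("channel mismatch in conv_fwd");
  const int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  if (Ho < 1 || Wo < 1) stop("input too small for kernel");
  const size_t rows = (size_t)N * Ho * Wo, cols = (size_t)Ci * kh * kw;
  std::vector<double> P(rows * cols), Wm(cols * Co), O(rows * Co);
  im2col(x.begin(), N, Ci, H, W, kh, kw, stride, pad, Ho, Wo, P.data());
  weight_mat(w.begin(), Co, Ci, kh, kw, Wm.data());
  gemm('N', 'N', (int)rows, Co, (int)cols, P.data(), (int)rows,
       Wm.data(), (int)cols, 0.0, O.data(), (int)rows);
  NumericVector out(rows * Co);
  out.attr("dim") = IntegerVector::create(N, Co, Ho, Wo);
  double *po = out.begin();
  const bool has_b = b.size() > 0;
  for (int jo = 0; jo < Wo; ++jo)
    for (int io = 0; io < Ho; ++io)
      for (int co = 0; co < Co; ++co) {
        const double *src = O.data() + (size_t)N * (io + (size_t)Ho * jo) + rows * co;
        double *dst = po + (size_t)N * (co + (size_t)Co * (io + (size_t)Ho * jo));
        double bias = has_b ? b[co] : 0.0;
        for (int n = 0; n < N; ++n) dst[n] = src[n] + bias;
      }
  return out;
}

// Gradient of conv_fwd w.r.t. its input; equivalently the forward pass of a
// transposed convolution (g as input, w stored [Cg, Cr, k, k]).
// g: [N, Cg, Hg, Wg] -> result [N, Cr, H, W].
// [[Rcpp::export]]
NumericVector conv_grad_input(NumericVector g, NumericVector w,
                              int stride, int pad, int H, int W) {
  IntegerVector gd = g.attr("dim"), wd = w.attr("dim");
  const int N = gd[0], Cg = gd[1], Hg = gd[2], Wg = gd[3];
  const int Cr = wd[1], kh = wd[2], kw = wd[3];
  if (wd[0] != Cg) stop("channel mismatch in conv_grad_input");
  const size_t rows = (size_t)N * Hg * Wg, cols = (size_t)Cr * kh * kw;
  // gather g into G: rows x Cg
  std::vector<double> G(rows * Cg), Wm(cols * Cg), P(rows * cols);
  const double *pg = g.begin();
  for (int jo = 0; jo < Wg; ++jo)
    for (int io = 0; io < Hg; ++io)
      for (int cg = 0; cg < Cg; ++cg) {
        const double *src = pg + (size_t)N * (cg + (size_t)Cg * (io + (size_t)Hg * jo));
        double *dst = G.data() + (size_t)N * (io + (size_t)Hg * jo) + rows * cg;
        for (int n = 0; n < N; ++n) dst[n] = src[n];
      }
  weight_mat(w.begin(), Cg, Cr, kh, kw, Wm.data());   // (Cr*kh*kw) x Cg
  // P = G %*% Wm^T : rows x (Cr*k*k)
  gemm('N', 'T', (int)rows, (int)cols, Cg, G.data(), (int)rows,
       Wm.data(), (int)cols, 0.0, P.data(), (int)rows);
  NumericVector out((size_t)N * Cr * H * W);
  out.attr("dim") = IntegerVector::create(N, Cr, H, W);
  col2im(P.data(), N, Cr, H, W, kh, kw, stride, pad, Hg, Wg, out.begin());
  return out;
}

// Gradient of conv_fwd w.r.t. weights and bias.
// x: [N, Ci, H, W], g: [N, Co, Ho, Wo] -> gw [Co, Ci, k, k], gb [Co].
// [[Rcpp::export]]
List conv_grad_wb(NumericVector x, NumericVector g, int kh, int kw,
                  int stride, int pad) {
  IntegerVector xd = x.attr("dim"), gd = g.attr("dim");
  const int N = xd[0], Ci = xd[1], H = xd[2], W = xd[3];
  const int Co = gd[1], Ho = gd[2], Wo = gd[3];
  const size_t rows = (size_t)N * Ho * Wo, cols = (size_t)Ci * kh * kw;
  std::vector<double> P(rows * cols), G(rows * Co), GW(cols * Co);
  im2col(x.begin(), N, Ci, H, W, kh, kw, stride, pad, Ho, Wo, P.data());
  NumericVector gb(Co);
  const double *pg = g.begin();
  for (int jo = 0; jo < Wo; ++jo)
    for (int io = 0; io < Ho; ++io)
      for (int co = 0; co < Co; ++co) {
        const double *src = pg + (size_t)N * (co + (size_t)Co * (io + (size_t)Ho * jo));
        double *dst = G.data() + (size_t)N * (io + (size_t)Ho * jo) + rows * co;
        double acc = 0.0;
        for (int n = 0; n < N; ++n) { dst[n] = src[n]; acc += src[n]; }
        gb[co] += acc;
      }
  // GW = P^T %*% G : (Ci*k*k) x Co
  gemm('T', 'N', (int)cols, Co, (int)rows, P.data(), (int)rows,
       G.data(), (int)rows, 0.0, GW.data(), (int)cols);
  NumericVector gw((size_t)Co * Ci * kh * kw);
  gw.attr("dim") = IntegerVector::create(Co, Ci, kh, kw);
  double *pw = gw.begin();
  for (int co = 0; co < Co; ++co)
    for (size_t r = 0; r < cols; ++r)
      pw[co + (size_t)Co * r] = GW[r + cols * co];
  return List::create(_["gw"] = gw, _["gb"] = gb);
}

// Fused RMSprop update for one parameter array:
// v <- alpha v + (1-alpha) g^2 ;  p <- p - lr g / (sqrt(v) + eps).
// [[Rcpp::export]]
List rmsprop_kernel(NumericVector p, NumericVector g, NumericVector v,
                    double lr, double alpha, double eps) {
  R_xlen_t n = p.size();
  NumericVector p2(n), v2(n);
  const bool has_v = v.size() == n;
  for (R_xlen_t i = 0; i < n; ++i) {
    double vi = has_v ? v[i] : 0.0;
    vi = alpha * vi + (1.0 - alpha) * g[i] * g[i];
    v2[i] = vi;
    p2[i] = p[i] - lr * g[i] / (std::sqrt(vi) + eps);
  }
  p2.attr("dim") = p.attr("dim");
  return List::create(_["p"] = p2, _["v"] = v2);
}
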