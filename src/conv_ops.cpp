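#include <Rcpp.h>
using namespace Rcpp;

// Activations are stored channel-fastest: a 4-d tensor (C, H, W, N) flattened
// column-major. im2col unrolls k x k receptive fields so that convolution
// becomes one matrix product with the (C*kh*kw) x Cout weight matrix whose
// rows are ordered channel-fastest, then kernel row, then kernel column.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int C, int H, int W, int N,
                         int kh, int kw, int stride, int pad) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int rows = C * kh * kw;
  NumericMatrix out(rows, Ho * Wo * N);
  double* po = out.begin();
  const double* px = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int jo = 0; jo < Wo; ++jo) {
      for (int io = 0; io < Ho; ++io) {
        const long col = (long)n * Wo * Ho + (long)jo * Ho + io;
        double* dst = po + col * rows;
        int r = 0;
        for (int j = 0; j < kw; ++j) {
          const int wj = jo * stride - pad + j;
          for (int i = 0; i < kh; ++i) {
            const int hi = io * stride - pad + i;
            if (hi >= 0 && hi < H && wj >= 0 && wj < W) {
              const double* src = px + ((long)((n * W + wj) * H + hi)) * C;
              for (int c = 0; c < C; ++c) dst[r + c] = src[c];
            } else {
              for (int c = 0; c < C; ++c) dst[r + c] = 0.0;
            }
            r += C;
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int C, int H, int W, int N,
                         int kh, int kw, int stride, int pad) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int rows = C * kh * kw;
  NumericVector x((long)C * H * W * N);
  double* px = x.begin();
  const double* pc = cols.begin();
  for (int n = 0; n < N; ++n) {
    for (int jo = 0; jo < Wo; ++jo) {
      for (int io = 0; io < Ho; ++io) {
        const long col = (long)n * Wo * Ho + (long)jo * Ho + io;
        const double* src = pc + col * rows;
        int r = 0;
        for (int j = 0; j < kw; ++j) {
          const int wj = jo * stride - pad + j;
          for (int i = 0; i < kh; ++i) {
            const int hi = io * stride - pad + i;
            if (hi >= 0 && hi < H && wj >= 0 && wj < W) {
              double* dst = px + ((long)((n * W + wj) * H + hi)) * C;
              for (int c = 0; c < C; ++c) dst[c] += src[r + c];
            }
            r += C;
          }
        }
      }
    }
  }
  return x;
}

// Group normalization, channel-fastest layout (C, H*W, N). Two-pass moments
// per (group, sample); backward recomputes xhat from x to avoid caching it.

// [[Rcpp::export]]
List gn_fwd_cpp(NumericVector x, int C, int HW, int N, int G,
                NumericVector gamma, NumericVector beta, double eps) {
  const int Cg = C / G;
  const long m = (long)Cg * HW;
  NumericVector y(x.size());
  NumericMatrix mu(G, N), istd(G, N);
  const double* px = x.begin();
  double* py = y.begin();
  for (int n = 0; n < N; ++n) {
    const double* xs = px + (long)n * C * HW;
    for (int g = 0; g < G; ++g) {
      double s = 0, ss = 0;
      for (int hw = 0; hw < HW; ++hw) {
        const double* p = xs + (long)hw * C + g * Cg;
        for (int c = 0; c < Cg; ++c) { s += p[c]; ss += p[c] * p[c]; }
      }
      const double mean = s / m;
      const double var = ss / m - mean * mean;
      mu(g, n) = mean;
      istd(g, n) = 1.0 / std::sqrt(var + eps);
    }
    double* ys = py + (long)n * C * HW;
    for (int hw = 0; hw < HW; ++hw) {
      const double* p = xs + (long)hw * C;
      double* q = ys + (long)hw * C;
      for (int c = 0; c < C; ++c) {
        const int g = c / Cg;
        q[c] = gamma[c] * ((p[c] - mu(g, n)) * istd(g, n)) + beta[c];
      }
    }
  }
  return List::create(_["y"] = y, _["mu"] = mu, _["istd"] = istd);
}

// [[Rcpp::export]]
List gn_bwd_cpp(NumericVector x, NumericVector dy, int C, int HW, int N,
                int G, NumericVector gamma, NumericMatrix mu,
                NumericMatrix istd) {
  const int Cg = C / G;
  const long m = (long)Cg * HW;
  NumericVector dx(x.size());
  NumericVector dgamma(C), dbeta(C);
  const double* px = x.begin();
  const double* pdy = dy.begin();
  double* pdx = dx.begin();
  std::vector<double> s1(G), s2(G);
  for (int n = 0; n < N; ++n) {
    const double* xs = px + (long)n * C * HW;
    const double* ds = pdy + (long)n * C * HW;
    double* os = pdx + (long)n * C * HW;
    std::fill(s1.begin(), s1.end(), 0.0);
    std::fill(s2.begin(), s2.end(), 0.0);
    for (int hw = 0; hw < HW; ++hw) {
      const double* p = xs + (long)hw * C;
      const double* d = ds + (long)hw * C;
      for (int c = 0; c < C; ++c) {
        const int g = c / Cg;
        const double xhat = (p[c] - mu(g, n)) * istd(g, n);
        const double dxh = d[c] * gamma[c];
        s1[g] += dxh;
        s2[g] += dxh * xhat;
        dgamma[c] += d[c] * xhat;
        dbeta[c] += d[c];
      }
    }
    for (int hw = 0; hw < HW; ++hw) {
      const double* p = xs + (long)hw * C;
      const double* d = ds + (long)hw * C;
      double* o = os + (long)hw * C;
      for (int c = 0; c < C; ++c) {
        const int g = c / Cg;
        const double xhat = (p[c] - mu(g, n)) * istd(g, n);
        const double dxh = d[c] * gamma[c];
        o[c] = istd(g, n) * (dxh - s1[g] / m - xhat * s2[g] / m);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
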