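#include <Rcpp.h>
using namespace Rcpp;

// Feature tensors are stored column-major with dim (C, H, W, B) so that the
// channel axis is contiguous: depthwise taps then read/write C-long runs.
// Depthwise 3x3 kernels are stored as a C x 9 matrix, tap index
// t = (dy + 1) + 3 * (dx + 1) with dy, dx in {-1, 0, 1}.

static inline int out_size(int n, int stride) {
  // 3x3, pad 1: floor((n + 2 - 3) / stride) + 1
  return (n - 1) / stride + 1;
}

// [[Rcpp::export(name = ".dw3_fwd")]]
NumericVector dw3_fwd(NumericVector x, NumericVector k, NumericVector bias,
                      int C, int H, int W, int B, int stride) {
  const int Ho = out_size(H, stride), Wo = out_size(W, stride);
  NumericVector y(static_cast<R_xlen_t>(C) * Ho * Wo * B);
  const double *px = x.begin(), *pk = k.begin(), *pb = bias.begin();
  double *py = y.begin();
  for (int b = 0; b < B; ++b) {
    const double *xb = px + static_cast<R_xlen_t>(C) * H * W * b;
    double *yb = py + static_cast<R_xlen_t>(C) * Ho * Wo * b;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double *yo = yb + static_cast<R_xlen_t>(C) * (ho + Ho * wo);
        for (int c = 0; c < C; ++c) yo[c] = pb[c];
        for (int dx = -1; dx <= 1; ++dx) {
          const int wi = wo * stride + dx;
          if (wi < 0 || wi >= W) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            const int hi = ho * stride + dy;
            if (hi < 0 || hi >= H) continue;
            const double *xi = xb + static_cast<R_xlen_t>(C) * (hi + H * wi);
            const double *kt = pk + static_cast<R_xlen_t>(C) * ((dy + 1) + 3 * (dx + 1));
            for (int c = 0; c < C; ++c) yo[c] += kt[c] * xi[c];
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".dw3_bwd")]]
List dw3_bwd(NumericVector x, NumericVector k, NumericVector gy,
             int C, int H, int W, int B, int stride) {
  const int Ho = out_size(H, stride), Wo = out_size(W, stride);
  NumericVector gx(static_cast<R_xlen_t>(C) * H * W * B);
  NumericVector gk(static_cast<R_xlen_t>(C) * 9);
  NumericVector gb(C);
  const double *px = x.begin(), *pk = k.begin(), *pg = gy.begin();
  double *pgx = gx.begin(), *pgk = gk.begin(), *pgb = gb.begin();
  for (int b = 0; b < B; ++b) {
    const double *xb = px + static_cast<R_xlen_t>(C) * H * W * b;
    const double *gb_ = pg + static_cast<R_xlen_t>(C) * Ho * Wo * b;
    double *gxb = pgx + static_cast<R_xlen_t>(C) * H * W * b;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const double *go = gb_ + static_cast<R_xlen_t>(C) * (ho + Ho * wo);
        for (int c = 0; c < C; ++c) pgb[c] += go[c];
        for (int dx = -1; dx <= 1; ++dx) {
          const int wi = wo * stride + dx;
          if (wi < 0 || wi >= W) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            const int hi = ho * stride + dy;
            if (hi < 0 || hi >= H) continue;
            const double *xi = xb + static_cast<R_xlen_t>(C) * (hi + H * wi);
            double *gxi = gxb + static_cast<R_xlen_t>(C) * (hi + H * wi);
            const R_xlen_t toff = static_cast<R_xlen_t>(C) * ((dy + 1) + 3 * (dx + 1));
            const double *kt = pk + toff;
            double *gkt = pgk + toff;
            for (int c = 0; c < C; ++c) {
              gxi[c] += kt[c] * go[c];
              gkt[c] += xi[c] * go[c];
            }
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gk"] = gk, _["gbias"] = gb);
}

#include <R_ext/BLAS.h>

// y = W %*% x with x given as a (C1, N) column-major block (any dim attr)
// [[Rcpp::export(name = ".pw_fwd")]]
NumericVector pw_fwd_c(NumericVector x, NumericMatrix W) {
  const int C2 = W.nrow(), C1 = W.ncol();
  const int N = x.size() / C1;
  NumericVector y(static_cast<R_xlen_t>(C2) * N);
  const double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("N", "N", &C2, &N, &C1, &one, W.begin(), &C2,
                  x.begin(), &C1, &zero, y.begin(), &C2 FCONE FCONE);
  return y;
}

// gx = t(W) %*% gy ; gW = gy %*% t(x)
// [[Rcpp::export(name = ".pw_bwd")]]
List pw_bwd_c(NumericVector x, NumericMatrix W, NumericVector gy) {
  const int C2 = W.nrow(), C1 = W.ncol();
  const int N = x.size() / C1;
  NumericVector gx(static_cast<R_xlen_t>(C1) * N);
  NumericMatrix gW(C2, C1);
  const double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("T", "N", &C1, &N, &C2, &one, W.begin(), &C2,
                  gy.begin(), &C2, &zero, gx.begin(), &C1 FCONE FCONE);
  F77_CALL(dgemm)("N", "T", &C2, &C1, &N, &one, gy.begin(), &C2,
                  x.begin(), &C1, &zero, gW.begin(), &C2 FCONE FCONE);
  return List::create(_["gx"] = gx, _["gW"] = gW);
}

// batch normalization over the channel axis of a (C, N) block
// [[Rcpp::export(name = ".bn_fwd")]]
List bn_fwd_c(NumericVector x, NumericVector g, NumericVector b,
              NumericVector rm, NumericVector rv, bool train,
              double momentum, double eps) {
  const int C = g.size();
  const int N = x.size() / C;
  NumericVector y(x.size()), mu(C), invstd(C);
  NumericVector rm2 = clone(rm), rv2 = clone(rv);
  const double *px = x.begin();
  if (train) {
    std::vector<double> s1(C, 0.0), s2(C, 0.0);
    for (int j = 0; j < N; ++j) {
      const double *xc = px + static_cast<R_xlen_t>(C) * j;
      for (int c = 0; c < C; ++c) { s1[c] += xc[c]; s2[c] += xc[c] * xc[c]; }
    }
    for (int c = 0; c < C; ++c) {
      mu[c] = s1[c] / N;
      double v = s2[c] / N - mu[c] * mu[c];
      if (v < 0) v = 0;
      rm2[c] = (1 - momentum) * rm2[c] + momentum * mu[c];
      rv2[c] = (1 - momentum) * rv2[c] + momentum * v;
      invstd[c] = 1.0 / std::sqrt(v + eps);
    }
  } else {
    for (int c = 0; c < C; ++c) {
      mu[c] = rm[c];
      invstd[c] = 1.0 / std::sqrt(rv[c] + eps);
    }
  }
  double *py = y.begin();
  std::vector<double> sc(C), sb(C);
  for (int c = 0; c < C; ++c) {
    sc[c] = g[c] * invstd[c];
    sb[c] = b[c] - mu[c] * sc[c];
  }
  for (int j = 0; j < N; ++j) {
    const double *xc = px + static_cast<R_xlen_t>(C) * j;
    double *yc = py + static_cast<R_xlen_t>(C) * j;
    for (int c = 0; c < C; ++c) yc[c] = sc[c] * xc[c] + sb[c];
  }
  return List::create(_["y"] = y, _["mu"] = mu, _["invstd"] = invstd,
                      _["rm"] = rm2, _["rv"] = rv2);
}

// [[Rcpp::export(name = ".bn_bwd")]]
List bn_bwd_c(NumericVector x, NumericVector mu, NumericVector invstd,
              NumericVector g, NumericVector gy, bool train) {
  const int C = g.size();
  const int N = x.size() / C;
  NumericVector gx(x.size()), gg(C), gb(C);
  const double *px = x.begin(), *pg = gy.begin();
  std::vector<double> dg(C, 0.0), db(C, 0.0);
  for (int j = 0; j < N; ++j) {
    const double *xc = px + static_cast<R_xlen_t>(C) * j;
    const double *gc = pg + static_cast<R_xlen_t>(C) * j;
    for (int c = 0; c < C; ++c) {
      const double xhat = (xc[c] - mu[c]) * invstd[c];
      dg[c] += gc[c] * xhat;
      db[c] += gc[c];
    }
  }
  for (int c = 0; c < C; ++c) { gg[c] = dg[c]; gb[c] = db[c]; }
  double *pgx = gx.begin();
  if (train) {
    for (int j = 0; j < N; ++j) {
      const double *xc = px + static_cast<R_xlen_t>(C) * j;
      const double *gc = pg + static_cast<R_xlen_t>(C) * j;
      double *gxc = pgx + static_cast<R_xlen_t>(C) * j;
      for (int c = 0; c < C; ++c) {
        const double xhat = (xc[c] - mu[c]) * invstd[c];
        gxc[c] = g[c] * invstd[c] * (gc[c] - db[c] / N - xhat * dg[c] / N);
      }
    }
  } else {
    for (int j = 0; j < N; ++j) {
      const double *gc = pg + static_cast<R_xlen_t>(C) * j;
      double *gxc = pgx + static_cast<R_xlen_t>(C) * j;
      for (int c = 0; c < C; ++c) gxc[c] = g[c] * invstd[c] * gc[c];
    }
  }
  return List::create(_["gx"] = gx, _["gg"] = gg, _["gb"] = gb);
}

// [[Rcpp::export(name = ".relu_fwd")]]
NumericVector relu_fwd_c(NumericVector x) {
  NumericVector y(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) y[i] = x[i] > 0 ? x[i] : 0.0;
  return y;
}

// [[Rcpp::export(name = ".relu_bwd")]]
NumericVector relu_bwd_c(NumericVector y, NumericVector gy) {
  NumericVector gx(y.size());
  for (R_xlen_t i = 0; i < y.size(); ++i) gx[i] = y[i] > 0 ? gy[i] : 0.0;
  return gx;
}

// global average pool over the spatial axes of a (C, n, B) block
// [[Rcpp::export(name = ".gap_fwd")]]
NumericMatrix gap_fwd_c(NumericVector x, int C, int n, int B) {
  NumericMatrix emb(C, B);
  const double *px = x.begin();
  for (int b = 0; b < B; ++b) {
    double *e = emb.begin() + static_cast<R_xlen_t>(C) * b;
    for (int j = 0; j < n; ++j) {
      const double *xc = px + static_cast<R_xlen_t>(C) * (j + n * b);
      for (int c = 0; c < C; ++c) e[c] += xc[c];
    }
    for (int c = 0; c < C; ++c) e[c] /= n;
  }
  return emb;
}

// s = relu(a + b [+ c]) in one pass
// [[Rcpp::export(name = ".add_relu")]]
NumericVector add_relu_c(NumericVector a, NumericVector b,
                         Nullable<NumericVector> c) {
  NumericVector y(a.size());
  if (c.isNotNull()) {
    NumericVector cc(c);
    for (R_xlen_t i = 0; i < a.size(); ++i) {
      double s = a[i] + b[i] + cc[i];
      y[i] = s > 0 ? s : 0.0;
    }
  } else {
    for (R_xlen_t i = 0; i < a.size(); ++i) {
      double s = a[i] + b[i];
      y[i] = s > 0 ? s : 0.0;
    }
  }
  return y;
}

// batchnorm + relu fused forward (train or eval)
// [[Rcpp::export(name = ".bn_relu_fwd")]]
List bn_relu_fwd_c(NumericVector x, NumericVector g, NumericVector b,
                   NumericVector rm, NumericVector rv, bool train,
                   double momentum, double eps) {
  const int C = g.size();
  const int N = x.size() / C;
  NumericVector y(x.size()), mu(C), invstd(C);
  NumericVector rm2 = clone(rm), rv2 = clone(rv);
  const double *px = x.begin();
  if (train) {
    std::vector<double> s1(C, 0.0), s2(C, 0.0);
    for (int j = 0; j < N; ++j) {
      const double *xc = px + static_cast<R_xlen_t>(C) * j;
      for (int c = 0; c < C; ++c) { s1[c] += xc[c]; s2[c] += xc[c] * xc[c]; }
    }
    for (int c = 0; c < C; ++c) {
      mu[c] = s1[c] / N;
      double v = s2[c] / N - mu[c] * mu[c];
      if (v < 0) v = 0;
      rm2[c] = (1 - momentum) * rm2[c] + momentum * mu[c];
      rv2[c] = (1 - momentum) * rv2[c] + momentum * v;
      invstd[c] = 1.0 / std::sqrt(v + eps);
    }
  } else {
    for (int c = 0; c < C; ++c) {
      mu[c] = rm[c];
      invstd[c] = 1.0 / std::sqrt(rv[c] + eps);
    }
  }
  std::vector<double> sc(C), sb(C);
  for (int c = 0; c < C; ++c) {
    sc[c] = g[c] * invstd[c];
    sb[c] = b[c] - mu[c] * sc[c];
  }
  double *py = y.begin();
  for (int j = 0; j < N; ++j) {
    const double *xc = px + static_cast<R_xlen_t>(C) * j;
    double *yc = py + static_cast<R_xlen_t>(C) * j;
    for (int c = 0; c < C; ++c) {
      double t = sc[c] * xc[c] + sb[c];
      yc[c] = t > 0 ? t : 0.0;
    }
  }
  return List::create(_["y"] = y, _["mu"] = mu, _["invstd"] = invstd,
                      _["rm"] = rm2, _["rv"] = rv2);
}

// fused relu + batchnorm backward: y is the post-relu output
// [[Rcpp::export(name = ".bn_relu_bwd")]]
List bn_relu_bwd_c(NumericVector x, NumericVector mu, NumericVector invstd,
                   NumericVector g, NumericVector y, NumericVector gy,
                   bool train) {
  const int C = g.size();
  const int N = x.size() / C;
  NumericVector gx(x.size()), gg(C), gb(C);
  const double *px = x.begin(), *pg = gy.begin(), *py = y.begin();
  std::vector<double> dg(C, 0.0), db(C, 0.0);
  for (int j = 0; j < N; ++j) {
    const double *xc = px + static_cast<R_xlen_t>(C) * j;
    const double *gc = pg + static_cast<R_xlen_t>(C) * j;
    const double *yc = py + static_cast<R_xlen_t>(C) * j;
    for (int c = 0; c < C; ++c) {
      const double ge = yc[c] > 0 ? gc[c] : 0.0;
      const double xhat = (xc[c] - mu[c]) * invstd[c];
      dg[c] += ge * xhat;
      db[c] += ge;
    }
  }
  for (int c = 0; c < C; ++c) { gg[c] = dg[c]; gb[c] = db[c]; }
  double *pgx = gx.begin();
  if (train) {
    for (int j = 0; j < N; ++j) {
      const double *xc = px + static_cast<R_xlen_t>(C) * j;
      const double *gc = pg + static_cast<R_xlen_t>(C) * j;
      const double *yc = py + static_cast<R_xlen_t>(C) * j;
      double *gxc = pgx + static_cast<R_xlen_t>(C) * j;
      for (int c = 0; c < C; ++c) {
        const double ge = yc[c] > 0 ? gc[c] : 0.0;
        const double xhat = (xc[c] - mu[c]) * invstd[c];
        gxc[c] = g[c] * invstd[c] * (ge - db[c] / N - xhat * dg[c] / N);
      }
    }
  } else {
    for (int j = 0; j < N; ++j) {
      const double *gc = pg + static_cast<R_xlen_t>(C) * j;
      const double *yc = py + static_cast<R_xlen_t>(C) * j;
      double *gxc = pgx + static_cast<R_xlen_t>(C) * j;
      for (int c = 0; c < C; ++c) {
        gxc[c] = yc[c] > 0 ? g[c] * invstd[c] * gc[c] : 0.0;
      }
    }
  }
  return List::create(_["gx"] = gx, _["gg"] = gg, _["gb"] = gb);
}

// depthwise 1x1 with stride: y[c,ho,wo,b] = k[c] * x[c, ho*s, wo*s, b]
// [[Rcpp::export(name = ".dw1_fwd")]]
NumericVector dw1_fwd_c(NumericVector x, NumericVector k,
                        int C, int H, int W, int B, int stride) {
  const int Ho = (H - 1) / stride + 1, Wo = (W - 1) / stride + 1;
  NumericVector y(static_cast<R_xlen_t>(C) * Ho * Wo * B);
  const double *px = x.begin(); double *py = y.begin();
  for (int b = 0; b < B; ++b)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const double *xc = px + static_cast<R_xlen_t>(C) *
          (ho * stride + H * (static_cast<R_xlen_t>(wo) * stride + W * b));
        double *yc = py + static_cast<R_xlen_t>(C) *
          (ho + Ho * (static_cast<R_xlen_t>(wo) + Wo * b));
        for (int c = 0; c < C; ++c) yc[c] = k[c] * xc[c];
      }
  return y;
}

// [[Rcpp::export(name = ".dw1_bwd")]]
List dw1_bwd_c(NumericVector x, NumericVector k, NumericVector gy,
               int C, int H, int W, int B, int stride) {
  const int Ho = (H - 1) / stride + 1, Wo = (W - 1) / stride + 1;
  NumericVector gx(x.size()), gk(C);
  const double *px = x.begin(), *pg = gy.begin();
  double *pgx = gx.begin(), *pgk = gk.begin();
  for (int b = 0; b < B; ++b)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const R_xlen_t xi = static_cast<R_xlen_t>(C) *
          (ho * stride + H * (static_cast<R_xlen_t>(wo) * stride + W * b));
        const double *gc = pg + static_cast<R_xlen_t>(C) *
          (ho + Ho * (static_cast<R_xlen_t>(wo) + Wo * b));
        for (int c = 0; c < C; ++c) {
          pgx[xi + c] = k[c] * gc[c];
          pgk[c] += px[xi + c] * gc[c];
        }
      }
  return List::create(_["gx"] = gx, _["gk"] = gk);
}
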