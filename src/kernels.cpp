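// Compiled kernels for the inner loops of the network layers: scaled
// dot-product attention (forward/backward), batch-norm scale-shift,
// temporal max-pooling and ELU. All array arguments follow the package's
// column-major conventions: token tensors (B, n, C) are passed as
// (B*n, C) matrices with row index r = b + (i-1)*B.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Q2,K2,V2: (B*n, heads*d_k). Returns O2 (B*n, heads*d_k) and the attention
// weights A as a (B, heads, n, n) array.
// [[Rcpp::export(name = ".attn_fwd_cpp")]]
List attn_fwd_cpp(NumericMatrix Q2, NumericMatrix K2, NumericMatrix V2,
                  int B, int n, int heads, int d_k) {
  const double scl = 1.0 / std::sqrt((double)d_k);
  NumericMatrix O2(Q2.nrow(), Q2.ncol());
  NumericVector A((R_xlen_t)B * heads * n * n);
  A.attr("dim") = IntegerVector::create(B, heads, n, n);
  std::vector<double> srow(n);
  for (int b = 0; b < B; ++b) {
    for (int h = 0; h < heads; ++h) {
      const int c0 = h * d_k;
      for (int i = 0; i < n; ++i) {
        const int ri = b + i * B;
        double mx = -1e300;
        for (int j = 0; j < n; ++j) {
          const int rj = b + j * B;
          double s = 0.0;
          for (int d = 0; d < d_k; ++d) s += Q2(ri, c0 + d) * K2(rj, c0 + d);
          s *= scl;
          srow[j] = s;
          if (s > mx) mx = s;
        }
        double z = 0.0;
        for (int j = 0; j < n; ++j) { srow[j] = std::exp(srow[j] - mx); z += srow[j]; }
        for (int j = 0; j < n; ++j) {
          const double a = srow[j] / z;
          A[b + B * (h + heads * (i + (R_xlen_t)n * j))] = a;
        }
        for (int d = 0; d < d_k; ++d) {
          double o = 0.0;
          for (int j = 0; j < n; ++j)
            o += A[b + B * (h + heads * (i + (R_xlen_t)n * j))] * V2(b + j * B, c0 + d);
          O2(ri, c0 + d) = o;
        }
      }
    }
  }
  return List::create(Named("O2") = O2, Named("A") = A);
}

// Backward of the attention core. dO2: (B*n, heads*d_k).
// [[Rcpp::export(name = ".attn_bwd_cpp")]]
List attn_bwd_cpp(NumericMatrix dO2, NumericMatrix Q2, NumericMatrix K2,
                  NumericMatrix V2, NumericVector A,
                  int B, int n, int heads, int d_k) {
  const double scl = 1.0 / std::sqrt((double)d_k);
  NumericMatrix dQ2(Q2.nrow(), Q2.ncol());
  NumericMatrix dK2(Q2.nrow(), Q2.ncol());
  NumericMatrix dV2(Q2.nrow(), Q2.ncol());
  std::vector<double> dA(n), dS(n);
  for (int b = 0; b < B; ++b) {
    for (int h = 0; h < heads; ++h) {
      const int c0 = h * d_k;
      for (int i = 0; i < n; ++i) {
        const int ri = b + i * B;
        double dot = 0.0;
        for (int j = 0; j < n; ++j) {
          double s = 0.0;
          for (int d = 0; d < d_k; ++d) s += dO2(ri, c0 + d) * V2(b + j * B, c0 + d);
          dA[j] = s;
          dot += s * A[b + B * (h + heads * (i + (R_xlen_t)n * j))];
        }
        for (int j = 0; j < n; ++j) {
          const double a = A[b + B * (h + heads * (i + (R_xlen_t)n * j))];
          dS[j] = a * (dA[j] - dot) * scl;
        }
        for (int d = 0; d < d_k; ++d) {
          double dq = 0.0;
          const double doid = dO2(ri, c0 + d);
          for (int j = 0; j < n; ++j) {
            const int rj = b + j * B;
            const double a = A[b + B * (h + heads * (i + (R_xlen_t)n * j))];
            dq += dS[j] * K2(rj, c0 + d);
            dK2(rj, c0 + d) += dS[j] * Q2(ri, c0 + d);
            dV2(rj, c0 + d) += a * doid;
          }
          dQ2(ri, c0 + d) = dq;
        }
      }
    }
  }
  return List::create(Named("dQ2") = dQ2, Named("dK2") = dK2, Named("dV2") = dV2);
}

// Fused normalise-scale-shift: x2 (N, C) already centred? No: xc = x2 - mu,
// xhat = xc * inv, out = xhat * gamma + beta. Returns out and xhat.
// [[Rcpp::export(name = ".bn_scale_cpp")]]
List bn_scale_cpp(NumericMatrix x2, NumericVector mu, NumericVector inv,
                  NumericVector gamma, NumericVector beta) {
  const int nr = x2.nrow(), nc = x2.ncol();
  NumericMatrix out(nr, nc), xhat(nr, nc);
  for (int c = 0; c < nc; ++c) {
    const double m = mu[c], iv = inv[c], g = gamma[c], be = beta[c];
    for (int r = 0; r < nr; ++r) {
      const double xh = (x2(r, c) - m) * iv;
      xhat(r, c) = xh;
      out(r, c) = xh * g + be;
    }
  }
  return List::create(Named("out") = out, Named("xhat") = xhat);
}

// Batch-norm backward (training mode): dx = (gx - mean(gx) - xhat*mean(gx*xhat)) * inv
// with gx = g * gamma, means per column. Also returns dgamma, dbeta.
// [[Rcpp::export(name = ".bn_bwd_cpp")]]
List bn_bwd_cpp(NumericMatrix g2, NumericMatrix xhat, NumericVector gamma,
                NumericVector inv, bool train) {
  const int nr = g2.nrow(), nc = g2.ncol();
  NumericMatrix dx(nr, nc);
  NumericVector dgamma(nc), dbeta(nc);
  for (int c = 0; c < nc; ++c) {
    const double ga = gamma[c], iv = inv[c];
    double sg = 0.0, sgx = 0.0;
    for (int r = 0; r < nr; ++r) {
      const double g = g2(r, c);
      sg += g;
      sgx += g * xhat(r, c);
    }
    dgamma[c] = sgx;
    dbeta[c] = sg;
    if (train) {
      const double mg = ga * sg / nr, mgx = ga * sgx / nr;
      for (int r = 0; r < nr; ++r)
        dx(r, c) = (ga * g2(r, c) - mg - xhat(r, c) * mgx) * iv;
    } else {
      for (int r = 0; r < nr; ++r) dx(r, c) = ga * g2(r, c) * iv;
    }
  }
  return List::create(Named("dx") = dx, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}

// Non-overlapping temporal max pooling on (B, T, C); ragged tail allowed.
// [[Rcpp::export(name = ".maxpool_fwd_cpp")]]
List maxpool_fwd_cpp(NumericVector x, int B, int T, int C, int pool) {
  const int To = (T + pool - 1) / pool;
  NumericVector out(Dimension(B, To, C));
  IntegerVector arg(Dimension(B, To, C));
  for (int c = 0; c < C; ++c) {
    const R_xlen_t xoff = (R_xlen_t)c * B * T;
    const R_xlen_t ooff = (R_xlen_t)c * B * To;
    for (int to = 0; to < To; ++to) {
      const int t0 = to * pool;
      const int t1 = std::min(t0 + pool, T);
      for (int b = 0; b < B; ++b) {
        double best = x[xoff + b + (R_xlen_t)t0 * B];
        int aj = 1;
        for (int t = t0 + 1; t < t1; ++t) {
          const double v = x[xoff + b + (R_xlen_t)t * B];
          if (v > best) { best = v; aj = t - t0 + 1; }
        }
        out[ooff + b + (R_xlen_t)to * B] = best;
        arg[ooff + b + (R_xlen_t)to * B] = aj;
      }
    }
  }
  return List::create(Named("out") = out, Named("arg") = arg);
}

// [[Rcpp::export(name = ".maxpool_bwd_cpp")]]
NumericVector maxpool_bwd_cpp(NumericVector g, IntegerVector arg,
                              int B, int T, int C, int pool) {
  const int To = (T + pool - 1) / pool;
  NumericVector dx(Dimension(B, T, C));
  for (int c = 0; c < C; ++c) {
    const R_xlen_t xoff = (R_xlen_t)c * B * T;
    const R_xlen_t ooff = (R_xlen_t)c * B * To;
    for (int to = 0; to < To; ++to) {
      for (int b = 0; b < B; ++b) {
        const R_xlen_t oi = ooff + b + (R_xlen_t)to * B;
        const int t = to * pool + arg[oi] - 1;
        dx[xoff + b + (R_xlen_t)t * B] += g[oi];
      }
    }
  }
  return dx;
}

// [[Rcpp::export(name = ".elu_fwd_cpp")]]
List elu_fwd_cpp(NumericVector x) {
  NumericVector out(x.size());
  out.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = x[i] > 0 ? x[i] : std::expm1(x[i]);
  return List::create(Named("out") = out);
}

// d/dx ELU = 1 for x>0 else exp(x) = out+1
// [[Rcpp::export(name = ".elu_bwd_cpp")]]
NumericVector elu_bwd_cpp(NumericVector g, NumericVector out) {
  NumericVector dx(g.size());
  dx.attr("dim") = g.attr("dim");
  for (R_xlen_t i = 0; i < g.size(); ++i)
    dx[i] = out[i] > 0 ? g[i] : g[i] * (out[i] + 1.0);
  return dx;
}
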