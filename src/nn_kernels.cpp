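// Hot loops of the denoising network: window multi-head attention and the
// state-space scan, forward and reverse-mode.  Layouts follow the R side:
// token tensors are (M2, I, C) arrays (token within window, window instance,
// channel), column-major.  Each instance is repacked into contiguous
// buffers before the quadratic-in-M2 work for cache locality.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline void pack_instance(const double *src, double *dst,
                                 int M2, R_xlen_t I, int C, int i) {
  // src (M2, I, C) -> dst (M2, C) for instance i
  for (int c = 0; c < C; ++c) {
    const double *s = src + (R_xlen_t)M2 * (i + I * c);
    double *d = dst + (R_xlen_t)M2 * c;
    std::copy(s, s + M2, d);
  }
}

static inline void unpack_instance_add(const double *src, double *dst,
                                       int M2, R_xlen_t I, int C, int i) {
  for (int c = 0; c < C; ++c) {
    const double *s = src + (R_xlen_t)M2 * c;
    double *d = dst + (R_xlen_t)M2 * (i + I * c);
    for (int a = 0; a < M2; ++a) d[a] += s[a];
  }
}

// [[Rcpp::export]]
List attn_fwd_cpp(NumericVector Q, NumericVector K, NumericVector V,
                  NumericVector bias, NumericVector mask,
                  int M2, int I, int C, int heads, int B,
                  bool use_mask, bool keepP) {
  const int d = C / heads;
  const double scale = 1.0 / std::sqrt((double)d);
  NumericVector O(Q.size());
  NumericVector P_out(keepP ? (R_xlen_t)M2 * M2 * I * heads : 0);
  std::vector<double> qb(M2 * C), kb(M2 * C), vb(M2 * C), ob(M2 * C);
  std::vector<double> S(M2 * M2);
  const double *bi = bias.begin(), *mk = mask.begin();
  double *pout = keepP ? P_out.begin() : nullptr;

  for (int i = 0; i < I; ++i) {
    const R_xlen_t w = i / B;
    pack_instance(Q.begin(), qb.data(), M2, I, C, i);
    pack_instance(K.begin(), kb.data(), M2, I, C, i);
    pack_instance(V.begin(), vb.data(), M2, I, C, i);
    std::fill(ob.begin(), ob.end(), 0.0);
    for (int h = 0; h < heads; ++h) {
      const int c0 = h * d;
      const double *bih = bi + (R_xlen_t)M2 * M2 * h;
      const double *mkw = use_mask ? mk + (R_xlen_t)M2 * M2 * w : nullptr;
      // logits S[a,b] = scale * q_a . k_b + bias + mask
      for (int b = 0; b < M2; ++b) {
        double *Sb = S.data() + (R_xlen_t)M2 * b;
        const double *kcol = kb.data() + (R_xlen_t)M2 * c0;
        std::fill(Sb, Sb + M2, 0.0);
        for (int dd = 0; dd < d; ++dd) {
          const double *qc = qb.data() + (R_xlen_t)M2 * (c0 + dd);
          const double kv = kcol[b + (R_xlen_t)M2 * dd];
          for (int a = 0; a < M2; ++a) Sb[a] += qc[a] * kv;
        }
        if (use_mask) {
          for (int a = 0; a < M2; ++a)
            Sb[a] = Sb[a] * scale + bih[a + (R_xlen_t)M2 * b] + mkw[a + (R_xlen_t)M2 * b];
        } else {
          for (int a = 0; a < M2; ++a)
            Sb[a] = Sb[a] * scale + bih[a + (R_xlen_t)M2 * b];
        }
      }
      // row-wise softmax
      for (int a = 0; a < M2; ++a) {
        double mx = -1e300;
        for (int b = 0; b < M2; ++b) mx = std::max(mx, S[a + (R_xlen_t)M2 * b]);
        double sum = 0.0;
        for (int b = 0; b < M2; ++b) {
          double e = std::exp(S[a + (R_xlen_t)M2 * b] - mx);
          S[a + (R_xlen_t)M2 * b] = e;
          sum += e;
        }
        const double inv = 1.0 / sum;
        for (int b = 0; b < M2; ++b) S[a + (R_xlen_t)M2 * b] *= inv;
      }
      if (keepP) {
        std::copy(S.begin(), S.end(),
                  pout + (R_xlen_t)M2 * M2 * (i + (R_xlen_t)I * h));
      }
      // O = P V  (accumulate over b)
      for (int dd = 0; dd < d; ++dd) {
        double *oc = ob.data() + (R_xlen_t)M2 * (c0 + dd);
        const double *vc = vb.data() + (R_xlen_t)M2 * (c0 + dd);
        for (int b = 0; b < M2; ++b) {
          const double vv = vc[b];
          const double *Sb = S.data() + (R_xlen_t)M2 * b;
          for (int a = 0; a < M2; ++a) oc[a] += Sb[a] * vv;
        }
      }
    }
    // write back
    for (int c = 0; c < C; ++c) {
      double *dsto = O.begin() + (R_xlen_t)M2 * (i + (R_xlen_t)I * c);
      std::copy(ob.begin() + (R_xlen_t)M2 * c, ob.begin() + (R_xlen_t)M2 * (c + 1), dsto);
    }
  }
  return List::create(_["O"] = O, _["P"] = P_out);
}

// [[Rcpp::export]]
List attn_bwd_cpp(NumericVector dO, NumericVector Q, NumericVector K,
                  NumericVector V, NumericVector P,
                  int M2, int I, int C, int heads) {
  const int d = C / heads;
  const double scale = 1.0 / std::sqrt((double)d);
  NumericVector dQ(Q.size()), dK(K.size()), dV(V.size());
  NumericVector dBias((R_xlen_t)M2 * M2 * heads);
  std::vector<double> qb(M2 * C), kb(M2 * C), vb(M2 * C), dob(M2 * C);
  std::vector<double> dqb(M2 * C), dkb(M2 * C), dvb(M2 * C);
  std::vector<double> dP(M2 * M2), rowdot(M2);
  const double *p = P.begin();
  double *db = dBias.begin();

  for (int i = 0; i < I; ++i) {
    pack_instance(Q.begin(), qb.data(), M2, I, C, i);
    pack_instance(K.begin(), kb.data(), M2, I, C, i);
    pack_instance(V.begin(), vb.data(), M2, I, C, i);
    pack_instance(dO.begin(), dob.data(), M2, I, C, i);
    std::fill(dqb.begin(), dqb.end(), 0.0);
    std::fill(dkb.begin(), dkb.end(), 0.0);
    std::fill(dvb.begin(), dvb.end(), 0.0);
    for (int h = 0; h < heads; ++h) {
      const int c0 = h * d;
      const double *Pi = p + (R_xlen_t)M2 * M2 * (i + (R_xlen_t)I * h);
      double *dbh = db + (R_xlen_t)M2 * M2 * h;
      std::fill(dP.begin(), dP.end(), 0.0);
      for (int dd = 0; dd < d; ++dd) {
        const double *doc = dob.data() + (R_xlen_t)M2 * (c0 + dd);
        const double *vc = vb.data() + (R_xlen_t)M2 * (c0 + dd);
        double *dvc = dvb.data() + (R_xlen_t)M2 * (c0 + dd);
        for (int b = 0; b < M2; ++b) {
          const double *Pb = Pi + (R_xlen_t)M2 * b;
          double acc = 0.0;
          const double vv = vc[b];
          double *dPb = dP.data() + (R_xlen_t)M2 * b;
          for (int a = 0; a < M2; ++a) {
            acc += Pb[a] * doc[a];
            dPb[a] += doc[a] * vv;
          }
          dvc[b] += acc;
        }
      }
      // dS = P * (dP - rowdot), rowdot_a = sum_b dP[a,b] P[a,b]
      for (int a = 0; a < M2; ++a) rowdot[a] = 0.0;
      for (int b = 0; b < M2; ++b) {
        const double *Pb = Pi + (R_xlen_t)M2 * b;
        const double *dPb = dP.data() + (R_xlen_t)M2 * b;
        for (int a = 0; a < M2; ++a) rowdot[a] += dPb[a] * Pb[a];
      }
      for (int b = 0; b < M2; ++b) {
        const double *Pb = Pi + (R_xlen_t)M2 * b;
        double *dPb = dP.data() + (R_xlen_t)M2 * b;   // reuse as dS
        double *dbb = dbh + (R_xlen_t)M2 * b;
        for (int a = 0; a < M2; ++a) {
          const double val = Pb[a] * (dPb[a] - rowdot[a]);
          dPb[a] = val;
          dbb[a] += val;
        }
      }
      // dQ += scale * dS K ; dK += scale * dS^T Q
      for (int dd = 0; dd < d; ++dd) {
        const double *kc = kb.data() + (R_xlen_t)M2 * (c0 + dd);
        const double *qc = qb.data() + (R_xlen_t)M2 * (c0 + dd);
        double *dqc = dqb.data() + (R_xlen_t)M2 * (c0 + dd);
        double *dkc = dkb.data() + (R_xlen_t)M2 * (c0 + dd);
        for (int b = 0; b < M2; ++b) {
          const double *dSb = dP.data() + (R_xlen_t)M2 * b;
          const double kv = kc[b];
          double acc = 0.0;
          for (int a = 0; a < M2; ++a) {
            dqc[a] += scale * dSb[a] * kv;
            acc += dSb[a] * qc[a];
          }
          dkc[b] += scale * acc;
        }
      }
    }
    unpack_instance_add(dqb.data(), dQ.begin(), M2, I, C, i);
    unpack_instance_add(dkb.data(), dK.begin(), M2, I, C, i);
    unpack_instance_add(dvb.data(), dV.begin(), M2, I, C, i);
  }
  return List::create(_["dQ"] = dQ, _["dK"] = dK, _["dV"] = dV,
                      _["dBias"] = dBias);
}

// X: (Tlen, B, C); abar/bbar/Cc: (C, N); D: C.  State laid out (B, C*N).
// [[Rcpp::export]]
List ssm_scan_fwd_cpp(NumericVector X, NumericMatrix abar, NumericMatrix bbar,
                      NumericMatrix Cc, NumericVector D,
                      int Tlen, int B, int C, bool keepH) {
  const int N = abar.ncol();
  NumericVector Y(X.size());
  NumericVector Hall(keepH ? (R_xlen_t)Tlen * B * C * N : 0);
  std::vector<double> h((R_xlen_t)B * C * N, 0.0);
  const double *x = X.begin();
  double *y = Y.begin();
  double *hall = keepH ? Hall.begin() : nullptr;
  for (int t = 0; t < Tlen; ++t) {
    for (int c = 0; c < C; ++c) {
      const R_xlen_t xoff = t + (R_xlen_t)Tlen * ((R_xlen_t)B * c);
      for (int b = 0; b < B; ++b) {
        const double xv = x[xoff + (R_xlen_t)Tlen * b];
        double acc = D[c] * xv;
        for (int n = 0; n < N; ++n) {
          const R_xlen_t j = (R_xlen_t)B * (c + C * n) + b;
          h[j] = h[j] * abar(c, n) + bbar(c, n) * xv;
          acc += Cc(c, n) * h[j];
        }
        y[xoff + (R_xlen_t)Tlen * b] = acc;
      }
    }
    if (keepH) {
      for (R_xlen_t j = 0; j < (R_xlen_t)B * C * N; ++j)
        hall[t + (R_xlen_t)Tlen * j] = h[j];
    }
  }
  return List::create(_["Y"] = Y, _["Hall"] = Hall);
}

// [[Rcpp::export]]
List ssm_scan_bwd_cpp(NumericVector dY, NumericVector X, NumericVector Hall,
                      NumericMatrix abar, NumericMatrix bbar,
                      NumericMatrix Cc, NumericVector D,
                      int Tlen, int B, int C) {
  const int N = abar.ncol();
  NumericVector dX(X.size());
  NumericMatrix dabar(C, N), dbbar(C, N), dCc(C, N);
  NumericVector dD(C);
  std::vector<double> dh((R_xlen_t)B * C * N, 0.0);
  const double *dy = dY.begin(), *x = X.begin(), *hall = Hall.begin();
  double *dx = dX.begin();
  for (int t = Tlen - 1; t >= 0; --t) {
    for (int c = 0; c < C; ++c) {
      const R_xlen_t xoff = t + (R_xlen_t)Tlen * ((R_xlen_t)B * c);
      for (int b = 0; b < B; ++b) {
        const double dyv = dy[xoff + (R_xlen_t)Tlen * b];
        const double xv = x[xoff + (R_xlen_t)Tlen * b];
        dD[c] += dyv * xv;
        double dxv = dyv * D[c];
        for (int n = 0; n < N; ++n) {
          const R_xlen_t j = (R_xlen_t)B * (c + C * n) + b;
          const double ht = hall[t + (R_xlen_t)Tlen * j];
          const double hprev = (t > 0) ? hall[(t - 1) + (R_xlen_t)Tlen * j] : 0.0;
          dh[j] += dyv * Cc(c, n);
          dCc(c, n) += dyv * ht;
          dabar(c, n) += dh[j] * hprev;
          dbbar(c, n) += dh[j] * xv;
          dxv += dh[j] * bbar(c, n);
          dh[j] *= abar(c, n);
        }
        dx[xoff + (R_xlen_t)Tlen * b] = dxv;
      }
    }
  }
  return List::create(_["dX"] = dX, _["dabar"] = dabar, _["dbbar"] = dbbar,
                      _["dCc"] = dCc, _["dD"] = dD);
}

// Layer normalization over rows of a column-major (n, C) matrix.
// [[Rcpp::export]]
List layernorm_fwd_cpp(NumericMatrix X, NumericVector g, NumericVector b,
                       double eps) {
  const int n = X.nrow(), C = X.ncol();
  NumericMatrix Y(n, C), xh(n, C);
  NumericVector inv(n);
  std::vector<double> mu(n, 0.0), var(n, 0.0);
  const double *x = X.begin();
  for (int c = 0; c < C; ++c) {
    const double *xc = x + (R_xlen_t)n * c;
    for (int i = 0; i < n; ++i) mu[i] += xc[i];
  }
  for (int i = 0; i < n; ++i) mu[i] /= C;
  for (int c = 0; c < C; ++c) {
    const double *xc = x + (R_xlen_t)n * c;
    for (int i = 0; i < n; ++i) {
      const double d = xc[i] - mu[i];
      var[i] += d * d;
    }
  }
  for (int i = 0; i < n; ++i) inv[i] = 1.0 / std::sqrt(var[i] / C + eps);
  double *yh = xh.begin(), *y = Y.begin();
  for (int c = 0; c < C; ++c) {
    const double *xc = x + (R_xlen_t)n * c;
    double *hc = yh + (R_xlen_t)n * c;
    double *yc = y + (R_xlen_t)n * c;
    const double gc = g[c], bc = b[c];
    for (int i = 0; i < n; ++i) {
      const double h = (xc[i] - mu[i]) * inv[i];
      hc[i] = h;
      yc[i] = h * gc + bc;
    }
  }
  return List::create(_["out"] = Y, _["xh"] = xh, _["inv"] = inv);
}

// [[Rcpp::export]]
List layernorm_bwd_cpp(NumericMatrix dY, NumericMatrix xh, NumericVector inv,
                       NumericVector g) {
  const int n = dY.nrow(), C = dY.ncol();
  NumericMatrix dX(n, C);
  NumericVector dg(C), db(C);
  std::vector<double> s1(n, 0.0), s2(n, 0.0);
  const double *dy = dY.begin(), *h = xh.begin();
  for (int c = 0; c < C; ++c) {
    const double *dyc = dy + (R_xlen_t)n * c;
    const double *hc = h + (R_xlen_t)n * c;
    const double gc = g[c];
    double sg = 0.0, sb = 0.0;
    for (int i = 0; i < n; ++i) {
      const double dxh = dyc[i] * gc;
      s1[i] += dxh;
      s2[i] += dxh * hc[i];
      sg += dyc[i] * hc[i];
      sb += dyc[i];
    }
    dg[c] = sg; db[c] = sb;
  }
  double *dx = dX.begin();
  for (int c = 0; c < C; ++c) {
    const double *dyc = dy + (R_xlen_t)n * c;
    const double *hc = h + (R_xlen_t)n * c;
    double *dxc = dx + (R_xlen_t)n * c;
    const double gc = g[c];
    for (int i = 0; i < n; ++i) {
      dxc[i] = inv[i] / C * (C * dyc[i] * gc - s1[i] - hc[i] * s2[i]);
    }
  }
  return List::create(_["dX"] = dX, _["dg"] = dg, _["db"] = db);
}

// In-place bias add over columns of a column-major (n, C) matrix.
// [[Rcpp::export]]
void add_bias_inplace_cpp(NumericMatrix Y, NumericVector b) {
  const int n = Y.nrow(), C = Y.ncol();
  double *y = Y.begin();
  for (int c = 0; c < C; ++c) {
    const double bc = b[c];
    double *yc = y + (R_xlen_t)n * c;
    for (int i = 0; i < n; ++i) yc[i] += bc;
  }
}

// [[Rcpp::export]]
NumericVector gelu_cpp(NumericVector x) {
  NumericVector y(x.size());
  const double *xp = x.begin();
  double *yp = y.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    yp[i] = xp[i] / (1.0 + std::exp(-1.702 * xp[i]));
  }
  return y;
}

// [[Rcpp::export]]
NumericVector gelu_bwd_cpp(NumericVector dy, NumericVector x) {
  NumericVector out(x.size());
  const double *xp = x.begin(), *dp = dy.begin();
  double *op = out.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double s = 1.0 / (1.0 + std::exp(-1.702 * xp[i]));
    op[i] = dp[i] * (s + 1.702 * xp[i] * s * (1.0 - s));
  }
  return out;
}
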