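// hot inner kernels for the toy transformer: per-sample multi-head attention
// contractions, GELU, and row softmax. Shapes follow the R side: activations
// are (B*np) x D matrices with rows ordered position-fastest. Per-sample,
// per-head tiles are staged into contiguous row-major buffers so the dot
// products run over unit-stride memory.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// copy the (np x dh) tile for sample s / head h into a row-major buffer
static inline void load_tile(const double* M, int nrow, int r0, int c0,
                             int np, int dh, double* buf) {
  for (int dd = 0; dd < dh; ++dd) {
    const double* col = M + (R_xlen_t)(c0 + dd) * nrow + r0;
    for (int i = 0; i < np; ++i) buf[i * dh + dd] = col[i];
  }
}

static inline void store_tile(double* M, int nrow, int r0, int c0,
                              int np, int dh, const double* buf) {
  for (int dd = 0; dd < dh; ++dd) {
    double* col = M + (R_xlen_t)(c0 + dd) * nrow + r0;
    for (int i = 0; i < np; ++i) col[i] = buf[i * dh + dd];
  }
}

// multi-head attention forward for one trunk block.
// Q, K, V: (B*np) x D. Returns ctx (same shape) and the attention weights A
// as a (B*np*nh) x np matrix (rows: i fastest, then head, then sample).
// [[Rcpp::export(name = ".cpp_mha_forward")]]
List cpp_mha_forward(const NumericMatrix& Q, const NumericMatrix& K,
                     const NumericMatrix& V, int np, int nh) {
  const int rows = Q.nrow(), d = Q.ncol();
  const int b = rows / np, dh = d / nh;
  const double scale = 1.0 / std::sqrt((double)dh);
  NumericMatrix ctx(rows, d);
  NumericMatrix A((R_xlen_t)rows * nh, np);
  const double* qp = Q.begin();
  const double* kp = K.begin();
  const double* vp = V.begin();
  double* ap = A.begin();
  double* cp = ctx.begin();
  const R_xlen_t anrow = (R_xlen_t)rows * nh;
  std::vector<double> qb(np * dh), kb(np * dh), vb(np * dh), cb(np * dh), sc(np);
  for (int s = 0; s < b; ++s) {
    const int r0 = s * np;
    for (int h = 0; h < nh; ++h) {
      const int c0 = h * dh;
      load_tile(qp, rows, r0, c0, np, dh, qb.data());
      load_tile(kp, rows, r0, c0, np, dh, kb.data());
      load_tile(vp, rows, r0, c0, np, dh, vb.data());
      const R_xlen_t a0 = (R_xlen_t)(s * nh + h) * np;
      std::fill(cb.begin(), cb.end(), 0.0);
      for (int i = 0; i < np; ++i) {
        const double* qi = qb.data() + i * dh;
        double mx = -1e300;
        for (int j = 0; j < np; ++j) {
          const double* kj = kb.data() + j * dh;
          double acc = 0.0;
          for (int dd = 0; dd < dh; ++dd) acc += qi[dd] * kj[dd];
          sc[j] = acc * scale;
          if (sc[j] > mx) mx = sc[j];
        }
        double tot = 0.0;
        for (int j = 0; j < np; ++j) { sc[j] = std::exp(sc[j] - mx); tot += sc[j]; }
        double* ci = cb.data() + i * dh;
        for (int j = 0; j < np; ++j) {
          const double a = sc[j] / tot;
          ap[(R_xlen_t)j * anrow + a0 + i] = a;
          const double* vj = vb.data() + j * dh;
          for (int dd = 0; dd < dh; ++dd) ci[dd] += a * vj[dd];
        }
      }
      store_tile(cp, rows, r0, c0, np, dh, cb.data());
    }
  }
  return List::create(_["ctx"] = ctx, _["A"] = A);
}

// gradients of the attention contraction given the stored weights A
// [[Rcpp::export(name = ".cpp_mha_backward")]]
List cpp_mha_backward(const NumericMatrix& A, const NumericMatrix& Q,
                      const NumericMatrix& K, const NumericMatrix& V,
                      const NumericMatrix& dctx, int np, int nh) {
  const int rows = Q.nrow(), d = Q.ncol();
  const int b = rows / np, dh = d / nh;
  const double scale = 1.0 / std::sqrt((double)dh);
  NumericMatrix dQ(rows, d), dK(rows, d), dV(rows, d);
  const double* qp = Q.begin();
  const double* kp = K.begin();
  const double* vp = V.begin();
  const double* gp = dctx.begin();
  const double* ap = A.begin();
  const R_xlen_t anrow = (R_xlen_t)rows * nh;
  std::vector<double> qb(np * dh), kb(np * dh), vb(np * dh), gb(np * dh),
      dqb(np * dh), dkb(np * dh), dvb(np * dh), arow(np), dA(np), dS(np);
  for (int s = 0; s < b; ++s) {
    const int r0 = s * np;
    for (int h = 0; h < nh; ++h) {
      const int c0 = h * dh;
      load_tile(qp, rows, r0, c0, np, dh, qb.data());
      load_tile(kp, rows, r0, c0, np, dh, kb.data());
      load_tile(vp, rows, r0, c0, np, dh, vb.data());
      load_tile(gp, rows, r0, c0, np, dh, gb.data());
      std::fill(dqb.begin(), dqb.end(), 0.0);
      std::fill(dkb.begin(), dkb.end(), 0.0);
      std::fill(dvb.begin(), dvb.end(), 0.0);
      const R_xlen_t a0 = (R_xlen_t)(s * nh + h) * np;
      for (int i = 0; i < np; ++i) {
        const double* gi = gb.data() + i * dh;
        double dot = 0.0;
        for (int j = 0; j < np; ++j) {
          arow[j] = ap[(R_xlen_t)j * anrow + a0 + i];
          const double* vj = vb.data() + j * dh;
          double acc = 0.0;
          for (int dd = 0; dd < dh; ++dd) acc += gi[dd] * vj[dd];
          dA[j] = acc;
          dot += arow[j] * acc;
        }
        double* dqi = dqb.data() + i * dh;
        for (int j = 0; j < np; ++j) {
          const double a = arow[j];
          dS[j] = a * (dA[j] - dot) * scale;
          double* dvj = dvb.data() + j * dh;
          for (int dd = 0; dd < dh; ++dd) dvj[dd] += a * gi[dd];
        }
        for (int j = 0; j < np; ++j) {
          const double ds = dS[j];
          const double* kj = kb.data() + j * dh;
          const double* qi = qb.data() + i * dh;
          double* dkj = dkb.data() + j * dh;
          for (int dd = 0; dd < dh; ++dd) {
            dqi[dd] += ds * kj[dd];
            dkj[dd] += ds * qi[dd];
          }
        }
      }
      store_tile(dQ.begin(), rows, r0, c0, np, dh, dqb.data());
      store_tile(dK.begin(), rows, r0, c0, np, dh, dkb.data());
      store_tile(dV.begin(), rows, r0, c0, np, dh, dvb.data());
    }
  }
  return List::create(_["dQ"] = dQ, _["dK"] = dK, _["dV"] = dV);
}

// exact GELU x * Phi(x) and its derivative
// [[Rcpp::export(name = ".cpp_gelu")]]
NumericMatrix cpp_gelu(const NumericMatrix& x) {
  NumericMatrix y(x.nrow(), x.ncol());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const double v = x[i];
    y[i] = v * 0.5 * (1.0 + std::erf(v * M_SQRT1_2));
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_gelu_grad")]]
NumericMatrix cpp_gelu_grad(const NumericMatrix& x) {
  NumericMatrix y(x.nrow(), x.ncol());
  const double inv_sqrt2pi = 0.3989422804014327;
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const double v = x[i];
    const double phi = 0.5 * (1.0 + std::erf(v * M_SQRT1_2));
    y[i] = phi + v * inv_sqrt2pi * std::exp(-0.5 * v * v);
  }
  return y;
}

// numerically stable row softmax
// [[Rcpp::export(name = ".cpp_softmax_rows")]]
NumericMatrix cpp_softmax_rows(const NumericMatrix& z) {
  const int n = z.nrow(), k = z.ncol();
  NumericMatrix p(n, k);
  const double* zp = z.begin();
  double* pp = p.begin();
  for (int i = 0; i < n; ++i) {
    double mx = zp[i];
    for (int j = 1; j < k; ++j) {
      const double v = zp[(R_xlen_t)j * n + i];
      if (v > mx) mx = v;
    }
    double tot = 0.0;
    for (int j = 0; j < k; ++j) {
      const double e = std::exp(zp[(R_xlen_t)j * n + i] - mx);
      pp[(R_xlen_t)j * n + i] = e;
      tot += e;
    }
    for (int j = 0; j < k; ++j) pp[(R_xlen_t)j * n + i] /= tot;
  }
  return p;
}
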