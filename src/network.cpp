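// Fused forward/backward pass of the dual-pathway dilated-convolution
// network.  Activations are (pixels*batch) x channels; convolutions are
// im2col + one sgemm per layer.  Arithmetic is single precision — the
// customary precision for training convolutional networks — with double
// precision at the R interface.  The backward pass reuses the activations
// cached by the forward pass through an external pointer, so each
// mini-batch costs exactly one forward and one backward sweep.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fvec;

struct NetCache {
  fmat X, dw_out, h0p, h0;
  std::vector<fmat> loc_in, loc_p, glo_in, glo_p;
  fmat cat_in, cat_p;
  std::vector<fmat> fc_in, fc_p;
};

static fmat as_f(SEXP x) {
  NumericMatrix m(x);
  fmat out(m.nrow(), m.ncol());
  const double* src = m.begin();
  float* dst = out.memptr();
  const size_t n = out.n_elem;
  for (size_t i = 0; i < n; ++i) dst[i] = static_cast<float>(src[i]);
  return out;
}

static fvec as_fv(SEXP x) {
  NumericVector v(x);
  fvec out(v.size());
  for (int i = 0; i < v.size(); ++i) out[i] = static_cast<float>(v[i]);
  return out;
}

static NumericMatrix as_d(const fmat& m) {
  NumericMatrix out(m.n_rows, m.n_cols);
  const float* src = m.memptr();
  double* dst = out.begin();
  const size_t n = m.n_elem;
  for (size_t i = 0; i < n; ++i) dst[i] = static_cast<double>(src[i]);
  return out;
}

static NumericVector as_dv(const fvec& v) {
  NumericVector out(v.n_elem);
  for (size_t i = 0; i < v.n_elem; ++i) out[i] = static_cast<double>(v[i]);
  return out;
}

static fmat im2col(const fmat& A, const IntegerMatrix& D) {
  const int n = D.nrow(), k2 = D.ncol(), cin = A.n_cols;
  fmat xcol(n, (size_t)k2 * cin);
  for (int o = 0; o < k2; ++o) {
    const int* src = &D(0, o);
    for (int c = 0; c < cin; ++c) {
      float* dst = xcol.colptr((size_t)o * cin + c);
      const float* ac = A.colptr(c);
      for (int i = 0; i < n; ++i) {
        const int s = src[i];
        dst[i] = s ? ac[s - 1] : 0.0f;
      }
    }
  }
  return xcol;
}

static fmat col2im(const fmat& dxcol, const IntegerMatrix& D, int cin) {
  const int n = D.nrow(), k2 = D.ncol();
  fmat dA(n, cin, arma::fill::zeros);
  for (int o = 0; o < k2; ++o) {
    const int* src = &D(0, o);
    for (int c = 0; c < cin; ++c) {
      const float* g = dxcol.colptr((size_t)o * cin + c);
      float* ac = dA.colptr(c);
      for (int i = 0; i < n; ++i) {
        const int s = src[i];
        if (s) ac[s - 1] += g[i];
      }
    }
  }
  return dA;
}

static fmat conv_f(const fmat& A, const fmat& W, const fvec& b,
                   const IntegerMatrix& D, fmat* keep_xcol = nullptr) {
  fmat xcol = im2col(A, D);
  fmat Y = xcol * W;
  Y.each_row() += b.t();
  if (keep_xcol) *keep_xcol = std::move(xcol);
  return Y;
}

static fmat dwconv_f(const fmat& A, const fmat& w, const fvec& b,
                     const IntegerMatrix& D) {
  const int n = D.nrow(), k2 = D.ncol(), cc = A.n_cols;
  fmat Y(n, cc);
  Y.each_row() = b.t();
  for (int o = 0; o < k2; ++o) {
    const int* src = &D(0, o);
    for (int c = 0; c < cc; ++c) {
      const float wv = w(o, c);
      const float* ac = A.colptr(c);
      float* yc = Y.colptr(c);
      for (int i = 0; i < n; ++i) {
        const int s = src[i];
        if (s) yc[i] += wv * ac[s - 1];
      }
    }
  }
  return Y;
}

// in-place dLoss/dpre = dLoss/dpost * 1[pre > 0]
static inline void relu_mask(fmat& g, const fmat& pre) {
  float* gp = g.memptr();
  const float* pp = pre.memptr();
  const size_t n = g.n_elem;
  for (size_t i = 0; i < n; ++i) if (pp[i] <= 0.0f) gp[i] = 0.0f;
}

static inline fmat relu_f(const fmat& x) {
  fmat y = x;
  y.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  return y;
}

// [[Rcpp::export]]
List net_forward_cpp(List net, NumericMatrix X, IntegerMatrix D1,
                     IntegerMatrix D2, IntegerMatrix D4, IntegerMatrix D8,
                     bool keep_cache) {
  NetCache* cc = keep_cache ? new NetCache() : nullptr;
  const IntegerMatrix* Dg[3] = { &D2, &D4, &D8 };
  fmat x = as_f(X);
  if (cc) cc->X = x;
  fmat a = dwconv_f(x, as_f(net["dw_w"]), as_fv(net["dw_b"]), D1);
  if (cc) cc->dw_out = a;
  fmat h0p = a * as_f(net["mix_w"]);
  h0p.each_row() += as_fv(net["mix_b"]).t();
  fmat h0 = relu_f(h0p);
  if (cc) { cc->h0p = h0p; cc->h0 = h0; }
  fmat l = h0;
  for (int i = 0; i < 3; ++i) {
    if (cc) cc->loc_in.push_back(l);
    std::string nm = "loc" + std::to_string(i + 1);
    fmat lp = conv_f(l, as_f(net[nm + "_w"]), as_fv(net[nm + "_b"]), D1);
    l = relu_f(lp);
    if (cc) cc->loc_p.push_back(lp);
  }
  fmat g = h0;
  for (int i = 0; i < 3; ++i) {
    if (cc) cc->glo_in.push_back(g);
    std::string nm = "glo" + std::to_string(i + 1);
    fmat gp = conv_f(g, as_f(net[nm + "_w"]), as_fv(net[nm + "_b"]), *Dg[i]);
    g = relu_f(gp);
    if (cc) cc->glo_p.push_back(gp);
  }
  fmat cat = arma::join_rows(l, g);
  if (cc) cc->cat_in = cat;
  fmat cp = conv_f(cat, as_f(net["cat_w"]), as_fv(net["cat_b"]), D1);
  fmat h = relu_f(cp);
  if (cc) { cc->cat_p = cp; cc->fc_in.push_back(h); }
  for (int i = 0; i < 3; ++i) {
    std::string nm = "fc" + std::to_string(i + 1);
    fmat hp = h * as_f(net[nm + "_w"]);
    hp.each_row() += as_fv(net[nm + "_b"]).t();
    if (i < 2) {
      h = relu_f(hp);
      if (cc) { cc->fc_p.push_back(hp); cc->fc_in.push_back(h); }
    } else h = hp;
  }
  List out = List::create(Named("out") = as_d(h));
  if (cc) {
    XPtr<NetCache> ptr(cc, true);
    out["cache"] = ptr;
  }
  return out;
}

// [[Rcpp::export]]
List net_backward_cpp(List net, SEXP cache_ptr, NumericMatrix dOut,
                      IntegerMatrix D1, IntegerMatrix D2, IntegerMatrix D4,
                      IntegerMatrix D8) {
  XPtr<NetCache> cc(cache_ptr);
  const IntegerMatrix* Dg[3] = { &D2, &D4, &D8 };
  List gr;
  fmat dh = as_f(dOut);
  for (int i = 2; i >= 0; --i) {
    std::string nm = "fc" + std::to_string(i + 1);
    const fmat& hin = cc->fc_in[i];
    gr[nm + "_w"] = as_d(hin.t() * dh);
    gr[nm + "_b"] = as_dv(arma::sum(dh, 0).t());
    dh = dh * as_f(net[nm + "_w"]).t();
    if (i > 0) relu_mask(dh, cc->fc_p[i - 1]);
  }
  relu_mask(dh, cc->cat_p);
  {
    fmat xcol = im2col(cc->cat_in, D1);
    gr["cat_w"] = as_d(xcol.t() * dh);
    gr["cat_b"] = as_dv(arma::sum(dh, 0).t());
    dh = col2im(dh * as_f(net["cat_w"]).t(), D1, cc->cat_in.n_cols);
  }
  const int f = cc->loc_p[2].n_cols;
  fmat dl = dh.cols(0, f - 1);
  fmat dg = dh.cols(f, 2 * f - 1);
  for (int i = 2; i >= 0; --i) {
    std::string nm = "loc" + std::to_string(i + 1);
    relu_mask(dl, cc->loc_p[i]);
    fmat xcol = im2col(cc->loc_in[i], D1);
    gr[nm + "_w"] = as_d(xcol.t() * dl);
    gr[nm + "_b"] = as_dv(arma::sum(dl, 0).t());
    dl = col2im(dl * as_f(net[nm + "_w"]).t(), D1, cc->loc_in[i].n_cols);
  }
  for (int i = 2; i >= 0; --i) {
    std::string nm = "glo" + std::to_string(i + 1);
    relu_mask(dg, cc->glo_p[i]);
    fmat xcol = im2col(cc->glo_in[i], *Dg[i]);
    gr[nm + "_w"] = as_d(xcol.t() * dg);
    gr[nm + "_b"] = as_dv(arma::sum(dg, 0).t());
    dg = col2im(dg * as_f(net[nm + "_w"]).t(), *Dg[i], cc->glo_in[i].n_cols);
  }
  fmat dh0 = dl + dg;
  relu_mask(dh0, cc->h0p);
  gr["mix_w"] = as_d(cc->dw_out.t() * dh0);
  gr["mix_b"] = as_dv(arma::sum(dh0, 0).t());
  fmat da = dh0 * as_f(net["mix_w"]).t();
  {
    // depthwise layer gradients
    const IntegerMatrix& D = D1;
    const int n = D.nrow(), k2 = D.ncol(), cnum = cc->X.n_cols;
    fmat dw(k2, cnum, arma::fill::zeros);
    fmat wsp = as_f(net["dw_w"]);
    for (int o = 0; o < k2; ++o) {
      const int* src = &D(0, o);
      for (int c = 0; c < cnum; ++c) {
        const float* ac = cc->X.colptr(c);
        const float* gc = da.colptr(c);
        float acc = 0.0f;
        for (int i = 0; i < n; ++i) {
          const int s = src[i];
          if (s) acc += ac[s - 1] * gc[i];
        }
        dw(o, c) = acc;
      }
    }
    gr["dw_w"] = as_d(dw);
    gr["dw_b"] = as_dv(arma::sum(da, 0).t());
  }
  return gr;
}
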