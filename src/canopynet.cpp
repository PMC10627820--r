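#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::NumericVector;
using Rcpp::IntegerVector;

// Fully convolutional residual regressor with separable convolutions and two
// 1x1 heads (mean, log-variance). No downsampling: output dims == input dims.
//
// Activations are F x (P * nimg) matrices, P = H*W; a minibatch is processed
// as one wide matrix so the pointwise (1x1) convolutions are single GEMMs.
// Pixels follow R column-major order within each image: p = w*H + h
// (0-based), image i occupying columns [i*P, (i+1)*P).
//
// Flat parameter vector layout (column-major matrices), mirrored by
// paramLayout() on the R side -- keep the two in sync:
//   W0 (F x Cin), b0 (F)
//   for each block b = 1..B:
//     D1 (F x 9), P1 (F x F), c1 (F), D2 (F x 9), P2 (F x F), c2 (F)
//   Wm (F), bm (1), Wv (F), bv (1)
// Depthwise 3x3 kernel index k = (dw+1)*3 + (dh+1), dh/dw in {-1,0,1};
// zero padding at the grid boundary.

namespace {

struct Params {
  mat W0;
  std::vector<mat> D1, P1, D2, P2;
  std::vector<vec> c1, c2;
  vec b0, Wm, Wv;
  double bm, bv;
  int Cin, F, B;
};

inline int64_t n_params(int Cin, int F, int B) {
  return (int64_t)F * Cin + F + (int64_t)B * 2 * (9 * F + (int64_t)F * F + F) +
         2 * F + 2;
}

// Build views into a flat parameter (or gradient) vector.
void map_params(double* p, int Cin, int F, int B, Params& pr) {
  pr.Cin = Cin; pr.F = F; pr.B = B;
  pr.D1.resize(B); pr.P1.resize(B); pr.c1.resize(B);
  pr.D2.resize(B); pr.P2.resize(B); pr.c2.resize(B);
  double* c = p;
  pr.W0 = mat(c, F, Cin, false, true); c += (size_t)F * Cin;
  pr.b0 = vec(c, F, false, true); c += F;
  for (int b = 0; b < B; ++b) {
    pr.D1[b] = mat(c, F, 9, false, true); c += 9 * F;
    pr.P1[b] = mat(c, F, F, false, true); c += (size_t)F * F;
    pr.c1[b] = vec(c, F, false, true); c += F;
    pr.D2[b] = mat(c, F, 9, false, true); c += 9 * F;
    pr.P2[b] = mat(c, F, F, false, true); c += (size_t)F * F;
    pr.c2[b] = vec(c, F, false, true); c += F;
  }
  pr.Wm = vec(c, F, false, true); c += F;
  pr.bm = *c; c += 1;
  pr.Wv = vec(c, F, false, true); c += F;
  pr.bv = *c;
}

inline size_t off_bm(int Cin, int F, int B) {
  return (size_t)F * Cin + F + (size_t)B * 2 * (9 * F + (size_t)F * F + F) + F;
}

// Iterate the valid (output, input) column pairs of one 3x3 offset across
// all images and apply `body(out_col0, in_col0, ncols)` to each contiguous
// run (one run per image w-column, h-contiguous).
template <typename Body>
inline void dw_sweep(int k, int H, int W, int nimg, Body body) {
  const int dh = k % 3 - 1, dw_ = k / 3 - 1;
  const int h0 = std::max(0, -dh), h1 = H - 1 - std::max(0, dh);
  const int w0 = std::max(0, -dw_), w1 = W - 1 - std::max(0, dw_);
  if (h1 < h0 || w1 < w0) return;
  const int P = H * W, len = h1 - h0 + 1, shift = dw_ * H + dh;
  for (int i = 0; i < nimg; ++i)
    for (int w = w0; w <= w1; ++w) {
      const int c0 = i * P + w * H + h0;
      body(c0, c0 + shift, len);
    }
}

void dw_forward(const mat& D, const mat& x, int H, int W, int nimg, mat& out) {
  const int F = x.n_rows;
  out.zeros(F, x.n_cols);
  for (int k = 0; k < 9; ++k) {
    const double* dk = D.colptr(k);
    dw_sweep(k, H, W, nimg, [&](int co, int ci, int len) {
      double* o = out.memptr() + (size_t)co * F;
      const double* xi = x.memptr() + (size_t)ci * F;
      for (int c = 0; c < len; ++c, o += F, xi += F)
        for (int f = 0; f < F; ++f) o[f] += dk[f] * xi[f];
    });
  }
}

// dD (weights) and dx (data) gradients of a depthwise layer.
void dw_backward(const mat& D, const mat& x, const mat& dout, int H, int W,
                 int nimg, mat& dD, mat& dx) {
  const int F = x.n_rows;
  dx.zeros(F, x.n_cols);
  for (int k = 0; k < 9; ++k) {
    const double* dk = D.colptr(k);
    double* gk = dD.colptr(k);
    dw_sweep(k, H, W, nimg, [&](int co, int ci, int len) {
      const double* go = dout.memptr() + (size_t)co * F;
      const double* xi = x.memptr() + (size_t)ci * F;
      double* dxi = dx.memptr() + (size_t)ci * F;
      for (int c = 0; c < len; ++c, go += F, xi += F, dxi += F)
        for (int f = 0; f < F; ++f) {
          gk[f] += go[f] * xi[f];
          dxi[f] += dk[f] * go[f];
        }
    });
  }
}

struct Cache {
  mat a0pre;
  std::vector<mat> xin, t1, upre, t2, spre;
  mat top;
  rowvec mu, lv;
};

void forward_pass(const Params& pr, const mat& X, int H, int W, int nimg,
                  Cache& ca) {
  const int B = pr.B;
  ca.a0pre = pr.W0 * X;
  ca.a0pre.each_col() += pr.b0;
  mat act = clamp(ca.a0pre, 0.0, datum::inf);
  ca.xin.resize(B); ca.t1.resize(B); ca.upre.resize(B);
  ca.t2.resize(B); ca.spre.resize(B);
  for (int b = 0; b < B; ++b) {
    ca.xin[b] = act;
    dw_forward(pr.D1[b], ca.xin[b], H, W, nimg, ca.t1[b]);
    ca.upre[b] = pr.P1[b] * ca.t1[b];
    ca.upre[b].each_col() += pr.c1[b];
    mat u = clamp(ca.upre[b], 0.0, datum::inf);
    dw_forward(pr.D2[b], u, H, W, nimg, ca.t2[b]);
    mat v = pr.P2[b] * ca.t2[b];
    v.each_col() += pr.c2[b];
    ca.spre[b] = ca.xin[b] + v;
    act = clamp(ca.spre[b], 0.0, datum::inf);
  }
  ca.top = act;
  ca.mu = pr.Wm.t() * ca.top;
  ca.mu += pr.bm;
  ca.lv = pr.Wv.t() * ca.top;
  ca.lv += pr.bv;
}

void backward_pass(const Params& pr, const Cache& ca, const mat& X, int H,
                   int W, int nimg, const rowvec& dmu, const rowvec& dlv,
                   Params& gr, double* gflat) {
  const int B = pr.B, F = pr.F;
  gr.Wm += ca.top * dmu.t();
  gr.Wv += ca.top * dlv.t();
  gflat[off_bm(pr.Cin, F, B)] += accu(dmu);
  gflat[off_bm(pr.Cin, F, B) + F + 1] += accu(dlv);

  mat dtop = pr.Wm * dmu + pr.Wv * dlv;
  mat dx;
  for (int b = B - 1; b >= 0; --b) {
    mat dspre = dtop % conv_to<mat>::from(ca.spre[b] > 0.0);
    gr.P2[b] += dspre * ca.t2[b].t();
    gr.c2[b] += sum(dspre, 1);
    mat dt2 = pr.P2[b].t() * dspre;
    mat u = clamp(ca.upre[b], 0.0, datum::inf);
    dw_backward(pr.D2[b], u, dt2, H, W, nimg, gr.D2[b], dx);
    mat du = dx % conv_to<mat>::from(ca.upre[b] > 0.0);
    gr.P1[b] += du * ca.t1[b].t();
    gr.c1[b] += sum(du, 1);
    mat dt1 = pr.P1[b].t() * du;
    dw_backward(pr.D1[b], ca.xin[b], dt1, H, W, nimg, gr.D1[b], dx);
    dtop = dspre + dx;  // skip connection + branch input
  }
  mat da0 = dtop % conv_to<mat>::from(ca.a0pre > 0.0);
  gr.W0 += da0 * X.t();
  gr.b0 += sum(da0, 1);
}

}  // namespace

// [[Rcpp::export(name = ".cf_n_params")]]
double cf_n_params(int Cin, int F, int B) {
  return (double)n_params(Cin, F, B);
}

// Forward pass over one image. X is Cin x (H*W); returns mean and
// log-variance vectors of length H*W.
// [[Rcpp::export(name = ".cf_forward")]]
List cf_forward(NumericVector params, int Cin, int F, int B,
                const arma::mat& X, int H, int W) {
  if ((int64_t)params.size() != n_params(Cin, F, B))
    Rcpp::stop("parameter vector length does not match the architecture");
  if ((int)X.n_rows != Cin || (int)X.n_cols != H * W)
    Rcpp::stop("input must be Cin x (H*W)");
  Params pr;
  map_params(params.begin(), Cin, F, B, pr);
  Cache ca;
  forward_pass(pr, X, H, W, 1, ca);
  return List::create(
      Rcpp::Named("mu") = NumericVector(ca.mu.begin(), ca.mu.end()),
      Rcpp::Named("logvar") = NumericVector(ca.lv.begin(), ca.lv.end()));
}

// Mini-batch Gaussian-NLL loss and gradient under sparse supervision.
// Xs: list of Cin x (H*W) matrices; idxs: list of 0-based labelled pixel
// indices; ys: list of (normalized) labels; ws: list of per-label loss
// weights (all 1 for the unbalanced loss). Loss is the mean over all
// labelled pixels in the batch of w * ((mu-y)^2/(2*var) + 0.5*log(var)).
// [[Rcpp::export(name = ".cf_batch_grad")]]
List cf_batch_grad(NumericVector params, int Cin, int F, int B, List Xs,
                   List idxs, List ys, List ws, int H, int W) {
  if ((int64_t)params.size() != n_params(Cin, F, B))
    Rcpp::stop("parameter vector length does not match the architecture");
  Params pr;
  map_params(params.begin(), Cin, F, B, pr);
  NumericVector grad(params.size());
  Params gr;
  map_params(grad.begin(), Cin, F, B, gr);

  const int nimg = Xs.size(), P = H * W;
  double ntot = 0;
  for (int i = 0; i < nimg; ++i) ntot += (double)IntegerVector(idxs[i]).size();
  if (ntot < 1) Rcpp::stop("no labelled pixels in batch");

  mat Xall(Cin, (size_t)P * nimg);
  for (int i = 0; i < nimg; ++i) {
    const mat Xi = Rcpp::as<mat>(Xs[i]);
    if ((int)Xi.n_rows != Cin || (int)Xi.n_cols != P)
      Rcpp::stop("every input must be Cin x (H*W)");
    Xall.cols((size_t)i * P, (size_t)(i + 1) * P - 1) = Xi;
  }

  Cache ca;
  forward_pass(pr, Xall, H, W, nimg, ca);

  double loss = 0.0;
  rowvec dmu((size_t)P * nimg, fill::zeros), dlv((size_t)P * nimg, fill::zeros);
  for (int i = 0; i < nimg; ++i) {
    IntegerVector idx = idxs[i];
    NumericVector y = ys[i], w = ws[i];
    for (int j = 0; j < idx.size(); ++j) {
      const size_t p = (size_t)i * P + idx[j];
      const double m = ca.mu(p), lv = ca.lv(p), v = std::exp(lv);
      const double r = m - y[j];
      loss += w[j] * (r * r / (2.0 * v) + 0.5 * lv);
      dmu(p) += w[j] * r / v / ntot;
      dlv(p) += w[j] * (0.5 - r * r / (2.0 * v)) / ntot;
    }
  }
  backward_pass(pr, ca, Xall, H, W, nimg, dmu, dlv, gr, grad.begin());
  loss /= ntot;
  return List::create(Rcpp::Named("loss") = loss, Rcpp::Named("grad") = grad);
}
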