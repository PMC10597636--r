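// Single-precision compute core for the fully convolutional surrogate.
//
// Activations are kept in float32 (BLAS sgemm) for speed on one CPU; the
// parameters cross the R boundary as doubles.  Sequences are stacked
// row-wise with (kernel-1)/2 zero rows of padding between them, so a
// same-padded 1-D convolution is a sum of k shifted GEMMs with no im2col
// buffer and no cross-sequence leakage.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;
using arma::fmat;
using arma::fvec;

namespace {

struct Stacked {
  int L, B, Lp, pad;
  arma::uvec data_rows;  // rows holding real positions
};

fmat to_f(const NumericMatrix& m) {
  arma::mat d = as<arma::mat>(m);
  return arma::conv_to<fmat>::from(d);
}
NumericMatrix to_r(const fmat& m) {
  arma::mat d = arma::conv_to<arma::mat>::from(m);
  return wrap(d);
}

void zero_pad_rows(fmat& A, const Stacked& s) {
  for (int b = 0; b < s.B; ++b) {
    if (s.pad == 0) continue;
    A.rows(b * s.Lp, b * s.Lp + s.pad - 1).zeros();
    A.rows(b * s.Lp + s.pad + s.L, (b + 1) * s.Lp - 1).zeros();
  }
}

// shifted-copy im2col: col block t of `cols` holds A shifted by t - pad
void im2col(const fmat& A, int k, fmat& cols) {
  const int d_in = A.n_cols;
  const int pad = (k - 1) / 2;
  const int R = A.n_rows;
  cols.set_size(R, k * d_in);
  for (int t = 0; t < k; ++t) {
    int o = t - pad;
    int r0 = std::max(0, -o), r1 = R - 1 - std::max(0, o);
    if (r0 > 0) cols.submat(0, t * d_in, r0 - 1, (t + 1) * d_in - 1).zeros();
    if (r1 < R - 1)
      cols.submat(r1 + 1, t * d_in, R - 1, (t + 1) * d_in - 1).zeros();
    if (r0 <= r1)
      cols.submat(r0, t * d_in, r1, (t + 1) * d_in - 1) =
          A.rows(r0 + o, r1 + o);
  }
}

// Y += conv(A) with kernel blocks Wk (k stacked d_in x d_out blocks)
void conv_forward(const fmat& A, const fmat& Wk, int k, fmat& Y,
                  fmat& work) {
  im2col(A, k, work);
  Y = work * Wk;
}

void conv_backward(const fmat& A_in, const fmat& dZ, const fmat& Wk, int k,
                   fmat& dA_in, fmat& gWk, fmat& work) {
  const int d_in = A_in.n_cols;
  const int pad = (k - 1) / 2;
  const int R = A_in.n_rows;
  im2col(A_in, k, work);
  gWk = work.t() * dZ;
  work = dZ * Wk.t();  // R x (k * d_in), fold shifted blocks back
  for (int t = 0; t < k; ++t) {
    int o = t - pad;
    int r0 = std::max(0, -o), r1 = R - 1 - std::max(0, o);
    if (r0 <= r1)
      dA_in.rows(r0 + o, r1 + o) +=
          work.submat(r0, t * d_in, r1, (t + 1) * d_in - 1);
  }
}

Stacked make_stacked(int L, int B, int k) {
  Stacked s;
  s.L = L;
  s.B = B;
  s.pad = (k - 1) / 2;
  s.Lp = L + 2 * s.pad;
  return s;
}

fmat embed_tokens(const IntegerMatrix& tokens, const fmat& E,
                  const Stacked& s) {
  fmat A(s.Lp * s.B, E.n_cols, arma::fill::zeros);
  for (int b = 0; b < s.B; ++b)
    for (int l = 0; l < s.L; ++l)
      A.row(b * s.Lp + s.pad + l) = E.row(tokens(l, b) - 1);
  return A;
}

std::vector<fmat> forward_layers(const fmat& A0, const List& Wl,
                                 const List& bl, int k, const Stacked& s,
                                 fmat& work) {
  const int n_layers = Wl.size();
  std::vector<fmat> acts;
  acts.reserve(n_layers + 1);
  acts.push_back(A0);
  for (int ell = 0; ell < n_layers; ++ell) {
    fmat Wk = to_f(Wl[ell]);
    fvec bv = arma::conv_to<fvec>::from(
        arma::vec(as<NumericVector>(bl[ell]).begin(), Wk.n_cols));
    fmat Y;
    conv_forward(acts.back(), Wk, k, Y, work);
    Y.each_row() += bv.t();
    float* y = Y.memptr();
    const arma::uword ny = Y.n_elem;
    for (arma::uword i = 0; i < ny; ++i)  // ReLU, in place
      if (y[i] < 0.0f) y[i] = 0.0f;
    zero_pad_rows(Y, s);
    acts.push_back(std::move(Y));
  }
  return acts;
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_fcn_predict(IntegerMatrix tokens, NumericMatrix E, List Wl,
                              List bl, NumericVector whead, double bhead,
                              int kernel) {
  const int L = tokens.nrow(), B = tokens.ncol();
  Stacked s = make_stacked(L, B, kernel);
  fmat work;
  fmat A0 = embed_tokens(tokens, to_f(E), s);
  std::vector<fmat> acts = forward_layers(A0, Wl, bl, kernel, s, work);
  fvec wh = arma::conv_to<fvec>::from(arma::vec(whead.begin(), whead.size()));
  fvec pred = acts.back() * wh + (float)bhead;
  NumericMatrix out(L, B);
  for (int b = 0; b < B; ++b)
    for (int l = 0; l < L; ++l) out(l, b) = pred[b * s.Lp + s.pad + l];
  return out;
}

// [[Rcpp::export]]
List cpp_fcn_grad(IntegerMatrix tokens, NumericMatrix E, List Wl, List bl,
                  NumericVector whead, double bhead, int kernel,
                  NumericMatrix targets, NumericMatrix mask) {
  const int L = tokens.nrow(), B = tokens.ncol();
  const int n_layers = Wl.size();
  Stacked s = make_stacked(L, B, kernel);
  fmat work;
  fmat Ef = to_f(E);
  fmat A0 = embed_tokens(tokens, Ef, s);
  std::vector<fmat> acts = forward_layers(A0, Wl, bl, kernel, s, work);
  fvec wh = arma::conv_to<fvec>::from(arma::vec(whead.begin(), whead.size()));
  fvec pred = acts.back() * wh + (float)bhead;

  // masked MSE over valid prediction positions
  double msum = 0.0, loss = 0.0;
  fvec dpred(pred.n_elem, arma::fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int l = 0; l < L; ++l) {
      double m = mask(l, b);
      if (m == 0.0) continue;
      int r = b * s.Lp + s.pad + l;
      double e = (double)pred[r] - targets(l, b);
      loss += m * e * e;
      dpred[r] = (float)(m * e);
      msum += m;
    }
  if (msum <= 0.0) stop("no valid positions in batch");
  loss /= msum;
  dpred *= (float)(2.0 / msum);

  fvec gwhead_f = acts.back().t() * dpred;
  double gbhead = arma::accu(dpred);
  fmat dA = dpred * wh.t();

  List gW(n_layers), gb(n_layers);
  for (int ell = n_layers - 1; ell >= 0; --ell) {
    // ReLU gate: acts[ell+1] stores post-activation values
    {
      float* da = dA.memptr();
      const float* a = acts[ell + 1].memptr();
      const arma::uword ne = dA.n_elem;
      for (arma::uword i = 0; i < ne; ++i)
        if (a[i] <= 0.0f) da[i] = 0.0f;
    }
    zero_pad_rows(dA, s);
    fmat Wk = to_f(Wl[ell]);
    fmat gWk(Wk.n_rows, Wk.n_cols, arma::fill::zeros);
    fmat dA_in(acts[ell].n_rows, acts[ell].n_cols, arma::fill::zeros);
    conv_backward(acts[ell], dA, Wk, kernel, dA_in, gWk, work);
    gW[ell] = to_r(gWk);
    gb[ell] = wrap(arma::conv_to<arma::vec>::from(arma::sum(dA, 0).t()));
    dA = std::move(dA_in);
  }
  // embedding gradient: scatter-add by token
  arma::mat gE(E.nrow(), E.ncol(), arma::fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int l = 0; l < L; ++l) {
      int r = b * s.Lp + s.pad + l;
      gE.row(tokens(l, b) - 1) +=
          arma::conv_to<arma::rowvec>::from(dA.row(r));
    }
  return List::create(
      _["loss"] = loss, _["gE"] = wrap(gE), _["gW"] = gW, _["gb"] = gb,
      _["gwhead"] = wrap(arma::conv_to<arma::vec>::from(gwhead_f)),
      _["gbhead"] = gbhead);
}
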