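// Batched convolution branch (im2col conv + ReLU + argmax pooling) and
// weighted batch normalisation: the non-recurrent hot loops of the
// network.  Row layout convention throughout: a (B*S) x F matrix stores
// position s of example b at row s*B + b.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
Rcpp::List branch_forward_cpp(const arma::cube &x, const arma::mat &Wc,
                              const arma::vec &bc, const int k,
                              const int m) {
  const uword B = x.n_rows, L = x.n_cols, C = x.n_slices;
  const uword S = L - k + 1, P = S / m, F = Wc.n_cols;
  mat M(B * S, (uword)k * C);
  for (uword r = 0; r < (uword)k; ++r) {
    for (uword c = 0; c < C; ++c) {
      M.col(r * C + c) = vectorise(x.slice(c).cols(r, r + S - 1));
    }
  }
  mat Z = M * Wc;
  Z.each_row() += bc.t();
  mat A = clamp(Z, 0.0, datum::inf);
  mat V(B * P, F);
  umat argr(B * P, F);
  for (uword p = 0; p < P; ++p) {
    mat best = A.rows(p * m * B, p * m * B + B - 1);
    umat br(B, F, fill::zeros);
    for (uword r = 1; r < (uword)m; ++r) {
      const mat cand = A.rows((p * m + r) * B, (p * m + r) * B + B - 1);
      const umat upd = cand > best;
      best(find(upd)) = cand(find(upd));
      br(find(upd)).fill(r);
    }
    V.rows(p * B, p * B + B - 1) = best;
    argr.rows(p * B, p * B + B - 1) = br;
  }
  return Rcpp::List::create(Rcpp::_["v"] = V, Rcpp::_["m"] = M,
                            Rcpp::_["z"] = Z, Rcpp::_["argr"] = argr,
                            Rcpp::_["s"] = (double)S, Rcpp::_["p"] = (double)P);
}

// [[Rcpp::export]]
Rcpp::List branch_backward_cpp(const arma::mat &dv, const arma::umat &argr,
                               const arma::mat &Z, const arma::mat &M,
                               const int m, const int B) {
  const uword F = dv.n_cols;
  const uword Bsz = (uword)B;
  const uword Pn = dv.n_rows / Bsz;
  mat dz(Z.n_rows, F, fill::zeros);
  for (uword f = 0; f < F; ++f) {
    for (uword p = 0; p < Pn; ++p) {
      for (uword b = 0; b < Bsz; ++b) {
        const uword r = argr(p * Bsz + b, f);
        dz((p * m + r) * Bsz + b, f) = dv(p * Bsz + b, f);
      }
    }
  }
  dz %= conv_to<mat>::from(Z > 0.0);
  return Rcpp::List::create(Rcpp::_["dWc"] = M.t() * dz,
                            Rcpp::_["dbc"] = sum(dz, 0).t());
}

// [[Rcpp::export]]
Rcpp::List bn_forward_cpp(const arma::mat &x, const arma::vec &gamma,
                          const arma::vec &beta, const double eps,
                          const arma::vec &w) {
  const bool weighted = w.n_elem == x.n_rows;
  const double n = weighted ? accu(w) : (double)x.n_rows;
  rowvec mu = weighted ? sum(x.each_col() % w, 0) / n : sum(x, 0) / n;
  mat xc = x.each_row() - mu;
  if (weighted) xc.each_col() %= w;
  rowvec v = sum(square(xc), 0) / (n - 1.0);
  rowvec s = sqrt(v + eps);
  mat xhat = xc.each_row() / s;
  mat y = xhat.each_row() % (gamma.t());
  y.each_row() += beta.t();
  if (weighted) y.each_col() %= w;
  return Rcpp::List::create(Rcpp::_["y"] = y, Rcpp::_["xhat"] = xhat,
                            Rcpp::_["s"] = s.t(), Rcpp::_["mu"] = mu.t(),
                            Rcpp::_["var"] = v.t(), Rcpp::_["n"] = n);
}

// [[Rcpp::export]]
Rcpp::List bn_backward_cpp(const arma::mat &dy0, const arma::mat &xhat,
                           const arma::vec &s, const double n,
                           const arma::vec &gamma, const arma::vec &w) {
  const bool weighted = w.n_elem == dy0.n_rows;
  mat dy = dy0;
  if (weighted) dy.each_col() %= w;
  rowvec dgamma = sum(dy % xhat, 0);
  rowvec dbeta = sum(dy, 0);
  mat dxhat = dy.each_row() % (gamma.t());
  rowvec st = s.t();
  mat xc = xhat.each_row() % st;
  rowvec dvar = sum(dxhat % xc, 0) % (-0.5 / pow(st, 3));
  rowvec dmu = -sum(dxhat, 0) / st;
  mat dx = dxhat.each_row() / st + xc.each_row() % (2.0 * dvar / (n - 1.0));
  dx.each_row() += dmu / n;
  if (weighted) dx.each_col() %= w;
  return Rcpp::List::create(Rcpp::_["dx"] = dx,
                            Rcpp::_["dgamma"] = dgamma.t(),
                            Rcpp::_["dbeta"] = dbeta.t());
}
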