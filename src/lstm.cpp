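// Peephole LSTM forward/backward over a right-padded batch.
//
// The input projection x_t W_x (bias added here) is precomputed by the
// caller as a (B*T) x 4H matrix whose rows for time t are the contiguous
// block [t*B, (t+1)*B); gate order along the column axis is
// [input | forget | candidate | output].  The per-step 0/1 mask implements
// carry-through semantics: where mask == 0 the cell and hidden state are
// copied from the previous step, so padding is ignored exactly.  With
// reverse = true the steps are scanned in reverse time order (the
// backward direction of a BLSTM); caches are stored in processing order
// and gradients are written back at the true time blocks, so the caller
// never reorders anything.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
Rcpp::List lstm_forward_cpp(const arma::mat &xproj, const arma::vec &bias,
                            const arma::mat &Wh, const arma::mat &peep,
                            const arma::mat &mask, const bool reverse) {
  const uword B = mask.n_rows, T = mask.n_cols, H4 = xproj.n_cols;
  const uword H = H4 / 4;
  const rowvec pi = peep.col(0).t(), pf = peep.col(1).t(),
               po = peep.col(2).t();
  const rowvec bt = bias.t();
  mat Hc(B * T, H), Cc(B * T, H), G(B * T, H4), Tc(B * T, H);
  mat h(B, H, fill::zeros), c(B, H, fill::zeros);
  mat A(B, H4);
  for (uword s = 0; s < T; ++s) {
    const uword t = reverse ? (T - 1 - s) : s;
    A = xproj.rows(t * B, t * B + B - 1);
    A.each_row() += bt;
    A += h * Wh;
    A.cols(0, H - 1) += c.each_row() % pi;
    A.cols(H, 2 * H - 1) += c.each_row() % pf;
    A.cols(0, 2 * H - 1) = 1.0 / (1.0 + exp(-A.cols(0, 2 * H - 1)));
    A.cols(2 * H, 3 * H - 1) = tanh(A.cols(2 * H, 3 * H - 1));
    const mat cn = A.cols(H, 2 * H - 1) % c +
                   A.cols(0, H - 1) % A.cols(2 * H, 3 * H - 1);
    A.cols(3 * H, 4 * H - 1) += cn.each_row() % po;
    A.cols(3 * H, 4 * H - 1) =
        1.0 / (1.0 + exp(-A.cols(3 * H, 4 * H - 1)));
    const mat tcn = tanh(cn);
    const mat hn = A.cols(3 * H, 4 * H - 1) % tcn;
    const vec m = mask.col(t);
    c = cn.each_col() % m + c.each_col() % (1.0 - m);
    h = hn.each_col() % m + h.each_col() % (1.0 - m);
    G.rows(s * B, s * B + B - 1) = A;
    Tc.rows(s * B, s * B + B - 1) = tcn;
    Cc.rows(s * B, s * B + B - 1) = c;
    Hc.rows(s * B, s * B + B - 1) = h;
  }
  return Rcpp::List::create(Rcpp::_["h_final"] = h, Rcpp::_["h"] = Hc,
                            Rcpp::_["c"] = Cc, Rcpp::_["g"] = G,
                            Rcpp::_["tc"] = Tc);
}

// [[Rcpp::export]]
Rcpp::List lstm_backward_cpp(const arma::mat &G, const arma::mat &Cc,
                             const arma::mat &Hc, const arma::mat &Tc,
                             const arma::mat &Wh, const arma::mat &peep,
                             const arma::mat &mask, const arma::mat &dhT,
                             const bool reverse) {
  const uword B = mask.n_rows, T = mask.n_cols, H4 = G.n_cols;
  const uword H = H4 / 4;
  const rowvec pi = peep.col(0).t(), pf = peep.col(1).t(),
               po = peep.col(2).t();
  mat dX(B * T, H4, fill::zeros);
  mat dWh(H, H4, fill::zeros), dpeep(H, 3, fill::zeros);
  mat dh = dhT, dc(B, H, fill::zeros);
  mat dA(B, H4);
  const mat zero(B, H, fill::zeros);
  for (uword s = T; s-- > 0;) {
    const uword t = reverse ? (T - 1 - s) : s;
    const mat cprev =
        (s > 0) ? mat(Cc.rows((s - 1) * B, s * B - 1)) : zero;
    const mat hprev =
        (s > 0) ? mat(Hc.rows((s - 1) * B, s * B - 1)) : zero;
    const auto i = G(span(s * B, s * B + B - 1), span(0, H - 1));
    const auto f = G(span(s * B, s * B + B - 1), span(H, 2 * H - 1));
    const auto g = G(span(s * B, s * B + B - 1), span(2 * H, 3 * H - 1));
    const auto o = G(span(s * B, s * B + B - 1), span(3 * H, 4 * H - 1));
    const mat tc = Tc.rows(s * B, s * B + B - 1);
    const vec m = mask.col(t);
    const mat dh_eff = dh.each_col() % m;
    const mat dc_eff = dc.each_col() % m;
    mat da_o = dh_eff % tc % o % (1.0 - o);
    const mat dct =
        dc_eff + dh_eff % o % (1.0 - tc % tc) + da_o.each_row() % po;
    dA.cols(0, H - 1) = dct % g % i % (1.0 - i);
    dA.cols(H, 2 * H - 1) = dct % cprev % f % (1.0 - f);
    dA.cols(2 * H, 3 * H - 1) = dct % i % (1.0 - g % g);
    dA.cols(3 * H, 4 * H - 1) = da_o;
    dX.rows(t * B, t * B + B - 1) = dA;
    dWh += hprev.t() * dA;
    dpeep.col(0) += sum(dA.cols(0, H - 1) % cprev, 0).t();
    dpeep.col(1) += sum(dA.cols(H, 2 * H - 1) % cprev, 0).t();
    dpeep.col(2) += sum(da_o % Cc.rows(s * B, s * B + B - 1), 0).t();
    dh = dh.each_col() % (1.0 - m) + dA * Wh.t();
    dc = dc.each_col() % (1.0 - m) + dct % f +
         dA.cols(0, H - 1).eval().each_row() % pi +
         dA.cols(H, 2 * H - 1).eval().each_row() % pf;
  }
  return Rcpp::List::create(Rcpp::_["dx"] = dX, Rcpp::_["dWh"] = dWh,
                            Rcpp::_["dpeep"] = dpeep);
}
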