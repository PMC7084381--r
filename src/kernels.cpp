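// Compiled kernels for the training hot path: the LSTM recurrence
// (forward and backward-through-time) and a fused in-place Adam update.
// Only the sequential per-timestep work lives here; everything that can
// be expressed as one large BLAS call stays in R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// idx: n_sent x t_max matrix of 1-based flat token rows, 0 = no token.
// Returns the per-token caches needed for backward-through-time.
// [[Rcpp::export(name = ".lstm_forward_cpp")]]
List lstm_forward_cpp(const arma::mat& input, const arma::imat& idx,
                      const arma::mat& wx, const arma::mat& wh,
                      const arma::vec& b, const int h, const bool cache) {
  const arma::uword n = idx.n_rows, t_max = idx.n_cols;
  const arma::uword n_tok = input.n_rows, h4 = 4 * (arma::uword)h;
  arma::mat xproj = input * wx;
  xproj.each_row() += b.t();
  arma::mat h_state(n, h, arma::fill::zeros);
  arma::mat c_state(n, h, arma::fill::zeros);
  arma::mat h_out(n_tok, h, arma::fill::zeros);
  arma::mat gates, tc_all, h_prev_all, c_prev_all;
  if (cache) {
    gates.zeros(n_tok, h4);
    tc_all.zeros(n_tok, h);
    h_prev_all.zeros(n_tok, h);
    c_prev_all.zeros(n_tok, h);
  }
  for (arma::uword t = 0; t < t_max; ++t) {
    arma::uvec act = arma::find(idx.col(t) > 0);
    if (act.n_elem == 0) continue;
    arma::uvec rws(act.n_elem);
    for (arma::uword i = 0; i < act.n_elem; ++i)
      rws(i) = (arma::uword)idx(act(i), t) - 1;
    arma::mat h_prev = h_state.rows(act);
    arma::mat c_prev = c_state.rows(act);
    arma::mat a = xproj.rows(rws) + h_prev * wh;
    // gate order: input, forget, output, candidate
    a.cols(0, 3 * h - 1) =
      1.0 / (1.0 + arma::exp(-a.cols(0, 3 * h - 1)));
    a.cols(3 * h, h4 - 1) = arma::tanh(a.cols(3 * h, h4 - 1));
    arma::mat c_new = a.cols(h, 2 * h - 1) % c_prev +
      a.cols(0, h - 1) % a.cols(3 * h, h4 - 1);
    arma::mat tc = arma::tanh(c_new);
    arma::mat h_new = a.cols(2 * h, 3 * h - 1) % tc;
    h_state.rows(act) = h_new;
    c_state.rows(act) = c_new;
    h_out.rows(rws) = h_new;
    if (cache) {
      gates.rows(rws) = a;
      tc_all.rows(rws) = tc;
      h_prev_all.rows(rws) = h_prev;
      c_prev_all.rows(rws) = c_prev;
    }
  }
  if (!cache) return List::create(Named("h_out") = h_out);
  return List::create(Named("h_out") = h_out, Named("gates") = gates,
                      Named("tc") = tc_all, Named("h_prev") = h_prev_all,
                      Named("c_prev") = c_prev_all);
}

// [[Rcpp::export(name = ".lstm_backward_cpp")]]
List lstm_backward_cpp(const arma::mat& d_h_out, const List fwd,
                       const arma::mat& input, const arma::imat& idx,
                       const arma::mat& wx, const arma::mat& wh,
                       const int h) {
  const arma::mat& gates = fwd["gates"];
  const arma::mat& tc_all = fwd["tc"];
  const arma::mat& h_prev_all = fwd["h_prev"];
  const arma::mat& c_prev_all = fwd["c_prev"];
  const arma::uword n = idx.n_rows, t_max = idx.n_cols;
  const arma::uword h4 = 4 * (arma::uword)h;
  arma::mat dh_state(n, h, arma::fill::zeros);
  arma::mat dc_state(n, h, arma::fill::zeros);
  arma::mat d_xproj(input.n_rows, h4, arma::fill::zeros);
  for (arma::uword tt = t_max; tt-- > 0;) {
    arma::uvec act = arma::find(idx.col(tt) > 0);
    if (act.n_elem == 0) continue;
    arma::uvec rws(act.n_elem);
    for (arma::uword i = 0; i < act.n_elem; ++i)
      rws(i) = (arma::uword)idx(act(i), tt) - 1;
    arma::mat g = gates.rows(rws);
    arma::mat tc = tc_all.rows(rws);
    arma::mat i_g = g.cols(0, h - 1);
    arma::mat f_g = g.cols(h, 2 * h - 1);
    arma::mat o_g = g.cols(2 * h, 3 * h - 1);
    arma::mat g_g = g.cols(3 * h, h4 - 1);
    arma::mat dh = dh_state.rows(act) + d_h_out.rows(rws);
    arma::mat dc = dc_state.rows(act) + dh % o_g % (1.0 - tc % tc);
    arma::mat da(act.n_elem, h4);
    da.cols(0, h - 1) = (dc % g_g) % i_g % (1.0 - i_g);
    da.cols(h, 2 * h - 1) =
      (dc % c_prev_all.rows(rws)) % f_g % (1.0 - f_g);
    da.cols(2 * h, 3 * h - 1) = (dh % tc) % o_g % (1.0 - o_g);
    da.cols(3 * h, h4 - 1) = (dc % i_g) % (1.0 - g_g % g_g);
    d_xproj.rows(rws) = da;
    dh_state.rows(act) = da * wh.t();
    dc_state.rows(act) = dc % f_g;
  }
  return List::create(
    Named("d_input") = arma::mat(d_xproj * wx.t()),
    Named("d_Wx") = arma::mat(input.t() * d_xproj),
    Named("d_Wh") = arma::mat(h_prev_all.t() * d_xproj),
    Named("d_b") = arma::rowvec(arma::sum(d_xproj, 0)));
}

// Fused Adam update, in place.  The trainer owns `par`, `m` and `v`
// exclusively (it deep-copies the parameters before the first step), so
// mutating their storage directly is safe and avoids reallocating the
// full parameter set on every step.
// [[Rcpp::export(name = ".adam_update_cpp")]]
void adam_update_cpp(List par, const List grads, List m, List v,
                     const double lr, const double beta1,
                     const double beta2, const double eps, const int t) {
  const double bc1 = 1.0 - std::pow(beta1, t);
  const double bc2 = 1.0 - std::pow(beta2, t);
  const double c1 = lr * std::sqrt(bc2) / bc1;
  const double c2 = eps * std::sqrt(bc2);
  for (int i = 0; i < par.size(); ++i) {
    NumericVector p = par[i], g = grads[i], mi = m[i], vi = v[i];
    const R_xlen_t len = p.size();
    double* pp = REAL(p); const double* gp = REAL(g);
    double* mp = REAL(mi); double* vp = REAL(vi);
    for (R_xlen_t j = 0; j < len; ++j) {
      mp[j] = beta1 * mp[j] + (1.0 - beta1) * gp[j];
      vp[j] = beta2 * vp[j] + (1.0 - beta2) * gp[j] * gp[j];
      pp[j] -= c1 * mp[j] / (std::sqrt(vp[j]) + c2);
    }
  }
}
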