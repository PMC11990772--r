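#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Symmetrized (community-enhanced) InfoNCE over two views' row-normalized
// embeddings. For each anchor i in view 1, the positive is spot i in view
// 2 and the negatives are all other spots of both views; the two view
// directions are averaged. `bonus` is a per-spot vector b adding b_i + b_j
// to every similarity term (empty = none). A single global shift keeps the
// exponentials bounded (cosine similarities are bounded, so no per-row
// shift is needed).
template <typename eT>
static double infonce_core(const Mat<eT>& U1, const Mat<eT>& U2, eT tau,
                           const Col<eT>& bonus, bool grad,
                           Mat<eT>& dU1, Mat<eT>& dU2) {
  const uword n = U1.n_rows;
  Mat<eT> S11 = U1 * U1.t() / tau;
  Mat<eT> S22 = U2 * U2.t() / tau;
  Mat<eT> T12 = U2 * U1.t() / tau;  // T12(j, i) = s12(i, j)
  if (bonus.n_elem == n) {
    S11.each_col() += bonus;  S11.each_row() += bonus.t();
    S22.each_col() += bonus;  S22.each_row() += bonus.t();
    T12.each_col() += bonus;  T12.each_row() += bonus.t();
  }
  const eT smax = std::max(S11.max(), std::max(S22.max(), T12.max()));
  Col<eT> pos = T12.diag();
  Mat<eT> E11 = exp(S11 - smax);
  E11.diag().zeros();  // intra-view sum excludes j == i
  Mat<eT> E22 = exp(S22 - smax);
  E22.diag().zeros();
  Mat<eT> ET = exp(T12 - smax);
  Col<eT> denom1 = (sum(E11, 0) + sum(ET, 0)).t();  // anchors of view 1
  Col<eT> denom2 = sum(E22, 0).t() + sum(ET, 1);    // anchors of view 2
  double loss = 0.5 * (accu(-pos + smax + log(denom1)) +
                       accu(-pos + smax + log(denom2))) / n;
  if (!grad) return loss;

  const eT sc = eT(1) / (eT(2) * n);
  Col<eT> inv1 = sc / denom1;
  Col<eT> inv2 = sc / denom2;
  // N(j, i) = softmax weight of pair (i, j) summed over both directions;
  // N^T is the gradient wrt the cross-view similarity matrix s12.
  Mat<eT> N = ET.each_row() % inv1.t();
  N += ET.each_col() % inv2;
  N.diag() -= eT(2) * sc;
  Mat<eT> A11 = E11.each_row() % inv1.t();
  Mat<eT> sym11 = A11 + A11.t();
  Mat<eT> A22 = E22.each_row() % inv2.t();
  Mat<eT> sym22 = A22 + A22.t();
  dU1 = (N.t() * U2 + sym11 * U1) / tau;
  dU2 = (N * U1 + sym22 * U2) / tau;
  return loss;
}

// [[Rcpp::export]]
Rcpp::List cpp_infonce(const arma::mat& U1, const arma::mat& U2,
                       double tau, const arma::vec& bonus, bool grad,
                       bool single = false) {
  if (!single) {
    mat dU1, dU2;
    double loss = infonce_core<double>(U1, U2, tau, bonus, grad, dU1, dU2);
    if (!grad) return Rcpp::List::create(Rcpp::Named("loss") = loss);
    return Rcpp::List::create(Rcpp::Named("loss") = loss,
                              Rcpp::Named("dU1") = dU1,
                              Rcpp::Named("dU2") = dU2);
  }
  fmat U1f = conv_to<fmat>::from(U1);
  fmat U2f = conv_to<fmat>::from(U2);
  fvec bf = conv_to<fvec>::from(bonus);
  fmat dU1, dU2;
  double loss = infonce_core<float>(U1f, U2f, float(tau), bf, grad,
                                    dU1, dU2);
  if (!grad) return Rcpp::List::create(Rcpp::Named("loss") = loss);
  return Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("dU1") = conv_to<mat>::from(dU1),
    Rcpp::Named("dU2") = conv_to<mat>::from(dU2));
}

// Spatial similarity constraint: sum_ij Dsn_ij (1 - Dz_ij) / n^2 with Dsn
// the pre-normalized spatial distances and Dz the embedding distances
// scaled by their maximum over all pairs (the minimum over evaluated pairs
// is 0 on the diagonal). The normalizing maximum is treated as a constant
// in the gradient.
template <typename eT>
static double within_core(const Mat<eT>& Z, const arma::mat& Dsn, bool grad,
                          Mat<eT>& dZ) {
  const uword n = Z.n_rows;
  const double n2 = double(n) * double(n);
  Col<eT> sq = sum(square(Z), 1);
  Mat<eT> d = Z * Z.t();
  eT dmax = 0;
  for (uword j = 0; j < n; ++j) {
    eT* cj = d.colptr(j);
    for (uword i = 0; i < n; ++i) {
      eT v = sq[i] + sq[j] - eT(2) * cj[i];
      v = v > 0 ? std::sqrt(v) : eT(0);
      cj[i] = v;
      if (v > dmax) dmax = v;
    }
  }
  if (dmax <= 0) {
    if (grad) dZ.zeros(n, Z.n_cols);
    return accu(Dsn) / n2;
  }
  double loss = 0.0;
  if (!grad) {
    for (uword j = 0; j < n; ++j) {
      const eT* cj = d.colptr(j);
      const double* sj = Dsn.colptr(j);
      for (uword i = 0; i < n; ++i)
        loss += sj[i] * (1.0 - double(cj[i]) / dmax);
    }
    return loss / n2;
  }
  // reuse d's storage for M_ij = Dsn_ij / (n^2 dmax d_ij), zero when d = 0
  const double c0 = 1.0 / (n2 * double(dmax));
  for (uword j = 0; j < n; ++j) {
    eT* cj = d.colptr(j);
    const double* sj = Dsn.colptr(j);
    for (uword i = 0; i < n; ++i) {
      double dij = cj[i];
      loss += sj[i] * (1.0 - dij / dmax);
      cj[i] = dij > 0 ? eT(sj[i] * c0 / dij) : eT(0);
    }
  }
  Col<eT> rs = sum(d, 1);
  dZ = eT(-2) * (Z.each_col() % rs - d * Z);
  return loss / n2;
}

// [[Rcpp::export]]
Rcpp::List cpp_within(const arma::mat& Z, const arma::mat& Dsn, bool grad,
                      bool single = false) {
  if (!single) {
    mat dZ;
    double loss = within_core<double>(Z, Dsn, grad, dZ);
    if (!grad) return Rcpp::List::create(Rcpp::Named("loss") = loss);
    return Rcpp::List::create(Rcpp::Named("loss") = loss,
                              Rcpp::Named("dZ") = dZ);
  }
  fmat Zf = conv_to<fmat>::from(Z);
  fmat dZ;
  double loss = within_core<float>(Zf, Dsn, grad, dZ);
  if (!grad) return Rcpp::List::create(Rcpp::Named("loss") = loss);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("dZ") = conv_to<mat>::from(dZ));
}
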