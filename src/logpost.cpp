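// Compiled hot path for the non-centered multi-trait animal-model
// log-posterior and gradient. Mirrors the R reference implementation in
// R/model_core.R exactly (same parameter layout, same Jacobian
// bookkeeping); agreement between the two paths is asserted in the test
// suite.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Canonical-partial-correlation forward map for one correlation Cholesky
// factor. u is row-wise (rows 2..t). Returns false if a diagonal
// underflows.
static bool corr_forward(const vec& u, int t, mat& L, double& logJ) {
  L.eye(t, t);
  logJ = 0.0;
  int k = 0;
  for (int i = 1; i < t; ++i) {
    double w = 1.0;
    for (int j = 0; j < i; ++j) {
      double z = std::tanh(u(k++));
      double s = std::sqrt(w);
      L(i, j) = z * s;
      logJ += std::log1p(-z * z) + 0.5 * std::log(w);
      w -= L(i, j) * L(i, j);
    }
    if (w <= 0.0) return false;
    L(i, i) = std::sqrt(w);
  }
  return true;
}

// Reverse-mode pass through the forward recursion; adds the gradient of
// the transform log-Jacobian. gL holds df/dL on the lower triangle.
static void corr_backward(const vec& u, int t, const mat& gL, vec& gu) {
  int k = 0;
  for (int i = 1; i < t; ++i) {
    int m = i;
    vec zi(m), w(m + 1), Lrow(m);
    for (int j = 0; j < m; ++j) zi(j) = std::tanh(u(k + j));
    w(0) = 1.0;
    for (int j = 0; j < m; ++j) {
      Lrow(j) = zi(j) * std::sqrt(w(j));
      w(j + 1) = w(j) - Lrow(j) * Lrow(j);
    }
    vec gw(m + 1, fill::zeros);
    gw(m) = gL(i, i) * 0.5 / std::sqrt(w(m));
    for (int j = m - 1; j >= 0; --j) {
      double gLj = gL(i, j) - 2.0 * Lrow(j) * gw(j + 1);
      double gwj = gw(j + 1) + 0.5 / w(j);        // jacobian d(0.5 log w_j)
      double sj = std::sqrt(w(j));
      double gz = gLj * sj;
      gwj += gLj * zi(j) * 0.5 / sj;
      gw(j) = gwj;
      gu(k + j) = gz * (1.0 - zi(j) * zi(j)) - 2.0 * zi(j);
    }
    k += m;
  }
}

// [[Rcpp::export(name = ".logpost_cpp")]]
Rcpp::List logpost_cpp(const arma::vec& u, const arma::mat& ytilde,
                       const arma::vec& cvec, const arma::vec& sqrt_d,
                       int kind, double eta, double cauchy_scale,
                       const arma::mat& PsiA, const arma::mat& PsiE,
                       double vA, double vE) {
  const int n = ytilde.n_rows, t = ytilde.n_cols;
  const int m = t * (t - 1) / 2;
  const int nt = n * t;
  const double log2pi = std::log(2.0 * M_PI);

  // layout: z_a | log_sd_a | log_sd_e | u_corr_a | u_corr_e | mu
  mat Z(const_cast<double*>(u.memptr()), n, t, false, true);
  vec lsa = u.subvec(nt, nt + t - 1);
  vec lse = u.subvec(nt + t, nt + 2 * t - 1);
  vec ua = (m > 0) ? u.subvec(nt + 2 * t, nt + 2 * t + m - 1) : vec();
  vec ue = (m > 0) ? u.subvec(nt + 2 * t + m, nt + 2 * t + 2 * m - 1) : vec();
  vec mu = u.subvec(nt + 2 * t + 2 * m, nt + 2 * t + 2 * m + t - 1);

  vec sa = exp(lsa), se = exp(lse);
  mat La, Le;
  double logJa, logJe;
  bool oka = corr_forward(ua, t, La, logJa);
  bool oke = corr_forward(ue, t, Le, logJe);
  if (!oka || !oke || !sa.is_finite() || !se.is_finite() ||
      sa.min() <= 0.0 || se.min() <= 0.0) {
    return Rcpp::List::create(Rcpp::Named("logp") = R_NegInf,
                              Rcpp::Named("grad") = vec(u.n_elem, fill::zeros));
  }

  mat Ba = La.each_col() % sa;
  mat Be = Le.each_col() % se;

  mat P = Z.each_col() % sqrt_d;
  mat E = ytilde - P * Ba.t() - cvec * mu.t();
  mat Binv_e = inv(trimatl(Be));
  mat W = Binv_e.t() * Binv_e;
  mat EW = E * W;

  double loglik = -0.5 * n * t * log2pi - n * accu(log(Be.diag())) -
    0.5 * accu(EW % E);
  double logp_z = -0.5 * n * t * log2pi - 0.5 * accu(Z % Z);
  double logJ = accu(lsa) + accu(lse) + logJa + logJe;

  mat EWBa = EW * Ba;
  mat gZ = (EWBa.each_col() % sqrt_d) - Z;
  vec gmu = EW.t() * cvec;
  mat gBa = EW.t() * P;
  mat S = E.t() * E;
  mat gBe = W * S * W * Be;
  gBe.diag() -= n / Be.diag();

  vec glsa(t, fill::zeros), glse(t, fill::zeros);
  mat gLa(t, t, fill::zeros), gLe(t, t, fill::zeros);
  double logprior;

  if (kind == 0) {  // LKJ-Cholesky + half-Cauchy
    double cs = cauchy_scale;
    double lp_corr = 0.0;
    for (int i = 1; i < t; ++i) {
      double co = t - (i + 1) + 2.0 * eta - 2.0;
      lp_corr += co * (std::log(La(i, i)) + std::log(Le(i, i)));
      gLa(i, i) += co / La(i, i);
      gLe(i, i) += co / Le(i, i);
    }
    double lp_sd = 0.0;
    for (int i = 0; i < t; ++i) {
      lp_sd += 2.0 * (std::log(2.0) - std::log(M_PI * cs));
      lp_sd -= std::log1p(sa(i) * sa(i) / (cs * cs));
      lp_sd -= std::log1p(se(i) * se(i) / (cs * cs));
      glsa(i) -= 2.0 * sa(i) * sa(i) / (cs * cs + sa(i) * sa(i));
      glse(i) -= 2.0 * se(i) * se(i) / (cs * cs + se(i) * se(i));
    }
    logprior = lp_corr + lp_sd;
  } else {          // inverse-Wishart with factorization Jacobian
    mat Binv_a = inv(trimatl(Ba));
    mat Wg = Binv_a.t() * Binv_a;
    double logdetG = 2.0 * accu(lsa) + 2.0 * accu(log(La.diag()));
    double logdetR = 2.0 * accu(lse) + 2.0 * accu(log(Le.diag()));
    double lp_G = -0.5 * (vA + t + 1) * logdetG - 0.5 * accu(Wg % PsiA);
    double lp_R = -0.5 * (vE + t + 1) * logdetR - 0.5 * accu(W % PsiE);
    double jac = t * (accu(lsa) + accu(lse)) + 2.0 * t * std::log(2.0);
    for (int i = 0; i < t; ++i) {
      double co = t - (i + 1);
      jac += co * (std::log(La(i, i)) + std::log(Le(i, i)));
      gLa(i, i) += (-(vA + t + 1) + co) / La(i, i);
      gLe(i, i) += (-(vE + t + 1) + co) / Le(i, i);
    }
    logprior = lp_G + lp_R + jac;
    glsa += (-(vA + t + 1) + t) * vec(t, fill::ones);
    glse += (-(vE + t + 1) + t) * vec(t, fill::ones);
    gBa += Wg * PsiA * Wg * Ba;
    gBe += W * PsiE * W * Be;
  }

  gBa = trimatl(gBa);
  gBe = trimatl(gBe);
  glsa += sum(gBa % Ba, 1) + 1.0;      // +1: exp-transform Jacobian
  glse += sum(gBe % Be, 1) + 1.0;
  gLa += gBa.each_col() % sa;
  gLe += gBe.each_col() % se;
  vec gua(m, fill::zeros), gue(m, fill::zeros);
  if (m > 0) {
    corr_backward(ua, t, gLa, gua);
    corr_backward(ue, t, gLe, gue);
  }

  vec grad(u.n_elem);
  grad.subvec(0, nt - 1) = vectorise(gZ);
  grad.subvec(nt, nt + t - 1) = glsa;
  grad.subvec(nt + t, nt + 2 * t - 1) = glse;
  if (m > 0) {
    grad.subvec(nt + 2 * t, nt + 2 * t + m - 1) = gua;
    grad.subvec(nt + 2 * t + m, nt + 2 * t + 2 * m - 1) = gue;
  }
  grad.subvec(nt + 2 * t + 2 * m, nt + 2 * t + 2 * m + t - 1) = gmu;

  double logp = loglik + logp_z + logprior + logJ;
  return Rcpp::List::create(Rcpp::Named("logp") = logp,
                            Rcpp::Named("grad") = grad);
}
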