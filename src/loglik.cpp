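#include <Rcpp.h>
using namespace Rcpp;

// Parameter layout (length J + 12):
// beta0, beta_x[J], beta_g, beta_m, beta_e, alpha0, alpha_g,
// gamma0, gamma_g, gamma_m, sigma1_sq, sigma2_sq, p
//
// scheme codes per row: 0 complete, 1 expression missing,
// 2 methylation missing, 3 both missing.
//
// Complete rows use the exact logistic phenotype term; rows with a missing
// omics layer use the probit-approximated marginalized probability, whose
// denominator absorbs the marginal variance of the integrated-out layer.

static double negloglik_impl(const NumericVector& par,
                             const NumericVector& y,
                             const NumericMatrix& X,
                             const NumericVector& G,
                             const NumericVector& M,
                             const NumericVector& E,
                             const IntegerVector& scheme) {
  const int n = y.size();
  const int J = X.ncol();
  const double beta0 = par[0];
  const double beta_g = par[J + 1], beta_m = par[J + 2], beta_e = par[J + 3];
  const double alpha0 = par[J + 4], alpha_g = par[J + 5];
  const double gamma0 = par[J + 6], gamma_g = par[J + 7], gamma_m = par[J + 8];
  // Clamp just inside the admissible region so finite-difference probes a
  // hair outside the optimizer's box stay finite.
  const double s1 = std::max(par[J + 9], 1e-10);
  const double s2 = std::max(par[J + 10], 1e-10);
  const double p = std::min(std::max(par[J + 11], 1e-12), 1.0 - 1e-12);
  const double ab = M_PI / sqrt(3.0);
  const double ab2 = ab * ab;
  const double sd1 = sqrt(s1), sd2 = sqrt(s2);
  const double vE = s2 + gamma_m * gamma_m * s1;     // Var(E | G)
  const double sdE = sqrt(vE);
  const double vM = s1 * s2 / vE;                    // Var(M | E, G)
  const double bem = beta_e * gamma_m + beta_m;
  const double den1 = sqrt(ab2 + beta_e * beta_e * s2);
  const double den2 = sqrt(ab2 + beta_m * beta_m * vM);
  const double den3 = sqrt(ab2 + beta_e * beta_e * s2 + bem * bem * s1);
  const double lp = log(p), lq = log1p(-p);

  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double xb = beta0;
    for (int j = 0; j < J; ++j) xb += par[1 + j] * X(i, j);
    const double g = G[i];
    const double muM = alpha0 + alpha_g * g;
    // Binomial(2, p) genotype mass
    ll += (g == 1.0 ? M_LN2 : 0.0) + g * lp + (2.0 - g) * lq;
    switch (scheme[i]) {
    case 0: {
      const double eta = xb + beta_g * g + beta_m * M[i] + beta_e * E[i];
      ll += R::plogis(y[i] * eta, 0.0, 1.0, 1, 1);
      ll += R::dnorm(E[i], gamma0 + gamma_g * g + gamma_m * M[i], sd2, 1);
      ll += R::dnorm(M[i], muM, sd1, 1);
      break;
    }
    case 1: {  // expression integrated out
      const double mu0 = gamma0 + gamma_g * g + gamma_m * M[i];
      const double eta = xb + beta_g * g + beta_m * M[i] + beta_e * mu0;
      ll += R::pnorm(y[i] * eta / den1, 0.0, 1.0, 1, 1);
      ll += R::dnorm(M[i], muM, sd1, 1);
      break;
    }
    case 2: {  // methylation integrated out
      const double mc = (muM * s2 +
                         gamma_m * (E[i] - gamma0 - gamma_g * g) * s1) / vE;
      const double eta = xb + beta_g * g + beta_e * E[i] + beta_m * mc;
      ll += R::pnorm(y[i] * eta / den2, 0.0, 1.0, 1, 1);
      ll += R::dnorm(E[i], gamma0 + gamma_g * g + gamma_m * muM, sdE, 1);
      break;
    }
    default: {  // both integrated out
      const double eta = xb + beta_g * g +
        beta_e * (gamma0 + gamma_g * g) + bem * muM;
      ll += R::pnorm(y[i] * eta / den3, 0.0, 1.0, 1, 1);
    }
    }
  }
  return -ll;
}

// [[Rcpp::export]]
double cpp_negloglik(NumericVector par, NumericVector y, NumericMatrix X,
                     NumericVector G, NumericVector M, NumericVector E,
                     IntegerVector scheme) {
  return negloglik_impl(par, y, X, G, M, E, scheme);
}

// Central finite-difference gradient over the free coordinates only.
// [[Rcpp::export]]
NumericVector cpp_negloglik_grad(NumericVector par, IntegerVector free_idx,
                                 NumericVector y, NumericMatrix X,
                                 NumericVector G, NumericVector M,
                                 NumericVector E, IntegerVector scheme) {
  const int k = free_idx.size();
  NumericVector grad(k);
  NumericVector work = clone(par);
  for (int j = 0; j < k; ++j) {
    const int idx = free_idx[j];            // 0-based
    const double x0 = work[idx];
    const double h = 1e-6 * (1.0 + fabs(x0));
    work[idx] = x0 + h;
    const double fp = negloglik_impl(work, y, X, G, M, E, scheme);
    work[idx] = x0 - h;
    const double fm = negloglik_impl(work, y, X, G, M, E, scheme);
    work[idx] = x0;
    grad[j] = (fp - fm) / (2.0 * h);
  }
  return grad;
}

// Analytic gradient of the negative log-likelihood over the full parameter
// vector. The finite-difference version above doubles as its test oracle.
// [[Rcpp::export]]
NumericVector cpp_negloglik_agrad(NumericVector par, NumericVector y,
                                  NumericMatrix X, NumericVector G,
                                  NumericVector M, NumericVector E,
                                  IntegerVector scheme) {
  const int n = y.size();
  const int J = X.ncol();
  const int np = J + 12;
  const double beta0 = par[0];
  const double beta_g = par[J + 1], beta_m = par[J + 2], beta_e = par[J + 3];
  const double alpha0 = par[J + 4], alpha_g = par[J + 5];
  const double gamma0 = par[J + 6], gamma_g = par[J + 7], gamma_m = par[J + 8];
  const double s1 = std::max(par[J + 9], 1e-10);
  const double s2 = std::max(par[J + 10], 1e-10);
  const double p = std::min(std::max(par[J + 11], 1e-12), 1.0 - 1e-12);
  const int iB0 = 0, iBG = J + 1, iBM = J + 2, iBE = J + 3,
    iA0 = J + 4, iAG = J + 5, iG0 = J + 6, iGG = J + 7, iGM = J + 8,
    iS1 = J + 9, iS2 = J + 10, iP = J + 11;
  const double ab = M_PI / sqrt(3.0), ab2 = ab * ab;
  const double sd1 = sqrt(s1), sd2 = sqrt(s2);
  const double vE = s2 + gamma_m * gamma_m * s1;
  const double vM = s1 * s2 / vE;
  const double bem = beta_e * gamma_m + beta_m;
  const double den1 = sqrt(ab2 + beta_e * beta_e * s2);
  const double den2 = sqrt(ab2 + beta_m * beta_m * vM);
  const double den3 = sqrt(ab2 + beta_e * beta_e * s2 + bem * bem * s1);

  NumericVector grad(np);  // gradient of +loglik; negated at the end

  for (int i = 0; i < n; ++i) {
    double xb = beta0;
    for (int j = 0; j < J; ++j) xb += par[1 + j] * X(i, j);
    const double g = G[i];
    const double muM = alpha0 + alpha_g * g;
    grad[iP] += g / p - (2.0 - g) / (1.0 - p);

    switch (scheme[i]) {
    case 0: {
      const double eta = xb + beta_g * g + beta_m * M[i] + beta_e * E[i];
      const double w = y[i] * (1.0 - R::plogis(y[i] * eta, 0.0, 1.0, 1, 0));
      grad[iB0] += w;
      for (int j = 0; j < J; ++j) grad[1 + j] += w * X(i, j);
      grad[iBG] += w * g; grad[iBM] += w * M[i]; grad[iBE] += w * E[i];
      const double r2 = E[i] - gamma0 - gamma_g * g - gamma_m * M[i];
      grad[iG0] += r2 / s2; grad[iGG] += r2 * g / s2;
      grad[iGM] += r2 * M[i] / s2;
      grad[iS2] += -0.5 / s2 + r2 * r2 / (2.0 * s2 * s2);
      const double r1 = M[i] - muM;
      grad[iA0] += r1 / s1; grad[iAG] += r1 * g / s1;
      grad[iS1] += -0.5 / s1 + r1 * r1 / (2.0 * s1 * s1);
      break;
    }
    case 1: {  // E missing
      const double mu0 = gamma0 + gamma_g * g + gamma_m * M[i];
      const double eta = xb + beta_g * g + beta_m * M[i] + beta_e * mu0;
      const double z = y[i] * eta / den1;
      const double mills = exp(R::dnorm(z, 0.0, 1.0, 1) -
                               R::pnorm(z, 0.0, 1.0, 1, 1));
      const double base = mills * y[i] / den1;            // d/d eta
      const double dzden = -mills * z / den1;             // d/d den1
      grad[iB0] += base;
      for (int j = 0; j < J; ++j) grad[1 + j] += base * X(i, j);
      grad[iBG] += base * g; grad[iBM] += base * M[i];
      grad[iBE] += base * mu0 + dzden * beta_e * s2 / den1;
      grad[iG0] += base * beta_e; grad[iGG] += base * beta_e * g;
      grad[iGM] += base * beta_e * M[i];
      grad[iS2] += dzden * beta_e * beta_e / (2.0 * den1);
      const double r1 = M[i] - muM;
      grad[iA0] += r1 / s1; grad[iAG] += r1 * g / s1;
      grad[iS1] += -0.5 / s1 + r1 * r1 / (2.0 * s1 * s1);
      break;
    }
    case 2: {  // M missing
      const double r = E[i] - gamma0 - gamma_g * g;
      const double num = muM * s2 + gamma_m * r * s1;
      const double mc = num / vE;
      const double eta = xb + beta_g * g + beta_e * E[i] + beta_m * mc;
      const double z = y[i] * eta / den2;
      const double mills = exp(R::dnorm(z, 0.0, 1.0, 1) -
                               R::pnorm(z, 0.0, 1.0, 1, 1));
      const double base = mills * y[i] / den2;
      const double dzden = -mills * z / den2;
      // mc partials
      const double mc_a0 = s2 / vE, mc_ag = g * s2 / vE;
      const double mc_g0 = -gamma_m * s1 / vE, mc_gg = -gamma_m * g * s1 / vE;
      const double mc_gm = (r * s1 * vE - num * 2.0 * gamma_m * s1) / (vE * vE);
      const double mc_s1 = (gamma_m * r * vE - num * gamma_m * gamma_m) /
        (vE * vE);
      const double mc_s2 = (muM * vE - num) / (vE * vE);
      // vM partials
      const double vM_s1 = s2 * s2 / (vE * vE);
      const double vM_s2 = gamma_m * gamma_m * s1 * s1 / (vE * vE);
      const double vM_gm = -2.0 * gamma_m * s1 * s1 * s2 / (vE * vE);
      grad[iB0] += base;
      for (int j = 0; j < J; ++j) grad[1 + j] += base * X(i, j);
      grad[iBG] += base * g;
      grad[iBE] += base * E[i];
      grad[iBM] += base * mc + dzden * beta_m * vM / den2;
      grad[iA0] += base * beta_m * mc_a0;
      grad[iAG] += base * beta_m * mc_ag;
      const double bm2h = beta_m * beta_m / (2.0 * den2);
      grad[iG0] += base * beta_m * mc_g0;
      grad[iGG] += base * beta_m * mc_gg;
      grad[iGM] += base * beta_m * mc_gm + dzden * bm2h * vM_gm;
      grad[iS1] += base * beta_m * mc_s1 + dzden * bm2h * vM_s1;
      grad[iS2] += base * beta_m * mc_s2 + dzden * bm2h * vM_s2;
      // marginal E | G density
      const double rE = E[i] - gamma0 - gamma_g * g - gamma_m * muM;
      const double dv = -0.5 / vE + rE * rE / (2.0 * vE * vE);
      grad[iG0] += rE / vE; grad[iGG] += rE * g / vE;
      grad[iGM] += rE * muM / vE + dv * 2.0 * gamma_m * s1;
      grad[iA0] += rE * gamma_m / vE; grad[iAG] += rE * gamma_m * g / vE;
      grad[iS1] += dv * gamma_m * gamma_m;
      grad[iS2] += dv;
      break;
    }
    default: {  // both missing
      const double mu0g = gamma0 + gamma_g * g;
      const double eta = xb + beta_g * g + beta_e * mu0g + bem * muM;
      const double z = y[i] * eta / den3;
      const double mills = exp(R::dnorm(z, 0.0, 1.0, 1) -
                               R::pnorm(z, 0.0, 1.0, 1, 1));
      const double base = mills * y[i] / den3;
      const double dzden = -mills * z / den3;
      grad[iB0] += base;
      for (int j = 0; j < J; ++j) grad[1 + j] += base * X(i, j);
      grad[iBG] += base * g;
      grad[iBE] += base * (mu0g + gamma_m * muM) +
        dzden * (beta_e * s2 + bem * gamma_m * s1) / den3;
      grad[iBM] += base * muM + dzden * bem * s1 / den3;
      grad[iG0] += base * beta_e; grad[iGG] += base * beta_e * g;
      grad[iGM] += base * beta_e * muM + dzden * bem * beta_e * s1 / den3;
      grad[iA0] += base * bem; grad[iAG] += base * bem * g;
      grad[iS1] += dzden * bem * bem / (2.0 * den3);
      grad[iS2] += dzden * beta_e * beta_e / (2.0 * den3);
    }
    }
  }
  for (int k = 0; k < np; ++k) grad[k] = -grad[k];
  return grad;
}
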