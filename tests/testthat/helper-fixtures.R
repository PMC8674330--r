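# Shared fixtures for the test suite. Everything is generated in code.

# A generic, non-degenerate parameter set (not the simulation defaults).
fixture_params <- function(J = 2) {
  trio_params(beta0 = 0.4, beta_x = c(0.02, -0.1)[seq_len(J)],
              beta_g = 0.1, beta_m = 0.2, beta_e = 0.3,
              alpha0 = 1.3, alpha_g = 2.4,
              gamma0 = 1.9, gamma_g = 0.6, gamma_m = 2.3,
              sigma1_sq = 1.2, sigma2_sq = 0.8, p = 0.2)
}

# Random admissible parameter draws for property-style tests.
random_params <- function(J = 2) {
  trio_params(beta0 = runif(1, -1, 1), beta_x = runif(J, -0.5, 0.5),
              beta_g = runif(1, -1, 1), beta_m = runif(1, -1, 1),
              beta_e = runif(1, -1, 1),
              alpha0 = runif(1, -2, 2), alpha_g = runif(1, -2, 2),
              gamma0 = runif(1, -2, 2), gamma_g = runif(1, -2, 2),
              gamma_m = runif(1, -2, 2),
              sigma1_sq = runif(1, 0.3, 3), sigma2_sq = runif(1, 0.3, 3),
              p = runif(1, 0.05, 0.95))
}

# A small deterministic dataset with all four missingness strata.
fixture_data <- function(n = 40, seed = 101, m_both = 0.1,
                         m_meth_only = 0.1, m_expr_only = 0.2, ...) {
  cfg <- sim_config(n_case = n / 2, n_control = n / 2, seed = seed,
                    m_both = m_both, m_meth_only = m_meth_only,
                    m_expr_only = m_expr_only, ...)
  simulate_trio_data(cfg)
}

# Quadrature oracle: marginalize the probit-approximated phenotype model
# over the missing layer(s) numerically. Independent of the closed forms.
oracle_missing_e <- function(y, x, g, m, th) {
  stats::integrate(function(e)
    sigmoid_probit_approx(y * (th$beta0 + sum(th$beta_x * x) + th$beta_g * g +
                                 th$beta_m * m + th$beta_e * e)) *
      stats::dnorm(e, th$gamma0 + th$gamma_g * g + th$gamma_m * m,
                   sqrt(th$sigma2_sq)),
    -Inf, Inf, rel.tol = 1e-10)$value
}

oracle_missing_m <- function(y, x, g, e, th) {
  # conditional law M | E, G from the two Gaussian regressions
  vE <- th$sigma2_sq + th$gamma_m^2 * th$sigma1_sq
  mc <- ((th$alpha0 + th$alpha_g * g) * th$sigma2_sq +
           th$gamma_m * (e - th$gamma0 - th$gamma_g * g) * th$sigma1_sq) / vE
  vc <- th$sigma1_sq * th$sigma2_sq / vE
  stats::integrate(function(m)
    sigmoid_probit_approx(y * (th$beta0 + sum(th$beta_x * x) + th$beta_g * g +
                                 th$beta_m * m + th$beta_e * e)) *
      stats::dnorm(m, mc, sqrt(vc)),
    -Inf, Inf, rel.tol = 1e-10)$value
}

oracle_missing_em <- function(y, x, g, th) {
  # outer quadrature over M, inner closed e-marginalization via the
  # missing-E oracle's integrand structure done numerically as well
  stats::integrate(Vectorize(function(m)
    oracle_missing_e(y, x, g, m, th) *
      stats::dnorm(m, th$alpha0 + th$alpha_g * g, sqrt(th$sigma1_sq))),
    -Inf, Inf, rel.tol = 1e-9)$value
}

# Term-by-term R composition of the complete-data log-likelihood,
# independent of the C++ evaluator.
loglik_by_hand <- function(data, th) {
  stopifnot(all(data$scheme == 0L))
  eta <- th$beta0 + drop(data$X %*% th$beta_x) + th$beta_g * data$G +
    th$beta_m * data$M + th$beta_e * data$E
  sum(log(sigmoid(data$y * eta))) +
    sum(dnorm(data$E, th$gamma0 + th$gamma_g * data$G + th$gamma_m * data$M,
              sqrt(th$sigma2_sq), log = TRUE)) +
    sum(dnorm(data$M, th$alpha0 + th$alpha_g * data$G, sqrt(th$sigma1_sq),
              log = TRUE)) +
    sum(dbinom(data$G, 2, th$p, log = TRUE))
}
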