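test_that("general log-likelihood reduces exactly to the complete-data form", {
  d <- fixture_data(n = 60, seed = 31, m_both = 0, m_meth_only = 0,
                    m_expr_only = 0)
  th <- fixture_params()
  expect_equal(trio_loglik(d, th), loglik_by_hand(d, th), tolerance = 1e-12)
})

test_that("one complete individual matches hand-composed term arithmetic", {
  th <- fixture_params()
  x <- c(1.5, 1); g <- 2; m <- 3.2; e <- 9.1; y <- 1
  d <- trio_data(y = y, X = matrix(x, 1), G = g, M = m, E = e)
  by_hand <- log(1 / (1 + exp(-(y * (th$beta0 + 0.02 * 1.5 - 0.1 * 1 +
                                       th$beta_g * g + th$beta_m * m +
                                       th$beta_e * e))))) +
    log(dnorm(e, th$gamma0 + th$gamma_g * g + th$gamma_m * m,
              sqrt(th$sigma2_sq))) +
    log(dnorm(m, th$alpha0 + th$alpha_g * g, sqrt(th$sigma1_sq))) +
    log(choose(2, g) * th$p^g * (1 - th$p)^(2 - g))
  expect_equal(trio_loglik(d, th), by_hand, tolerance = 1e-12)
})

test_that("each missing stratum contributes its marginalized factor additively", {
  th <- fixture_params()
  base <- fixture_data(n = 20, seed = 37, m_both = 0, m_meth_only = 0,
                       m_expr_only = 0)
  ll0 <- trio_loglik(base, th)
  add_row <- function(data, y, x, g, m, e) {
    trio_data(y = c(data$y, y), X = rbind(data$X, x), G = c(data$G, g),
              M = c(data$M, m), E = c(data$E, e))
  }
  geno_mass <- function(g) log(dbinom(g, 2, th$p))
  # both missing
  d4 <- add_row(base, -1, c(0.3, 1), 1, NA, NA)
  expect_equal(trio_loglik(d4, th) - ll0,
               cond_prob_missing_em(-1, c(0.3, 1), 1, th, log.p = TRUE) +
                 geno_mass(1), tolerance = 1e-10)
  # expression missing: marginalized probit times M | G density
  d2 <- add_row(base, 1, c(-0.2, 0), 2, 4.1, NA)
  expect_equal(trio_loglik(d2, th) - ll0,
               cond_prob_missing_e(1, c(-0.2, 0), 2, 4.1, th, log.p = TRUE) +
                 dnorm(4.1, th$alpha0 + th$alpha_g * 2, sqrt(th$sigma1_sq),
                       log = TRUE) + geno_mass(2), tolerance = 1e-10)
  # methylation missing: marginalized probit times E | G marginal density
  d3 <- add_row(base, -1, c(1, 1), 0, NA, 2.2)
  expect_equal(trio_loglik(d3, th) - ll0,
               cond_prob_missing_m(-1, c(1, 1), 0, 2.2, th, log.p = TRUE) +
                 marginal_density_e_given_g(2.2, 0, th, log = TRUE) +
                 geno_mass(0), tolerance = 1e-10)
})

test_that("log-likelihood is invariant to row permutation", {
  d <- fixture_data(n = 50, seed = 41)
  th <- fixture_params()
  set.seed(1)
  perm <- sample(length(d$y))
  dp <- trio_data_subset(d, perm)
  expect_equal(trio_loglik(dp, th), trio_loglik(d, th), tolerance = 1e-12)
})

test_that("duplicating every individual doubles the fitted log-likelihood", {
  d <- fixture_data(n = 40, seed = 43)
  th <- fixture_params()
  dd <- trio_data_subset(d, rep(seq_along(d$y), 2))
  expect_equal(trio_loglik(dd, th), 2 * trio_loglik(d, th), tolerance = 1e-10)
})

test_that("constrained fits never beat the unconstrained fit", {
  d <- fixture_data(n = 80, seed = 47)
  f_alt <- fit_trio(d)
  f_null <- fit_trio(d, constrained = c("beta_g", "beta_m", "beta_e"))
  expect_lte(f_null$loglik, f_alt$loglik + 1e-6)
  expect_equal(f_null$params$beta_g, 0)
  expect_equal(f_null$params$beta_m, 0)
  expect_equal(f_null$params$beta_e, 0)
  expect_error(fit_trio(d, constrained = "nope"), "unknown parameter")
})

test_that("MLE recovers the generative parameters on complete data", {
  cfg <- sim_config(n_case = 200, n_control = 200, null_scenario = TRUE,
                    seed = 53)
  fits <- lapply(1:8, function(i) {
    cfg$seed <- 53 + i
    fit_trio(simulate_trio_data(cfg))$params
  })
  est <- sapply(fits, function(p)
    c(p$alpha0, p$alpha_g, p$gamma0, p$gamma_g, p$gamma_m,
      p$sigma1_sq, p$sigma2_sq, p$p))
  truth <- c(1.3, 2.4, 1.9, 0.6, 2.3, 1, 1, 0.2)
  bias <- rowMeans(est) - truth
  # spread-calibrated: each mean estimate within 4 SE of the truth
  se <- apply(est, 1, sd) / sqrt(ncol(est))
  expect_true(all(abs(bias) < 4 * se + 0.02))
})

test_that("dropping an omics layer still yields consistent estimates as n grows", {
  err <- sapply(c(100, 400, 1600), function(n) {
    cfg <- sim_config(n_case = n / 2, n_control = n / 2,
                      null_scenario = TRUE, seed = 59)
    d <- simulate_trio_data(cfg)
    d <- trio_data(y = d$y, X = d$X, G = d$G, M = d$M,
                   E = rep(NA_real_, n))  # expression never observed
    # the degenerate stratum pattern legitimately triggers the
    # weak-identifiability warning
    fit <- NULL
    expect_warning(fit <- fit_trio(d), "weakly identified")
    p <- fit$params
    abs(p$alpha_g - 2.4) + abs(p$alpha0 - 1.3)
  })
  expect_true(is.finite(err[3]))
  expect_lt(err[3], err[1] + 0.05)
})

test_that("analytic gradient matches central finite differences", {
  d <- fixture_data(n = 60, seed = 63, m_both = 0.15, m_meth_only = 0.15,
                    m_expr_only = 0.2)
  M0 <- ifelse(is.na(d$M), 0, d$M)
  E0 <- ifelse(is.na(d$E), 0, d$E)
  set.seed(65)
  for (i in 1:10) {
    v <- c(runif(6, -1, 1), runif(5, -2, 2), runif(2, 0.3, 3),
           runif(1, 0.05, 0.95))
    ga <- omictrio:::cpp_negloglik_agrad(v, d$y, d$X, d$G, M0, E0, d$scheme)
    gf <- omictrio:::cpp_negloglik_grad(v, 0:13, d$y, d$X, d$G, M0, E0,
                                        d$scheme)
    expect_lt(max(abs(ga - gf) / (1 + abs(gf))), 1e-5)
  }
})

test_that("covariate dimension mismatches are rejected", {
  d <- fixture_data(n = 20, seed = 61)
  th <- fixture_params()
  th$beta_x <- c(0.1)
  expect_error(trio_loglik(d, th), "covariate dimension")
})
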