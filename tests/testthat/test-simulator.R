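test_that("case genotype law is the Bayes inversion of additive penetrances", {
  # hand-computed oracle at the default study conditions:
  # HWE(0.2) = (0.64, 0.32, 0.04); f0 solved from
  # 0.1 = f0 * (0.64 + 1.2*0.32 + 1.4*0.04)
  hwe <- c(0.64, 0.32, 0.04)
  f0 <- 0.1 / sum(c(1, 1.2, 1.4) * hwe)
  oracle <- f0 * c(1, 1.2, 1.4) * hwe / 0.1
  expect_equal(unname(genotype_freqs_case(0.2, 1.2, 0.1)), oracle)
  expect_equal(sum(genotype_freqs_case(0.35, 1.7, 0.05)), 1, tolerance = 1e-12)
  # no effect: case law collapses to the control HWE law
  expect_equal(unname(genotype_freqs_case(0.2, 1, 0.1)),
               dbinom(0:2, 2, 0.2))
  # multiplicative variant
  f0m <- 0.1 / sum(1.2^(0:2) * hwe)
  expect_equal(unname(genotype_freqs_case(0.2, 1.2, 0.1, "multiplicative")),
               f0m * 1.2^(0:2) * hwe / 0.1)
  expect_error(genotype_freqs_case(0.2, 25, 0.9), "infeasible")
})

test_that("covariates follow their generating laws and are reproducible", {
  cfg <- sim_config()
  set.seed(1)
  X <- simulate_covariates(1e5, cfg)
  expect_lt(abs(mean(X[, "age"]) - 40), 3 * 6 / sqrt(1e5))
  expect_lt(abs(sd(X[, "age"]) - 6), 0.1)
  expect_true(all(X[, "sex"] %in% c(0, 1)))
  set.seed(9); X1 <- simulate_covariates(50, cfg)
  set.seed(9); X2 <- simulate_covariates(50, cfg)
  expect_identical(X1, X2)
})

test_that("omics layers have the analytic first and second moments", {
  cfg <- sim_config()
  set.seed(2)
  G <- rep(1, 2e5)
  ome <- simulate_omics(G, rep(FALSE, 2e5), cfg)
  muM <- cfg$alpha0 + cfg$alpha_g
  expect_lt(abs(mean(ome$M) - muM), 0.02)
  expect_lt(abs(mean(ome$E) - (cfg$gamma0 + cfg$gamma_g + cfg$gamma_m * muM)),
            0.05)
  # Cov(M, E | G) = gamma_m * sigma1^2
  expect_lt(abs(cov(ome$M, ome$E) - cfg$gamma_m * cfg$sigma1_sq), 0.05)
  # degenerate structure: no genotype or cross effects
  cfg0 <- sim_config(alpha_g = 0, gamma_g = 0, gamma_m = 0)
  ome0 <- simulate_omics(G, rep(FALSE, 2e5), cfg0)
  expect_lt(abs(cov(ome0$M, ome0$E)), 0.01)
})

test_that("simulated datasets honor stratum sizes, labels and determinism", {
  d <- simulate_trio_data(sim_config(n_case = 30, n_control = 50, seed = 3))
  expect_equal(sum(d$y == 1), 30)
  expect_equal(sum(d$y == -1), 50)
  d0 <- simulate_trio_data(sim_config(n_case = 0, n_control = 10, seed = 3))
  expect_true(all(d0$y == -1))
  d1 <- simulate_trio_data(sim_config(n_case = 20, n_control = 20, seed = 11,
                                      m_both = 0.1, m_expr_only = 0.2))
  d2 <- simulate_trio_data(sim_config(n_case = 20, n_control = 20, seed = 11,
                                      m_both = 0.1, m_expr_only = 0.2))
  expect_identical(d1$M, d2$M)
  expect_identical(d1$E, d2$E)
  expect_identical(d1$G, d2$G)
  expect_equal(length(attr(d1, "bernoulli_prob")), 40)
})

test_that("null scenario equalizes the generative law across strata", {
  d <- simulate_trio_data(sim_config(n_case = 4000, n_control = 4000,
                                     null_scenario = TRUE, seed = 13))
  ks_m <- suppressWarnings(ks.test(d$M[d$y == 1], d$M[d$y == -1]))$p.value
  ks_e <- suppressWarnings(ks.test(d$E[d$y == 1], d$E[d$y == -1]))$p.value
  expect_gt(ks_m, 0.001)
  expect_gt(ks_e, 0.001)
  expect_lt(abs(mean(d$G[d$y == 1]) - mean(d$G[d$y == -1])), 0.1)
})

test_that("control genotypes follow HWE and case genotypes the shifted law", {
  d <- simulate_trio_data(sim_config(n_case = 20000, n_control = 20000,
                                     seed = 17))
  hwe <- dbinom(0:2, 2, 0.2)
  case_law <- genotype_freqs_case(0.2, 1.2, 0.1)
  obs_co <- tabulate(d$G[d$y == -1] + 1, 3) / 20000
  obs_ca <- tabulate(d$G[d$y == 1] + 1, 3) / 20000
  expect_lt(max(abs(obs_co - hwe)), 0.01)
  expect_lt(max(abs(obs_ca - case_law)), 0.01)
})

test_that("missingness injection hits exact counts, disjointly and balanced", {
  d <- simulate_trio_data(sim_config(n_case = 200, n_control = 200, seed = 19))
  set.seed(1)
  d2 <- inject_missingness(d, 0.1, 0.1, 0.2)
  expect_equal(unname(d2$n), c(240, 80, 40, 40))
  # per-stratum balance
  for (s in c(1, -1)) {
    sel <- d2$y == s
    expect_equal(sum(is.na(d2$M[sel]) & is.na(d2$E[sel])), 20)
    expect_equal(sum(is.na(d2$M[sel]) & !is.na(d2$E[sel])), 20)
    expect_equal(sum(!is.na(d2$M[sel]) & is.na(d2$E[sel])), 40)
  }
  # no-op and over-subscription
  d3 <- inject_missingness(d, 0, 0, 0)
  expect_identical(d3$M, d$M)
  expect_error(inject_missingness(d, 0.6, 0.3, 0.3), "more than 1")
})

test_that("fractions summing to one leave no complete cases yet the fit runs", {
  d <- simulate_trio_data(sim_config(n_case = 60, n_control = 60, seed = 23,
                                     m_both = 0.2, m_meth_only = 0.4,
                                     m_expr_only = 0.4))
  expect_equal(d$n[["n1"]], 0)
  fit <- fit_trio(d)
  expect_true(is.finite(fit$loglik))
})

test_that("prospective and rejection modes fill quotas from Bernoulli draws", {
  dp <- simulate_trio_data(sim_config(n_case = 50, n_control = 50,
                                      mode = "prospective", seed = 29))
  expect_equal(sum(dp$y == 1), 50)
  expect_equal(sum(dp$y == -1), 50)
  # phenotype probabilities of sampled cases exceed those of controls on average
  pr <- attr(dp, "bernoulli_prob")
  expect_gt(mean(pr[dp$y == 1]), mean(pr[dp$y == -1]))
  dr <- simulate_trio_data(sim_config(n_case = 40, n_control = 40,
                                      mode = "rejection", seed = 31))
  expect_equal(sum(dr$y == 1), 40)
  expect_equal(sum(dr$y == -1), 40)
})
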