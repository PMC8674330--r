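test_that("sigmoid is symmetric, stable, and matches direct evaluation", {
  expect_equal(sigmoid(0), 0.5)
  v <- c(-30, -5, -1.3, 0.7, 4, 25)
  expect_equal(sigmoid(v) + sigmoid(-v), rep(1, length(v)))
  expect_equal(sigmoid(1.3), 1 / (1 + exp(-1.3)))
  expect_equal(sigmoid(700), 1)
  expect_gt(sigmoid(-700), 0 - 1e-300)
})

test_that("probit approximation agrees with the logistic within 0.02 sup-norm", {
  expect_equal(sigmoid_probit_approx(0), 0.5)
  # sup distance of the variance-matched normal approximation, computed by
  # dense grid evaluation: about 0.0226 near |v| ~ 2.4
  grid <- seq(-10, 10, by = 0.001)
  expect_lt(max(abs(sigmoid(grid) - sigmoid_probit_approx(grid))), 0.023)
  expect_equal(sigmoid_probit_approx(1e4), 1)
  expect_equal(approx_beta(), pi / sqrt(3))
})

test_that("closed-form product-of-normals integral matches adaptive quadrature", {
  # analytically trivial configuration
  expect_equal(lemma1_integral(1, 0, 0, 0, 1, 1), dnorm(0))
  quad <- function(a, b, c, d, s1, s2)
    integrate(function(x) dnorm((a * x - b) / s1) * dnorm((c - d * x) / s2),
              -Inf, Inf, rel.tol = 1e-12)$value
  expect_equal(lemma1_integral(2, 1, 0.5, 1.5, 1, 2),
               quad(2, 1, 0.5, 1.5, 1, 2), tolerance = 1e-8)
  # swapped configuration: same identity must hold
  expect_equal(lemma1_integral(1.5, 0.5, 1, 2, 2, 1),
               quad(1.5, 0.5, 1, 2, 2, 1), tolerance = 1e-8)
  set.seed(14)
  for (i in 1:50) {
    a <- runif(1, -3, 3); b <- runif(1, -3, 3)
    cc <- runif(1, -3, 3); d <- runif(1, -3, 3)
    if (abs(a) < 0.1 && abs(d) < 0.1) next
    s1 <- runif(1, 0.3, 3); s2 <- runif(1, 0.3, 3)
    expect_equal(lemma1_integral(a, b, cc, d, s1, s2),
                 quad(a, b, cc, d, s1, s2), tolerance = 1e-8)
  }
  expect_error(lemma1_integral(0, 1, 1, 0, 1, 1), "degenerate")
})

test_that("marginalized phenotype kernels equal quadrature marginalization", {
  set.seed(7)
  for (i in 1:30) {
    th <- random_params()
    x <- runif(2, -2, 2); g <- sample(0:2, 1)
    m <- rnorm(1, th$alpha0 + th$alpha_g * g, sqrt(th$sigma1_sq))
    e <- rnorm(1, 2, 2)
    for (y in c(-1, 1)) {
      expect_equal(cond_prob_missing_e(y, x, g, m, th),
                   oracle_missing_e(y, x, g, m, th), tolerance = 1e-6)
      expect_equal(cond_prob_missing_m(y, x, g, e, th),
                   oracle_missing_m(y, x, g, e, th), tolerance = 1e-6)
      expect_equal(cond_prob_missing_em(y, x, g, th),
                   oracle_missing_em(y, x, g, th), tolerance = 1e-5)
    }
  }
})

test_that("marginalized kernels are proper probabilities summing to one over y", {
  set.seed(8)
  for (i in 1:100) {
    th <- random_params()
    x <- runif(2, -2, 2); g <- sample(0:2, 1)
    m <- rnorm(1); e <- rnorm(1)
    pe <- cond_prob_missing_e(c(1, -1), x, g, m, th)
    pm <- cond_prob_missing_m(c(1, -1), x, g, e, th)
    pem <- cond_prob_missing_em(c(1, -1), x, g, th)
    for (p2 in list(pe, pm, pem)) {
      expect_true(all(p2 > 0 & p2 < 1))
      expect_equal(sum(p2), 1)
    }
  }
})

test_that("zero phenotype coefficients give probability one half", {
  th <- fixture_params()
  th$beta0 <- th$beta_g <- th$beta_m <- th$beta_e <- 0
  th$beta_x <- c(0, 0)
  expect_equal(cond_prob_missing_e(1, c(3, 1), 2, 0.7, th), 0.5)
  expect_equal(cond_prob_missing_em(-1, c(-1, 0), 1, th), 0.5)
})

test_that("missing-methylation kernel reduces to the plain probit when beta_m = 0", {
  th <- fixture_params()
  th$beta_m <- 0
  x <- c(0.5, 1); g <- 1; e <- 4
  eta <- th$beta0 + sum(th$beta_x * x) + th$beta_g * g + th$beta_e * e
  expect_equal(cond_prob_missing_m(1, x, g, e, th),
               sigmoid_probit_approx(eta))
})

test_that("both-missing kernel converges to the plug-in probit as variances vanish", {
  th <- fixture_params()
  th$sigma1_sq <- 1e-10; th$sigma2_sq <- 1e-10
  x <- c(0.5, -1); g <- 2
  m_mean <- th$alpha0 + th$alpha_g * g
  e_mean <- th$gamma0 + th$gamma_g * g + th$gamma_m * m_mean
  eta <- th$beta0 + sum(th$beta_x * x) + th$beta_g * g +
    th$beta_m * m_mean + th$beta_e * e_mean
  expect_equal(cond_prob_missing_em(1, x, g, th), sigmoid_probit_approx(eta),
               tolerance = 1e-6)
})

test_that("expression-given-genotype marginal is the convolved normal density", {
  th <- fixture_params()
  # gamma_m = 0 reduction
  th0 <- th; th0$gamma_m <- 0
  expect_equal(marginal_density_e_given_g(2.5, 1, th0),
               dnorm(2.5, th0$gamma0 + th0$gamma_g, sqrt(th0$sigma2_sq)))
  # normalization
  expect_equal(integrate(function(e) marginal_density_e_given_g(e, 2, th),
                         -Inf, Inf)$value, 1, tolerance = 1e-7)
  # numeric convolution of the two regression layers
  conv <- integrate(function(m)
    dnorm(4, th$gamma0 + th$gamma_g * 1 + th$gamma_m * m, sqrt(th$sigma2_sq)) *
      dnorm(m, th$alpha0 + th$alpha_g * 1, sqrt(th$sigma1_sq)),
    -Inf, Inf, rel.tol = 1e-10)$value
  expect_equal(marginal_density_e_given_g(4, 1, th), conv, tolerance = 1e-8)
})

test_that("parameter constructor enforces its invariants", {
  expect_error(trio_params(sigma1_sq = 0), "sigma1_sq")
  expect_error(trio_params(sigma2_sq = -1), "sigma2_sq")
  expect_error(trio_params(p = 0), "p must")
  expect_error(trio_params(p = 1), "p must")
})
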