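#' Logistic (sigmoid) function
#'
#' \eqn{\sigma(v) = 1/(1 + e^{-v})}, evaluated stably for large |v|.
#'
#' @param v Numeric vector.
#' @return Probabilities in (0, 1) (saturating at 0/1 in the extreme tails).
#' @examples
#' sigmoid(0)      # 0.5
#' sigmoid(1.3)
#' @export
sigmoid <- function(v) stats::plogis(v)

#' Probit approximation to the logistic function
#'
#' Replaces the logistic CDF by a normal CDF with scale
#' \eqn{\beta = \pi/\sqrt{3}}: \eqn{\sigma(v) \approx \Phi(v/\beta)}. The
#' sup-norm error of this classical approximation is below 0.02, and it turns
#' every Gaussian marginalization over an unobserved omics layer into a
#' closed-form normal probability.
#'
#' @param v Numeric vector.
#' @return Approximate probabilities \eqn{\Phi(v / (\pi/\sqrt{3}))}.
#' @export
sigmoid_probit_approx <- function(v) stats::pnorm(v / approx_beta())

#' Closed-form product-of-normal-densities integral
#'
#' Evaluates \deqn{\int_{-\infty}^{\infty} \phi\!\left(\frac{a x - b}
#' {\sigma_1}\right) \phi\!\left(\frac{c - d x}{\sigma_2}\right) dx =
#' \phi\!\left(\frac{a c - b d}{\sqrt{a^2 \sigma_2^2 + d^2 \sigma_1^2}}\right)
#' \frac{1}{\sqrt{a^2/\sigma_1^2 + d^2/\sigma_2^2}}}
#' where \eqn{\phi} is the standard normal density. This identity is the
#' engine behind each analytic marginalization of a missing omics layer.
#'
#' @param a,b,c,d Real constants; `a` and `d` must not both be zero
#'   (otherwise the integrand is constant and the integral diverges).
#' @param sigma1,sigma2 Positive scale constants.
#' @return The value of the integral.
#' @examples
#' lemma1_integral(1, 0, 0, 0, 1, 1)  # = dnorm(0)
#' @export
lemma1_integral <- function(a, b, c, d, sigma1, sigma2) {
  stopifnot(sigma1 > 0, sigma2 > 0)
  if (all(a == 0 & d == 0))
    stop("degenerate integrand: 'a' and 'd' must not both be zero")
  stats::dnorm((a * c - b * d) / sqrt(a^2 * sigma2^2 + d^2 * sigma1^2)) /
    sqrt(a^2 / sigma1^2 + d^2 / sigma2^2)
}

# Shared pieces of the marginalized phenotype probabilities. All three
# conditional kernels have the form Phi(y * eta / sqrt(beta^2 + extra_var))
# with beta = pi/sqrt(3): the unobserved layers are integrated out of the
# probit-approximated phenotype model, inflating the probit denominator by
# the marginal variance they contribute to the linear predictor.
cond_prob_core <- function(y, eta, extra_var, log.p = FALSE) {
  stats::pnorm(y * eta / sqrt(approx_beta()^2 + extra_var), log.p = log.p)
}

xbeta <- function(x, params) {
  if (length(params$beta_x) == 0L) return(params$beta0)
  if (is.matrix(x)) params$beta0 + drop(x %*% params$beta_x)
  else params$beta0 + sum(x * params$beta_x)
}

#' Phenotype probability when expression is missing
#'
#' The probability \eqn{P(Y = y \mid X, G, M)} with gene expression
#' integrated out of the probit-approximated phenotype model using the
#' conditional law \eqn{E \mid M, G \sim N(\gamma_0 + \gamma_g G + \gamma_m
#' M, \sigma_2^2)}:
#' \deqn{\Phi\!\left(\frac{y(\beta_0 + \beta_x'X + \beta_g G + \beta_m M +
#' \beta_e \mu_0)}{\sqrt{\beta^2 + \beta_e^2 \sigma_2^2}}\right)}
#' with \eqn{\mu_0 = \gamma_0 + \gamma_g G + \gamma_m M} and \eqn{\beta =
#' \pi/\sqrt{3}}.
#'
#' @param y Phenotype, coded -1 (control) / +1 (case); vectorized.
#' @param x Covariate vector (or matrix with one row per individual).
#' @param g Genotype, minor-allele count in \{0, 1, 2\}.
#' @param m Observed methylation value.
#' @param params A [trio_params()] object.
#' @param log.p Return the log probability?
#' @return \eqn{P(Y = y)} under the marginalized model.
#' @export
cond_prob_missing_e <- function(y, x, g, m, params, log.p = FALSE) {
  mu0 <- params$gamma0 + params$gamma_g * g + params$gamma_m * m
  eta <- xbeta(x, params) + params$beta_g * g + params$beta_m * m +
    params$beta_e * mu0
  cond_prob_core(y, eta, params$beta_e^2 * params$sigma2_sq, log.p)
}

#' Phenotype probability when methylation is missing
#'
#' The probability \eqn{P(Y = y \mid X, G, E)} with methylation integrated
#' out using the bivariate-normal conditional \eqn{M \mid E, G}, whose mean
#' is \eqn{[(\alpha_0 + \alpha_g G)\sigma_2^2 + \gamma_m(E - \gamma_0 -
#' \gamma_g G)\sigma_1^2] / (\sigma_2^2 + \gamma_m^2 \sigma_1^2)} and whose
#' variance is \eqn{\sigma_1^2 \sigma_2^2 / (\sigma_2^2 + \gamma_m^2
#' \sigma_1^2)}.
#'
#' @inheritParams cond_prob_missing_e
#' @param e Observed expression value.
#' @return \eqn{P(Y = y)} under the marginalized model.
#' @export
cond_prob_missing_m <- function(y, x, g, e, params, log.p = FALSE) {
  s1 <- params$sigma1_sq; s2 <- params$sigma2_sq; gm <- params$gamma_m
  vE <- s2 + gm^2 * s1
  m_cond <- ((params$alpha0 + params$alpha_g * g) * s2 +
               gm * (e - params$gamma0 - params$gamma_g * g) * s1) / vE
  v_cond <- s1 * s2 / vE
  eta <- xbeta(x, params) + params$beta_g * g + params$beta_e * e +
    params$beta_m * m_cond
  cond_prob_core(y, eta, params$beta_m^2 * v_cond, log.p)
}

#' Phenotype probability when both omics are missing
#'
#' The probability \eqn{P(Y = y \mid X, G)} with methylation and expression
#' both integrated out: the linear predictor is evaluated at the genotype-
#' implied means and the probit denominator absorbs
#' \eqn{\beta_e^2\sigma_2^2 + (\beta_e\gamma_m + \beta_m)^2\sigma_1^2}.
#'
#' @inheritParams cond_prob_missing_e
#' @return \eqn{P(Y = y)} under the marginalized model.
#' @export
cond_prob_missing_em <- function(y, x, g, params, log.p = FALSE) {
  muM <- params$alpha0 + params$alpha_g * g
  bem <- params$beta_e * params$gamma_m + params$beta_m
  eta <- xbeta(x, params) + params$beta_g * g +
    params$beta_e * (params$gamma0 + params$gamma_g * g) + bem * muM
  cond_prob_core(y, eta,
                 params$beta_e^2 * params$sigma2_sq + bem^2 * params$sigma1_sq,
                 log.p)
}

#' Marginal density of expression given genotype
#'
#' Collapsing the methylation layer gives \eqn{E \mid G \sim
#' N(\gamma_0 + \gamma_g G + \gamma_m(\alpha_0 + \alpha_g G),\;
#' \sigma_2^2 + \gamma_m^2 \sigma_1^2)}; this is the density attached to
#' individuals whose methylation value is missing.
#'
#' @param e Expression value(s).
#' @param g Genotype(s).
#' @param params A [trio_params()] object.
#' @param log Return the log density?
#' @return Density value(s).
#' @export
marginal_density_e_given_g <- function(e, g, params, log = FALSE) {
  mu <- params$gamma0 + params$gamma_g * g +
    params$gamma_m * (params$alpha0 + params$alpha_g * g)
  stats::dnorm(e, mean = mu,
               sd = sqrt(params$sigma2_sq + params$gamma_m^2 * params$sigma1_sq),
               log = log)
}
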