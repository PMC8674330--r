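#' Model parameter vector for the trio model
#'
#' Bundles every parameter of the three-layer model: the logistic phenotype
#' model \eqn{P(Y_i = 1) = \sigma(y_i(\beta_0 + \beta_e E_i + \beta_m M_i +
#' \beta_g G_i + \beta_x' X_i))}, the methylation regression
#' \eqn{M_i = \alpha_0 + \alpha_g G_i + \epsilon_{1i}}, the expression
#' regression \eqn{E_i = \gamma_0 + \gamma_g G_i + \gamma_m M_i +
#' \epsilon_{2i}}, the error variances, and the minor-allele frequency of the
#' Binomial(2, p) genotype law. The logistic-probit approximation constant
#' \eqn{\pi/\sqrt{3}} is fixed, never estimated, and exposed as
#' [approx_beta()].
#'
#' @param beta0 Intercept of the phenotype model (log-odds scale).
#' @param beta_x Numeric vector of covariate coefficients (length J).
#' @param beta_g,beta_m,beta_e Genotype, methylation and expression effects
#'   on the phenotype.
#' @param alpha0,alpha_g Intercept and genotype effect of the methylation
#'   model.
#' @param gamma0,gamma_g,gamma_m Intercept, genotype effect and methylation
#'   effect of the expression model.
#' @param sigma1_sq,sigma2_sq Error variances of the methylation and
#'   expression models; must be strictly positive.
#' @param p Minor-allele frequency, strictly inside (0, 1).
#'
#' @return An object of class `"trio_params"`: a named list with the fields
#'   above.
#' @examples
#' th <- trio_params(beta0 = 1, beta_x = c(0.01, 0.01), beta_g = 0.1,
#'                   beta_m = 0.2, beta_e = 0.3)
#' th$p
#' @export
trio_params <- function(beta0 = 0, beta_x = numeric(0), beta_g = 0,
                        beta_m = 0, beta_e = 0,
                        alpha0 = 0, alpha_g = 0,
                        gamma0 = 0, gamma_g = 0, gamma_m = 0,
                        sigma1_sq = 1, sigma2_sq = 1, p = 0.5) {
  stopifnot(is.numeric(beta_x),
            length(beta0) == 1L, length(beta_g) == 1L,
            length(beta_m) == 1L, length(beta_e) == 1L)
  if (!is.finite(sigma1_sq) || sigma1_sq <= 0)
    stop("sigma1_sq must be > 0")
  if (!is.finite(sigma2_sq) || sigma2_sq <= 0)
    stop("sigma2_sq must be > 0")
  if (!is.finite(p) || p <= 0 || p >= 1)
    stop("p must lie strictly inside (0, 1)")
  structure(list(beta0 = beta0, beta_x = as.numeric(beta_x),
                 beta_g = beta_g, beta_m = beta_m, beta_e = beta_e,
                 alpha0 = alpha0, alpha_g = alpha_g,
                 gamma0 = gamma0, gamma_g = gamma_g, gamma_m = gamma_m,
                 sigma1_sq = sigma1_sq, sigma2_sq = sigma2_sq, p = p),
            class = "trio_params")
}

#' The logistic-probit approximation constant
#'
#' The logistic CDF is approximated by a normal CDF with scale
#' \eqn{\beta = \pi/\sqrt{3}} (the standard deviation of the standard
#' logistic distribution), which makes every Gaussian marginalization in the
#' missing-data likelihood available in closed form.
#'
#' @return The constant \eqn{\pi/\sqrt{3}}.
#' @export
approx_beta <- function() pi / sqrt(3)

#' @export
print.trio_params <- function(x, ...) {
  cat("Trio model parameters\n")
  cat("  phenotype : beta0 =", format(x$beta0),
      " beta_g =", format(x$beta_g),
      " beta_m =", format(x$beta_m),
      " beta_e =", format(x$beta_e), "\n")
  if (length(x$beta_x))
    cat("  covariates: beta_x =", paste(format(x$beta_x), collapse = ", "), "\n")
  cat("  methylation: alpha0 =", format(x$alpha0),
      " alpha_g =", format(x$alpha_g),
      " sigma1_sq =", format(x$sigma1_sq), "\n")
  cat("  expression : gamma0 =", format(x$gamma0),
      " gamma_g =", format(x$gamma_g),
      " gamma_m =", format(x$gamma_m),
      " sigma2_sq =", format(x$sigma2_sq), "\n")
  cat("  genotype   : p =", format(x$p), "\n")
  invisible(x)
}

# Flatten to the optimizer's parameter layout:
# beta0, beta_x (J), beta_g, beta_m, beta_e, alpha0, alpha_g,
# gamma0, gamma_g, gamma_m, sigma1_sq, sigma2_sq, p
params_to_vector <- function(params, J = length(params$beta_x)) {
  bx <- params$beta_x
  if (length(bx) < J) bx <- c(bx, rep(0, J - length(bx)))
  v <- c(params$beta0, bx[seq_len(J)], params$beta_g, params$beta_m,
         params$beta_e, params$alpha0, params$alpha_g, params$gamma0,
         params$gamma_g, params$gamma_m, params$sigma1_sq,
         params$sigma2_sq, params$p)
  names(v) <- param_names(J)
  v
}

param_names <- function(J) {
  c("beta0", if (J > 0) paste0("beta_x", seq_len(J)),
    "beta_g", "beta_m", "beta_e", "alpha0", "alpha_g",
    "gamma0", "gamma_g", "gamma_m", "sigma1_sq", "sigma2_sq", "p")
}

vector_to_params <- function(v, J) {
  trio_params(beta0 = v[[1L]],
              beta_x = if (J > 0) v[1L + seq_len(J)] else numeric(0),
              beta_g = v[[J + 2L]], beta_m = v[[J + 3L]], beta_e = v[[J + 4L]],
              alpha0 = v[[J + 5L]], alpha_g = v[[J + 6L]],
              gamma0 = v[[J + 7L]], gamma_g = v[[J + 8L]],
              gamma_m = v[[J + 9L]],
              sigma1_sq = v[[J + 10L]], sigma2_sq = v[[J + 11L]],
              p = v[[J + 12L]])
}
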