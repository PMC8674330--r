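#' Log-likelihood of the trio model
#'
#' Evaluates the joint log-likelihood of a (possibly partially missing)
#' trio dataset. Complete individuals contribute the exact logistic
#' phenotype term times the two Gaussian regression densities; individuals
#' with a missing layer contribute the corresponding analytically
#' marginalized probit term together with the density of whatever omics
#' they do have; individuals missing both layers contribute only the
#' marginalized phenotype probability. Every individual contributes the
#' Binomial(2, p) genotype mass. The general form reduces exactly to the
#' complete-data likelihood (and to the single-scheme likelihoods) when the
#' corresponding strata are empty.
#'
#' @param data A [trio_data()] object.
#' @param params A [trio_params()] object; `beta_x` must match the covariate
#'   dimension of `data`.
#' @return The log-likelihood (a scalar).
#' @export
trio_loglik <- function(data, params) {
  J <- ncol(data$X)
  if (length(params$beta_x) != J)
    stop("length(beta_x) must equal the covariate dimension (", J, ")")
  -cpp_negloglik(params_to_vector(params, J), data$y, data$X, data$G,
                 ifelse(is.na(data$M), 0, data$M),
                 ifelse(is.na(data$E), 0, data$E),
                 data$scheme)
}

# Optimizer box constraints per parameter; generous relative to any
# realistic effect size, mainly there to keep the objective finite.
param_bounds <- function(J) {
  nm <- param_names(J)
  lower <- stats::setNames(rep(-50, length(nm)), nm)
  upper <- stats::setNames(rep(50, length(nm)), nm)
  lower[c("sigma1_sq", "sigma2_sq")] <- 1e-6
  upper[c("sigma1_sq", "sigma2_sq")] <- 1e6
  lower["p"] <- 1e-6
  upper["p"] <- 1 - 1e-6
  list(lower = lower, upper = upper)
}

# Deterministic, cheap starting values: least squares for the omics layers
# on whatever rows observe them, a logistic GLM on complete cases for the
# phenotype layer, sample allele frequency for p, residual variances for
# the sigmas. Everything is clamped into the optimizer box.
start_values <- function(data) {
  J <- ncol(data$X)
  v <- stats::setNames(numeric(J + 12), param_names(J))
  v["p"] <- min(max(mean(data$G) / 2, 0.01), 0.99)
  v["sigma1_sq"] <- 1
  v["sigma2_sq"] <- 1

  hasM <- !is.na(data$M)
  if (sum(hasM) >= 3) {
    fm <- stats::lm.fit(cbind(1, data$G[hasM]), data$M[hasM])
    v["alpha0"] <- fm$coefficients[1]
    v["alpha_g"] <- fm$coefficients[2]
    if (sum(hasM) > 2)
      v["sigma1_sq"] <- max(mean(fm$residuals^2), 1e-3)
  }
  hasME <- hasM & !is.na(data$E)
  if (sum(hasME) >= 4) {
    fe <- stats::lm.fit(cbind(1, data$G[hasME], data$M[hasME]), data$E[hasME])
    v["gamma0"] <- fe$coefficients[1]
    v["gamma_g"] <- fe$coefficients[2]
    v["gamma_m"] <- fe$coefficients[3]
    v["sigma2_sq"] <- max(mean(fe$residuals^2), 1e-3)
  } else if (sum(!is.na(data$E)) >= 3) {
    hasE <- !is.na(data$E)
    fe <- stats::lm.fit(cbind(1, data$G[hasE]), data$E[hasE])
    v["gamma0"] <- fe$coefficients[1]
    v["gamma_g"] <- fe$coefficients[2]
    v["sigma2_sq"] <- max(mean(fe$residuals^2), 1e-3)
  }

  cc <- data$scheme == 0L
  y01 <- (data$y + 1) / 2
  if (sum(cc) >= J + 5 && length(unique(y01[cc])) == 2) {
    Z <- cbind(data$X[cc, , drop = FALSE], G = data$G[cc],
               M = data$M[cc], E = data$E[cc])
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(cbind(1, Z), y01[cc],
                                      family = stats::binomial())),
      error = function(e) NULL)
    if (!is.null(fit) && all(is.finite(fit$coefficients))) {
      cf <- pmin(pmax(fit$coefficients, -5), 5)  # tame separation blow-ups
      v["beta0"] <- cf[1]
      if (J > 0) v[paste0("beta_x", seq_len(J))] <- cf[1 + seq_len(J)]
      v["beta_g"] <- cf[J + 2]
      v["beta_m"] <- cf[J + 3]
      v["beta_e"] <- cf[J + 4]
    }
  } else {
    pbar <- min(max(mean(y01), 0.05), 0.95)
    v["beta0"] <- stats::qlogis(pbar)
  }
  b <- param_bounds(J)
  pmin(pmax(v, b$lower + 1e-8), b$upper - 1e-8)
}

#' Maximum likelihood fit of the trio model
#'
#' Maximizes [trio_loglik()] by L-BFGS-B with box constraints (variances
#' bounded below, allele frequency kept interior). Parameters named in
#' `constrained` are fixed at zero and removed from the search space, which
#' is how the null models of the likelihood ratio tests are fitted. The fit
#' is deterministic given `data` and `start`; on non-convergence one restart
#' from a deterministically jittered start is attempted and the better of
#' the two solutions is kept.
#'
#' @param data A [trio_data()] object.
#' @param constrained Character vector of parameter names to fix at zero
#'   (e.g. `c("beta_g", "beta_m", "beta_e")` for the trio null).
#' @param start Optional [trio_params()] with starting values; by default a
#'   deterministic start is derived from least-squares and logistic fits on
#'   the observed strata.
#' @return An object of class `"trio_fit"`: a list with `params` (the
#'   [trio_params()] at the optimum), `loglik`, `converged`, `n_iter`,
#'   `constrained`, and `message`.
#' @examples
#' cfg <- sim_config(n_case = 60, n_control = 60, seed = 1)
#' d <- simulate_trio_data(cfg)
#' f <- fit_trio(d)
#' f$loglik
#' @export
fit_trio <- function(data, constrained = character(0), start = NULL) {
  J <- ncol(data$X)
  nm <- param_names(J)
  bad <- setdiff(constrained, nm)
  if (length(bad)) stop("unknown parameter name(s): ",
                        paste(bad, collapse = ", "))
  if (data$n[["n1"]] < 1 && (data$n[["n2"]] < 1 || data$n[["n3"]] < 1))
    warning("few informative strata: some parameters may be weakly identified")
  if (length(unique(data$G)) == 1L)
    warning("monomorphic genotype: allele frequency estimate is at a boundary")

  full <- if (is.null(start)) start_values(data) else
    params_to_vector(start, J)
  full[constrained] <- 0
  free <- setdiff(nm, constrained)
  free_i <- match(free, nm)
  b <- param_bounds(J)

  M0 <- ifelse(is.na(data$M), 0, data$M)
  E0 <- ifelse(is.na(data$E), 0, data$E)
  fn <- function(par) {
    full[free_i] <- par
    cpp_negloglik(full, data$y, data$X, data$G, M0, E0, data$scheme)
  }
  gr <- function(par) {
    full[free_i] <- par
    cpp_negloglik_agrad(full, data$y, data$X, data$G, M0, E0,
                        data$scheme)[free_i]
  }
  run <- function(p0) {
    tryCatch(
      stats::optim(p0, fn, gr, method = "L-BFGS-B",
                   lower = b$lower[free_i], upper = b$upper[free_i],
                   control = list(maxit = 500L, factr = 1e8)),
      error = function(e) list(par = p0, value = fn(p0), convergence = 52L,
                               counts = c(0L, 0L), message = conditionMessage(e)))
  }
  opt <- run(full[free_i])
  if (opt$convergence != 0L) {
    jitter <- 0.1 * (1 + abs(full[free_i])) *
      rep_len(c(0.5, -0.5, 0.25, -0.25), length(free_i))
    p1 <- pmin(pmax(full[free_i] + jitter, b$lower[free_i] + 1e-8),
               b$upper[free_i] - 1e-8)
    opt2 <- run(p1)
    if (opt2$value < opt$value) opt <- opt2
  }
  full[free_i] <- opt$par
  structure(list(params = vector_to_params(full, J),
                 loglik = -opt$value,
                 converged = opt$convergence == 0L,
                 n_iter = unname(opt$counts[1]),
                 constrained = constrained,
                 message = if (is.null(opt$message)) "" else opt$message),
            class = "trio_fit")
}

#' @export
print.trio_fit <- function(x, ...) {
  cat("Trio model fit: loglik =", format(x$loglik, digits = 8),
      if (!x$converged) "(NOT converged)" else "", "\n")
  if (length(x$constrained))
    cat("  constrained to zero:", paste(x$constrained, collapse = ", "), "\n")
  print(x$params)
  invisible(x)
}
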