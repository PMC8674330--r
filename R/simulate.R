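#' Simulation configuration
#'
#' Collects every knob of the synthetic case-control trio generator. The
#' defaults are the generative study conditions used throughout the
#' simulation harness: a cis-SNP at minor-allele frequency 0.2 under
#' Hardy-Weinberg equilibrium in controls, case genotypes from an additive
#' genotype-relative-risk model (relative risk 1.2, disease prevalence
#' 0.1), methylation and expression from the two-layer Gaussian regressions
#' with \eqn{\alpha_0 = 1.3, \alpha_g = 2.4, \gamma_0 = 1.9, \gamma_g =
#' 0.6, \gamma_m = 2.3, \sigma_1^2 = \sigma_2^2 = 1}, a case-control mean
#' separation of 0.3 in the (methylation, expression) pair, phenotype-model
#' coefficients \eqn{\beta_0 = 1, \beta_x = (0.01, 0.01), \beta_g = 0.1,
#' \beta_m = 0.2, \beta_e = 0.3}, and covariates age ~ N(40, sd 6) and
#' sex ~ Bernoulli(0.5).
#'
#' @param n_case,n_control Per-stratum sample sizes.
#' @param maf Minor-allele frequency of the SNP in controls.
#' @param rr Genotype relative risk per minor-allele copy.
#' @param prevalence Disease prevalence used to anchor the penetrances.
#' @param alpha0,alpha_g Methylation model intercept and genotype effect.
#' @param gamma0,gamma_g,gamma_m Expression model coefficients.
#' @param sigma1_sq,sigma2_sq Error variances of the two omics models.
#' @param case_shift Mean separation added to the case (M, E) pair.
#' @param beta0,beta_x,beta_g,beta_m,beta_e Phenotype model coefficients.
#' @param age_mean,age_sd,sex_prob Covariate distributions.
#' @param m_both,m_meth_only,m_expr_only Fractions of individuals with both
#'   omics missing, only methylation missing, only expression missing.
#' @param null_scenario If `TRUE`, generate under the global null: both
#'   strata draw genotypes from the control law and no case shift is
#'   applied, so (G, M, E) carries no phenotype information.
#' @param mode `"retrospective"` (default): case/control labels are fixed
#'   by stratum and case omics/genotypes follow the shifted laws.
#'   `"prospective"`: individuals are drawn from the control (population)
#'   law, the phenotype is drawn from the Bernoulli logistic model, and
#'   sampling continues until both quotas fill. `"rejection"`: intended
#'   cases (controls) are drawn from the shifted (unshifted) laws, the
#'   phenotype is drawn from the Bernoulli logistic model, and individuals
#'   are kept only when the drawn phenotype matches the intended stratum.
#' @param rr_model `"additive"` (penetrance increments equal per allele
#'   copy) or `"multiplicative"` (penetrance multiplied by `rr` per copy).
#' @param shift_mode How the case mean separation enters: `"conditional"`
#'   (default) adds `case_shift` to methylation and, conditionally on
#'   methylation, to expression (expression is generated from the shifted
#'   methylation); `"marginal"` adds `case_shift` to both values after
#'   generation, shifting each marginal mean by exactly `case_shift`.
#' @param seed Optional RNG seed; when set, generation is reproducible.
#' @return An object of class `"sim_config"` (a named list).
#' @export
sim_config <- function(n_case = 200, n_control = 200,
                       maf = 0.2, rr = 1.2, prevalence = 0.1,
                       alpha0 = 1.3, alpha_g = 2.4,
                       gamma0 = 1.9, gamma_g = 0.6, gamma_m = 2.3,
                       sigma1_sq = 1, sigma2_sq = 1,
                       case_shift = 0.3,
                       beta0 = 1, beta_x = c(0.01, 0.01),
                       beta_g = 0.1, beta_m = 0.2, beta_e = 0.3,
                       age_mean = 40, age_sd = 6, sex_prob = 0.5,
                       m_both = 0, m_meth_only = 0, m_expr_only = 0,
                       null_scenario = FALSE,
                       mode = c("retrospective", "prospective", "rejection"),
                       rr_model = c("additive", "multiplicative"),
                       shift_mode = c("conditional", "marginal"),
                       seed = NULL) {
  if (m_both < 0 || m_meth_only < 0 || m_expr_only < 0 ||
      m_both + m_meth_only + m_expr_only > 1)
    stop("missing fractions must be in [0,1] and sum to at most 1")
  stopifnot(maf > 0, maf < 1, prevalence > 0, prevalence < 1, rr > 0)
  structure(list(n_case = n_case, n_control = n_control, maf = maf, rr = rr,
                 prevalence = prevalence, alpha0 = alpha0, alpha_g = alpha_g,
                 gamma0 = gamma0, gamma_g = gamma_g, gamma_m = gamma_m,
                 sigma1_sq = sigma1_sq, sigma2_sq = sigma2_sq,
                 case_shift = case_shift, beta0 = beta0, beta_x = beta_x,
                 beta_g = beta_g, beta_m = beta_m, beta_e = beta_e,
                 age_mean = age_mean, age_sd = age_sd, sex_prob = sex_prob,
                 m_both = m_both, m_meth_only = m_meth_only,
                 m_expr_only = m_expr_only, null_scenario = null_scenario,
                 mode = match.arg(mode), rr_model = match.arg(rr_model),
                 shift_mode = match.arg(shift_mode), seed = seed),
            class = "sim_config")
}

#' Case genotype frequencies under a relative-risk model
#'
#' Controls follow Hardy-Weinberg equilibrium at the given minor-allele
#' frequency. Penetrances are anchored by the prevalence: with baseline
#' penetrance \eqn{f_0} solved from
#' \eqn{prevalence = \sum_g f_g P_{HWE}(g)}, the additive model sets
#' \eqn{f_1 = f_0 \cdot rr} and \eqn{f_2 = f_0 (2 rr - 1)} (equal
#' increments per allele copy); the multiplicative model sets
#' \eqn{f_g = f_0 \cdot rr^g}. Bayes inversion then gives the case law
#' \eqn{P(g \mid case) = f_g P_{HWE}(g) / prevalence}.
#'
#' @param maf Minor-allele frequency.
#' @param rr Genotype relative risk.
#' @param prevalence Disease prevalence.
#' @param rr_model `"additive"` or `"multiplicative"`.
#' @return Named probability 3-vector `c(g0, g1, g2)` (minor-allele count),
#'   summing to one.
#' @examples
#' genotype_freqs_case(0.2, 1.2, 0.1)
#' @export
genotype_freqs_case <- function(maf, rr, prevalence,
                                rr_model = c("additive", "multiplicative")) {
  rr_model <- match.arg(rr_model)
  hwe <- stats::dbinom(0:2, 2, maf)
  w <- if (rr_model == "additive") 1 + (rr - 1) * (0:2) else rr^(0:2)
  if (any(w <= 0)) stop("infeasible relative-risk configuration")
  f0 <- prevalence / sum(w * hwe)
  f <- f0 * w
  if (f0 <= 0 || any(f >= 1))
    stop("infeasible penetrances for this (maf, rr, prevalence)")
  stats::setNames(f * hwe / prevalence, c("g0", "g1", "g2"))
}

#' Simulate covariates
#'
#' Column 1 is age ~ Normal(`age_mean`, sd `age_sd`); column 2 is
#' sex ~ Bernoulli(`sex_prob`).
#'
#' @param n Number of individuals.
#' @param config A [sim_config()].
#' @return An `n x 2` matrix with columns `age` and `sex`.
#' @export
simulate_covariates <- function(n, config) {
  cbind(age = stats::rnorm(n, config$age_mean, config$age_sd),
        sex = stats::rbinom(n, 1, config$sex_prob))
}

#' Simulate methylation and expression given genotype
#'
#' Draws \eqn{M = \alpha_0 + \alpha_g G + \epsilon_1} and
#' \eqn{E = \gamma_0 + \gamma_g G + \gamma_m M + \epsilon_2} with
#' independent normal errors, then applies the case-control mean
#' separation according to `config$shift_mode` (no shift under the null
#' scenario).
#'
#' @param G Genotype vector.
#' @param case_flag Logical vector marking cases.
#' @param config A [sim_config()].
#' @return A list with numeric vectors `M` and `E`.
#' @export
simulate_omics <- function(G, case_flag, config) {
  n <- length(G)
  shift <- if (config$null_scenario) 0 else config$case_shift
  s <- shift * as.numeric(case_flag)
  M <- config$alpha0 + config$alpha_g * G +
    stats::rnorm(n, 0, sqrt(config$sigma1_sq)) + s
  E <- config$gamma0 + config$gamma_g * G +
    config$gamma_m * (if (config$shift_mode == "conditional") M else M - s) +
    stats::rnorm(n, 0, sqrt(config$sigma2_sq)) + s
  list(M = M, E = E)
}

eq1_linear_predictor <- function(X, G, M, E, config) {
  config$beta0 + drop(X %*% config$beta_x) + config$beta_g * G +
    config$beta_m * M + config$beta_e * E
}

#' Simulate a complete case-control trio dataset
#'
#' In the default retrospective mode, `n_case` cases and `n_control`
#' controls are generated by stratum: control genotypes from the
#' Hardy-Weinberg law, case genotypes from [genotype_freqs_case()], and
#' case omics shifted by `case_shift`; the logistic phenotype probability
#' of every individual is recorded as a diagnostic attribute
#' (`"bernoulli_prob"`) but the labels are fixed by design. In prospective
#' mode, individuals are drawn from the population (control) law, labels
#' are drawn from the Bernoulli logistic phenotype model, and sampling
#' continues until both quotas fill. Under `null_scenario` the two strata
#' share one generative law for (G, M, E).
#'
#' @param config A [sim_config()]. If `config$seed` is set the output is
#'   reproducible; missingness fractions in the config are applied via
#'   [inject_missingness()].
#' @return A [trio_data()] object (cases first, then controls) with
#'   attribute `"bernoulli_prob"`.
#' @export
simulate_trio_data <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  d <- switch(config$mode,
              prospective = simulate_prospective(config),
              rejection = simulate_rejection(config),
              simulate_retrospective(config))
  if (config$m_both > 0 || config$m_meth_only > 0 || config$m_expr_only > 0) {
    pr <- attr(d, "bernoulli_prob")
    d <- inject_missingness(d, config$m_both, config$m_meth_only,
                            config$m_expr_only)
    attr(d, "bernoulli_prob") <- pr
  }
  d
}

simulate_retrospective <- function(config) {
  n_ca <- config$n_case; n_co <- config$n_control
  G_co <- stats::rbinom(n_co, 2, config$maf)
  G_ca <- if (config$null_scenario) stats::rbinom(n_ca, 2, config$maf)
  else sample(0:2, n_ca, replace = TRUE,
              prob = genotype_freqs_case(config$maf, config$rr,
                                         config$prevalence, config$rr_model))
  G <- c(G_ca, G_co)
  case_flag <- c(rep(TRUE, n_ca), rep(FALSE, n_co))
  X <- simulate_covariates(n_ca + n_co, config)
  ome <- simulate_omics(G, case_flag, config)
  d <- trio_data(y = ifelse(case_flag, 1, -1), X = X, G = G,
                 M = ome$M, E = ome$E)
  attr(d, "bernoulli_prob") <-
    sigmoid(eq1_linear_predictor(X, G, ome$M, ome$E, config))
  d
}

simulate_prospective <- function(config) {
  n_ca <- config$n_case; n_co <- config$n_control
  acc <- list()
  got_ca <- 0L; got_co <- 0L
  guard <- 0L
  while ((got_ca < n_ca || got_co < n_co) && guard < 1000L) {
    guard <- guard + 1L
    nb <- max(2L * (n_ca + n_co), 1000L)
    G <- stats::rbinom(nb, 2, config$maf)
    X <- simulate_covariates(nb, config)
    cfg0 <- config; cfg0$null_scenario <- TRUE  # population law: no shift
    ome <- simulate_omics(G, rep(FALSE, nb), cfg0)
    cfg_eta <- config
    if (config$null_scenario) {
      cfg_eta$beta_g <- 0; cfg_eta$beta_m <- 0; cfg_eta$beta_e <- 0
    }
    pr <- sigmoid(eq1_linear_predictor(X, G, ome$M, ome$E, cfg_eta))
    yb <- stats::rbinom(nb, 1, pr)
    keep_ca <- which(yb == 1)[seq_len(min(n_ca - got_ca, sum(yb == 1)))]
    keep_co <- which(yb == 0)[seq_len(min(n_co - got_co, sum(yb == 0)))]
    keep <- c(keep_ca, keep_co)
    acc[[length(acc) + 1L]] <-
      list(y = yb[keep], X = X[keep, , drop = FALSE], G = G[keep],
           M = ome$M[keep], E = ome$E[keep], pr = pr[keep])
    got_ca <- got_ca + length(keep_ca); got_co <- got_co + length(keep_co)
  }
  if (got_ca < n_ca || got_co < n_co)
    stop("prospective sampling failed to fill the case/control quotas")
  y <- unlist(lapply(acc, `[[`, "y"))
  ord <- order(-y)  # cases first, in draw order
  X <- do.call(rbind, lapply(acc, `[[`, "X"))[ord, , drop = FALSE]
  d <- trio_data(y = y[ord], X = X,
                 G = unlist(lapply(acc, `[[`, "G"))[ord],
                 M = unlist(lapply(acc, `[[`, "M"))[ord],
                 E = unlist(lapply(acc, `[[`, "E"))[ord])
  attr(d, "bernoulli_prob") <- unlist(lapply(acc, `[[`, "pr"))[ord]
  d
}

simulate_rejection <- function(config) {
  draw_stratum <- function(n_want, as_case) {
    kept <- list(); got <- 0L; guard <- 0L
    while (got < n_want && guard < 1000L) {
      guard <- guard + 1L
      nb <- max(4L * n_want, 500L)
      G <- if (as_case && !config$null_scenario)
        sample(0:2, nb, replace = TRUE,
               prob = genotype_freqs_case(config$maf, config$rr,
                                          config$prevalence, config$rr_model))
      else stats::rbinom(nb, 2, config$maf)
      X <- simulate_covariates(nb, config)
      ome <- simulate_omics(G, rep(as_case, nb), config)
      cfg_eta <- config
      if (config$null_scenario) {
        cfg_eta$beta_g <- 0; cfg_eta$beta_m <- 0; cfg_eta$beta_e <- 0
      }
      pr <- sigmoid(eq1_linear_predictor(X, G, ome$M, ome$E, cfg_eta))
      yb <- stats::rbinom(nb, 1, pr)
      keep <- which(yb == if (as_case) 1L else 0L)
      keep <- keep[seq_len(min(n_want - got, length(keep)))]
      if (length(keep))
        kept[[length(kept) + 1L]] <-
          list(X = X[keep, , drop = FALSE], G = G[keep], M = ome$M[keep],
               E = ome$E[keep], pr = pr[keep])
      got <- got + length(keep)
    }
    if (got < n_want)
      stop("rejection sampling failed to fill the ",
           if (as_case) "case" else "control", " quota")
    kept
  }
  ca <- draw_stratum(config$n_case, TRUE)
  co <- draw_stratum(config$n_control, FALSE)
  both <- c(ca, co)
  d <- trio_data(y = rep(c(1, -1), c(config$n_case, config$n_control)),
                 X = do.call(rbind, lapply(both, `[[`, "X")),
                 G = unlist(lapply(both, `[[`, "G")),
                 M = unlist(lapply(both, `[[`, "M")),
                 E = unlist(lapply(both, `[[`, "E")))
  attr(d, "bernoulli_prob") <- unlist(lapply(both, `[[`, "pr"))
  d
}

#' Blank omics values completely at random
#'
#' Selects disjoint random subsets of the requested fractions - balanced
#' across cases and controls - and blanks both omics, only methylation, or
#' only expression for them. Counts are `round(fraction * stratum size)`
#' per stratum.
#'
#' @param data A complete [trio_data()] object.
#' @param m_both Fraction with both omics blanked.
#' @param m_meth_only Fraction with only methylation blanked.
#' @param m_expr_only Fraction with only expression blanked.
#' @return A new [trio_data()] with the updated missingness partition.
#' @export
inject_missingness <- function(data, m_both, m_meth_only, m_expr_only) {
  if (m_both + m_meth_only + m_expr_only > 1)
    stop("missing fractions sum to more than 1")
  M <- data$M; E <- data$E
  for (stratum in c(1, -1)) {
    rows <- which(data$y == stratum)
    n_s <- length(rows)
    k_b <- round(m_both * n_s)
    k_m <- round(m_meth_only * n_s)
    k_e <- round(m_expr_only * n_s)
    if (k_b + k_m + k_e > n_s)
      stop("rounded missingness counts exceed the stratum size")
    pick <- sample(rows, k_b + k_m + k_e)
    i_b <- pick[seq_len(k_b)]
    i_m <- pick[k_b + seq_len(k_m)]
    i_e <- pick[k_b + k_m + seq_len(k_e)]
    M[c(i_b, i_m)] <- NA
    E[c(i_b, i_e)] <- NA
  }
  trio_data(y = data$y, X = data$X, G = data$G, M = M, E = E)
}

#' Extract the generative parameters of a simulation configuration
#'
#' @param config A [sim_config()].
#' @return The corresponding [trio_params()] (under the null scenario the
#'   three omics effects are zero).
#' @export
sim_true_params <- function(config) {
  null <- config$null_scenario
  trio_params(beta0 = config$beta0, beta_x = config$beta_x,
              beta_g = if (null) 0 else config$beta_g,
              beta_m = if (null) 0 else config$beta_m,
              beta_e = if (null) 0 else config$beta_e,
              alpha0 = config$alpha0, alpha_g = config$alpha_g,
              gamma0 = config$gamma0, gamma_g = config$gamma_g,
              gamma_m = config$gamma_m,
              sigma1_sq = config$sigma1_sq, sigma2_sq = config$sigma2_sq,
              p = config$maf)
}
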