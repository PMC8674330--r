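#' Monte-Carlo type I error of the trio test
#'
#' Simulates `n_reps` datasets under the null scenario of `config`, runs the
#' trio likelihood ratio test on each, and reports the fraction rejected at
#' the asymptotic `level`.
#'
#' @param config A [sim_config()]; `null_scenario` is forced to `TRUE`.
#' @param n_reps Number of replicate datasets.
#' @param level Nominal significance level.
#' @param seed RNG seed for the whole study.
#' @return A `"power_study"` list: `rejection_rate`, `mc_se` (binomial
#'   Monte-Carlo standard error), `n_reps`, `level`, `lambdas` (the null
#'   statistics, reusable for empirical cutoffs), `scheme`, `sample_size`.
#' @export
estimate_type1 <- function(config, n_reps = 2000, level = 0.05, seed = 1) {
  config$null_scenario <- TRUE
  lam <- simulate_lambdas(config, n_reps, seed)
  r <- mean(lam > stats::qchisq(1 - level, df = 3))
  power_study(r, n_reps, level, lam, config, cutoff_source = "asymptotic")
}

#' Empirical null cutoff for power comparisons
#'
#' The empirical `(1 - level)` quantile of the null distribution of the
#' trio LRT statistic for a given missingness scheme and sample size, used
#' so that power comparisons hold the type I error at exactly `level` on
#' the calibration sample.
#'
#' @inheritParams estimate_type1
#' @return The cutoff (scalar). The simulated null statistics are attached
#'   as attribute `"lambdas"`.
#' @export
empirical_cutoff <- function(config, n_reps = 2000, level = 0.05, seed = 1) {
  config$null_scenario <- TRUE
  lam <- simulate_lambdas(config, n_reps, seed)
  structure(unname(stats::quantile(lam, 1 - level)), lambdas = lam)
}

#' Monte-Carlo power of the trio test
#'
#' Simulates `n_reps` datasets under the alternative scenario of `config`
#' and reports the fraction with LRT statistic above `cutoff` (an
#' empirical-null cutoff from [empirical_cutoff()], or an asymptotic
#' chi-square quantile).
#'
#' @inheritParams estimate_type1
#' @param cutoff Rejection threshold on the Lambda scale.
#' @return A `"power_study"` list as in [estimate_type1()].
#' @export
estimate_power <- function(config, n_reps = 500, cutoff, seed = 1) {
  config$null_scenario <- FALSE
  lam <- simulate_lambdas(config, n_reps, seed)
  r <- mean(lam > cutoff)
  power_study(r, n_reps, NA_real_, lam, config, cutoff_source = "empirical",
              cutoff = cutoff)
}

simulate_lambdas <- function(config, n_reps, seed) {
  set.seed(seed)
  config$seed <- NULL  # one stream for the whole study
  vapply(seq_len(n_reps),
         function(i) trio_lrt(simulate_trio_data(config))$lambda,
         numeric(1))
}

power_study <- function(rate, n_reps, level, lambdas, config,
                        cutoff_source, cutoff = NA_real_) {
  structure(list(rejection_rate = rate,
                 mc_se = sqrt(rate * (1 - rate) / n_reps),
                 n_reps = n_reps, level = level,
                 cutoff_source = cutoff_source, cutoff = cutoff,
                 lambdas = lambdas,
                 scheme = c(both = config$m_both, meth = config$m_meth_only,
                            expr = config$m_expr_only),
                 sample_size = c(case = config$n_case,
                                 control = config$n_control)),
            class = "power_study")
}

#' @export
print.power_study <- function(x, ...) {
  cat(sprintf("Rejection rate %.4f (MC SE %.4f, %d replicates)\n",
              x$rejection_rate, x$mc_se, x$n_reps))
  cat(sprintf("  scheme (both, meth-only, expr-only) = (%g, %g, %g), n = %d + %d\n",
              x$scheme[1], x$scheme[2], x$scheme[3],
              x$sample_size[1], x$sample_size[2]))
  invisible(x)
}

#' Case probability for an individual under a fitted model
#'
#' Returns \eqn{P(Y = +1)} given the observed layers: the exact logistic
#' model when methylation and expression are both present, and the
#' matching analytically marginalized kernel when one or both are missing.
#'
#' @param params A [trio_params()] (typically a fitted one).
#' @param x Covariate vector.
#' @param g Genotype.
#' @param m,e Methylation and expression; pass `NA` for a missing layer.
#' @return The case probability.
#' @export
classify_prob <- function(params, x, g, m = NA, e = NA) {
  if (!is.na(m) && !is.na(e))
    sigmoid(xbeta(x, params) + params$beta_g * g + params$beta_m * m +
              params$beta_e * e)
  else if (is.na(e) && !is.na(m)) cond_prob_missing_e(1, x, g, m, params)
  else if (is.na(m) && !is.na(e)) cond_prob_missing_m(1, x, g, e, params)
  else cond_prob_missing_em(1, x, g, params)
}

cv_fold_assignments <- function(idx_complete, y, k = 10) {
  folds <- integer(length(y))
  for (stratum in c(1, -1)) {
    rows <- idx_complete[y[idx_complete] == stratum]
    folds[sample(rows)] <- rep_len(seq_len(k), length(rows))
  }
  folds
}

#' Tenfold cross-validated classification performance
#'
#' Individuals with complete omics are split into ten case/control-
#' stratified blocks. Each block in turn is the test set; all remaining
#' individuals - including those with missing omics, who enter through the
#' marginalized likelihood - form the training set on which the full model
#' is fitted. Test individuals are classified as cases when their fitted
#' case probability exceeds `threshold`.
#'
#' @param data A [trio_data()] object with at least 10 complete cases and
#'   complete individuals of both classes.
#' @param threshold Classification threshold on the case probability.
#' @param seed RNG seed for the fold assignment.
#' @param keep_probs Also return the out-of-fold case probabilities.
#' @return A list with `accuracy`, `sensitivity`, `specificity` (averaged
#'   over folds) and, if requested, `probs`/`truth` for the complete cases.
#' @export
crossvalidate_tenfold <- function(data, threshold = 0.5, seed = 1,
                                  keep_probs = FALSE) {
  idx_complete <- which(data$scheme == 0L)
  if (length(idx_complete) < 10)
    stop("tenfold cross-validation needs at least 10 complete individuals")
  set.seed(seed)
  folds <- cv_fold_assignments(idx_complete, data$y)
  acc <- sens <- spec <- numeric(0)
  probs <- rep(NA_real_, length(data$y))
  for (k in sort(unique(folds[folds > 0]))) {
    test_i <- which(folds == k)
    train <- trio_data_subset(data, setdiff(seq_along(data$y), test_i))
    fit <- fit_trio(train)
    pk <- vapply(test_i, function(i)
      classify_prob(fit$params, data$X[i, ], data$G[i], data$M[i],
                    data$E[i]), numeric(1))
    probs[test_i] <- pk
    pred <- ifelse(pk > threshold, 1, -1)
    truth <- data$y[test_i]
    acc <- c(acc, mean(pred == truth))
    sens <- c(sens, if (any(truth == 1)) mean(pred[truth == 1] == 1) else NA)
    spec <- c(spec, if (any(truth == -1)) mean(pred[truth == -1] == -1) else NA)
  }
  out <- list(accuracy = mean(acc),
              sensitivity = mean(sens, na.rm = TRUE),
              specificity = mean(spec, na.rm = TRUE))
  if (keep_probs) {
    out$probs <- probs[idx_complete]
    out$truth <- data$y[idx_complete]
  }
  out
}

#' Cross-validated ROC operating points
#'
#' Computes out-of-fold case probabilities once via
#' [crossvalidate_tenfold()] and sweeps a threshold grid, returning one
#' (1 - specificity, sensitivity) point per threshold.
#'
#' @param data A [trio_data()] object.
#' @param thresholds Numeric threshold grid (default 101 uniform points).
#' @param seed RNG seed for the fold assignment.
#' @return A data frame with columns `threshold`, `fpr`, `sensitivity`.
#' @export
roc_points <- function(data, thresholds = seq(0, 1, length.out = 101),
                       seed = 1) {
  cv <- crossvalidate_tenfold(data, seed = seed, keep_probs = TRUE)
  pts <- t(vapply(thresholds, function(th) {
    pred <- ifelse(cv$probs > th, 1, -1)
    c(fpr = mean(pred[cv$truth == -1] == 1),
      sensitivity = mean(pred[cv$truth == 1] == 1))
  }, c(fpr = 0, sensitivity = 0)))
  data.frame(threshold = thresholds, pts)
}

#' Baseline fits: complete-case and imputation strategies
#'
#' The comparison methods of the simulation study. `complete_case` drops
#' every individual with any missing omics and fits the complete-data
#' likelihood. `mean_impute` fills each missing value with the observed
#' column mean. `knn_impute` fills a missing value with the average of the
#' `k` nearest neighbours among fully observed donors, with distances
#' computed over standardized always-observed features (covariates,
#' genotype, and the other omic when present). Both imputation strategies
#' then fit the complete-data likelihood on the filled-in data.
#'
#' @param data A [trio_data()] object.
#' @param strategy One of `"complete_case"`, `"mean_impute"`, `"knn_impute"`.
#' @param constrained Passed through to [fit_trio()].
#' @param k Neighbourhood size for KNN imputation.
#' @return A [fit_trio()] result; the (possibly reduced or imputed) dataset
#'   is attached as attribute `"data"`.
#' @export
baseline_fit <- function(data,
                         strategy = c("complete_case", "mean_impute",
                                      "knn_impute"),
                         constrained = character(0), k = 5) {
  strategy <- match.arg(strategy)
  d <- switch(strategy,
              complete_case = trio_data_subset(data, data$scheme == 0L),
              mean_impute = impute_mean(data),
              knn_impute = impute_knn(data, k = k))
  fit <- fit_trio(d, constrained = constrained)
  attr(fit, "data") <- d
  fit
}

impute_mean <- function(data) {
  M <- data$M; E <- data$E
  M[is.na(M)] <- mean(M, na.rm = TRUE)
  E[is.na(E)] <- mean(E, na.rm = TRUE)
  trio_data(y = data$y, X = data$X, G = data$G, M = M, E = E)
}

scale_cols <- function(Z) {
  apply(Z, 2, function(z) {
    s <- stats::sd(z)
    if (!is.finite(s) || s == 0) rep(0, length(z)) else (z - mean(z)) / s
  })
}

impute_knn <- function(data, k = 5) {
  M <- data$M; E <- data$E
  feat <- scale_cols(cbind(data$X, G = data$G))
  fill <- function(target, other) {
    miss <- which(is.na(target))
    if (!length(miss)) return(target)
    donors <- which(!is.na(target))
    if (length(donors) < 1) stop("no observed donors for KNN imputation")
    for (i in miss) {
      use_other <- !is.na(other[i]) & !is.na(other[donors])
      d2 <- rowSums((feat[donors, , drop = FALSE] -
                       matrix(feat[i, ], length(donors), ncol(feat),
                              byrow = TRUE))^2)
      if (any(use_other)) {
        oo <- scale_cols(cbind(other[donors[use_other]]))
        # restrict to donors sharing the other omic and include it
        dd <- donors[use_other]
        oi <- (other[i] - mean(other[dd])) /
          max(stats::sd(other[dd]), 1e-12)
        d2 <- d2[use_other] + (oo[, 1] - oi)^2
        nn <- dd[order(d2)[seq_len(min(k, length(dd)))]]
      } else {
        nn <- donors[order(d2)[seq_len(min(k, length(donors)))]]
      }
      target[i] <- mean(target[nn])
    }
    target
  }
  M2 <- fill(M, E)
  E2 <- fill(E, M)
  trio_data(y = data$y, X = data$X, G = data$G, M = M2, E = E2)
}
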