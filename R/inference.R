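#' Likelihood ratio test for a trio
#'
#' Tests whether any of the omics coefficients of the phenotype model are
#' nonzero. The default null is \eqn{H_0: \beta_e = \beta_m = \beta_g = 0}
#' (the full trio test, 3 df); `tested` may name any nonempty subset of
#' these for duo or single-omic tests, in which case the degrees of freedom
#' equal the subset size. The statistic is
#' \eqn{\Lambda = 2(\ell_{alt} - \ell_{null})} and the p-value comes from
#' the asymptotic upper \eqn{\chi^2_{df}} tail. Tiny negative \eqn{\Lambda}
#' from optimizer noise is clamped to zero; if the alternative fit lands
#' below the null fit it is refitted starting from the null optimum so the
#' nesting inequality holds.
#'
#' @param data A [trio_data()] object.
#' @param tested Character subset of `c("beta_g", "beta_m", "beta_e")` to
#'   constrain under the null.
#' @param trio_id Optional identifier carried into the result (e.g. a
#'   `(gene, snp, cpg)` label).
#' @return An object of class `"trio_test"`: a list with `lambda`, `df`,
#'   `p_value`, `fit_null`, `fit_alt`, `tested`, `trio_id`, `converged`.
#' @examples
#' d <- simulate_trio_data(sim_config(n_case = 80, n_control = 80, seed = 2))
#' tt <- trio_lrt(d)
#' tt$p_value
#' @export
trio_lrt <- function(data, tested = c("beta_g", "beta_m", "beta_e"),
                     trio_id = NULL) {
  tested <- match.arg(tested, c("beta_g", "beta_m", "beta_e"),
                      several.ok = TRUE)
  fit_alt <- fit_trio(data)
  null_start <- fit_alt$params
  for (nm in tested) null_start[[nm]] <- 0
  fit_null <- fit_trio(data, constrained = tested, start = null_start)
  if (fit_alt$loglik < fit_null$loglik) {
    # nested optima must satisfy l_alt >= l_null; restart alt from the null
    retry <- fit_trio(data, start = fit_null$params)
    if (retry$loglik > fit_alt$loglik) fit_alt <- retry
  }
  lambda <- 2 * (fit_alt$loglik - fit_null$loglik)
  if (lambda < 0) {
    if (lambda < -1e-6)
      warning("negative LRT statistic (", format(lambda),
              ") clamped to zero; optimizer may not have converged")
    lambda <- 0
  }
  df <- length(tested)
  structure(list(lambda = lambda, df = df,
                 p_value = stats::pchisq(lambda, df, lower.tail = FALSE),
                 fit_null = fit_null, fit_alt = fit_alt,
                 tested = tested, trio_id = trio_id,
                 converged = fit_null$converged && fit_alt$converged),
            class = "trio_test")
}

#' @export
print.trio_test <- function(x, ...) {
  cat("Trio likelihood ratio test",
      if (!is.null(x$trio_id)) paste0("[", paste(x$trio_id, collapse = "/"), "]"),
      "\n")
  cat("  H0:", paste(x$tested, collapse = " = "), "= 0\n")
  cat("  Lambda =", format(x$lambda, digits = 6),
      " df =", x$df,
      " p =", format.pval(x$p_value, digits = 4),
      if (!x$converged) " (fit did not converge)" else "", "\n")
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment applied across all trio tests of
#' a screen (one family). Thin wrapper over [stats::p.adjust()].
#'
#' @param p_values Numeric vector of raw p-values.
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) stats::p.adjust(p_values, method = "BH")

#' Batch trio screen with FDR correction
#'
#' Runs the trio likelihood ratio test for every entry of a trio catalog,
#' adjusts the p-values by Benjamini-Hochberg across all tests, and returns
#' a tidy results table sorted by adjusted p-value. A failing trio (e.g. a
#' malformed dataset) is recorded with status `"error"` rather than aborting
#' the batch.
#'
#' @param catalog A catalog from [build_trio_catalog()] (or any data frame
#'   with columns `gene_id`, `snp_id`, `cpg_id`).
#' @param data_for A function taking one catalog row (as a list) and
#'   returning the [trio_data()] for that trio.
#' @param alpha Significance level used for the `significant` flag on the
#'   adjusted p-values.
#' @return A data frame with one row per trio: identifiers, `lambda`, `df`,
#'   `p`, `p_adj`, `converged`, `status`, `significant`, sorted by `p_adj`.
#' @export
run_trio_screen <- function(catalog, data_for, alpha = 0.05) {
  entries <- as.data.frame(catalog)
  out <- data.frame(gene_id = character(0), snp_id = character(0),
                    cpg_id = character(0), lambda = numeric(0),
                    df = integer(0), p = numeric(0), p_adj = numeric(0),
                    converged = logical(0), status = character(0),
                    significant = logical(0))
  if (nrow(entries) == 0L) return(out)
  rows <- lapply(seq_len(nrow(entries)), function(i) {
    entry <- as.list(entries[i, ])
    res <- tryCatch(trio_lrt(data_for(entry)), error = function(e) e)
    if (inherits(res, "error")) {
      warning("trio ", entry$gene_id, "/", entry$snp_id, "/", entry$cpg_id,
              " failed: ", conditionMessage(res))
      data.frame(gene_id = entry$gene_id, snp_id = entry$snp_id,
                 cpg_id = entry$cpg_id, lambda = NA_real_, df = NA_integer_,
                 p = NA_real_, converged = FALSE, status = "error")
    } else {
      data.frame(gene_id = entry$gene_id, snp_id = entry$snp_id,
                 cpg_id = entry$cpg_id, lambda = res$lambda, df = res$df,
                 p = res$p_value, converged = res$converged, status = "ok")
    }
  })
  res <- do.call(rbind, rows)
  res$p_adj <- NA_real_
  ok <- !is.na(res$p)
  res$p_adj[ok] <- bh_adjust(res$p[ok])
  res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
  res[order(res$p_adj), , drop = FALSE]
}
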