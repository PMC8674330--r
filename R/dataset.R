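#' Aligned per-individual trio dataset
#'
#' Holds phenotype, covariates, genotype, methylation and expression for a
#' single trio, together with the missingness partition. Phenotype,
#' covariates and genotype must be fully observed (the design assumption of
#' the missing-data likelihood); methylation and/or expression may be `NA`,
#' which places the individual in one of four disjoint strata:
#' complete, expression-missing, methylation-missing, or both-missing.
#'
#' @param y Phenotype vector coded -1/+1; 0/1 coding is accepted and recoded
#'   (0 -> -1).
#' @param X Covariate matrix (n x J) or `NULL` for no covariates.
#' @param G Genotype vector with values in \{0, 1, 2\} (minor-allele count);
#'   no missing values allowed.
#' @param M Methylation vector; `NA` marks missing.
#' @param E Expression vector; `NA` marks missing.
#'
#' @return An object of class `"trio_data"`: a list with elements `y`, `X`,
#'   `G`, `M`, `E`, `scheme` (per-row code 0 = complete, 1 = expression
#'   missing, 2 = methylation missing, 3 = both missing) and `n` (named
#'   vector of the four stratum sizes `n1`..`n4`).
#' @examples
#' d <- trio_data(y = c(1, 0, 1, 0), G = c(0, 1, 2, 1),
#'                M = c(0.2, NA, 0.5, 0.1), E = c(1.1, 2.0, NA, 0.3))
#' d$n
#' @export
trio_data <- function(y, X = NULL, G, M, E) {
  y <- as.numeric(y)
  if (all(y %in% c(0, 1))) y <- ifelse(y == 0, -1, 1)
  if (anyNA(y) || !all(y %in% c(-1, 1)))
    stop("phenotype must be coded -1/+1 (or 0/1); offending rows: ",
         paste(which(is.na(y) | !(y %in% c(-1, 1))), collapse = ", "))
  n <- length(y)
  if (is.null(X)) X <- matrix(numeric(0), nrow = n, ncol = 0)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) != n) stop("X must have one row per individual")
  if (anyNA(X)) stop("covariates must be fully observed")
  G <- as.numeric(G)
  if (length(G) != n || anyNA(G) || !all(G %in% c(0, 1, 2)))
    stop("genotype must be fully observed with values in {0,1,2}; ",
         "offending rows: ",
         paste(which(is.na(G) | !(G %in% c(0, 1, 2))), collapse = ", "))
  M <- as.numeric(M); E <- as.numeric(E)
  if (length(M) != n || length(E) != n)
    stop("M and E must have one entry per individual")
  scheme <- ifelse(is.na(M) & is.na(E), 3L,
                   ifelse(is.na(M), 2L, ifelse(is.na(E), 1L, 0L)))
  structure(list(y = y, X = X, G = G, M = M, E = E,
                 scheme = scheme,
                 n = c(n1 = sum(scheme == 0L), n2 = sum(scheme == 1L),
                       n3 = sum(scheme == 2L), n4 = sum(scheme == 3L))),
            class = "trio_data")
}

#' @export
print.trio_data <- function(x, ...) {
  n <- length(x$y)
  cat("Trio dataset:", n, "individuals (",
      sum(x$y == 1), "cases /", sum(x$y == -1), "controls ),",
      ncol(x$X), "covariate(s)\n")
  cat("  complete:", x$n[["n1"]],
      " | expression missing:", x$n[["n2"]],
      " | methylation missing:", x$n[["n3"]],
      " | both missing:", x$n[["n4"]], "\n")
  invisible(x)
}

#' Subset a trio dataset by row
#'
#' @param data A [trio_data()] object.
#' @param idx Row indices (or logical vector).
#' @return A new `trio_data` with the selected rows.
#' @export
trio_data_subset <- function(data, idx) {
  trio_data(y = data$y[idx], X = data$X[idx, , drop = FALSE],
            G = data$G[idx], M = data$M[idx], E = data$E[idx])
}

as_data_frame_trio <- function(data) {
  df <- data.frame(y = ifelse(data$y == 1, 1L, 0L))
  if (ncol(data$X) > 0) {
    cn <- colnames(data$X)
    if (is.null(cn)) cn <- paste0("x", seq_len(ncol(data$X)))
    for (j in seq_len(ncol(data$X))) df[[cn[j]]] <- data$X[, j]
  }
  df$G <- data$G; df$M <- data$M; df$E <- data$E
  df
}

#' Read a trio dataset from a delimited text file
#'
#' Expects a header with a phenotype column, a genotype column, methylation
#' and expression columns, and optionally covariate columns. Phenotype may
#' be coded 0/1, -1/+1, or as the strings `"control"`/`"case"`.
#'
#' @param path File path.
#' @param sep Field separator (default tab).
#' @param na Missing-value token (default `"NA"`).
#' @param y_col,g_col,m_col,e_col Column names of phenotype, genotype,
#'   methylation and expression.
#' @param x_cols Character vector of covariate column names (default: every
#'   other column except an `id` column).
#' @return A [trio_data()] object.
#' @export
read_trio_data <- function(path, sep = "\t", na = "NA",
                           y_col = "y", g_col = "G", m_col = "M",
                           e_col = "E", x_cols = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = na, stringsAsFactors = FALSE)
  need <- c(y_col, g_col, m_col, e_col)
  if (!all(need %in% names(df)))
    stop("missing required column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (is.null(x_cols))
    x_cols <- setdiff(names(df), c(need, "id"))
  y <- df[[y_col]]
  if (is.character(y)) {
    if (!all(y %in% c("case", "control")))
      stop("character phenotype must use 'case'/'control' labels")
    y <- ifelse(y == "case", 1, -1)
  }
  if (anyNA(y)) stop("missing phenotype in row(s): ",
                     paste(which(is.na(y)), collapse = ", "))
  if (!all(y %in% c(0, 1)) && !all(y %in% c(-1, 1)))
    stop("phenotype values outside {0,1}/{-1,1} in row(s): ",
         paste(which(!(y %in% c(0, 1, -1))), collapse = ", "))
  X <- if (length(x_cols)) as.matrix(df[, x_cols, drop = FALSE]) else NULL
  d <- trio_data(y = y, X = X, G = df[[g_col]], M = df[[m_col]],
                 E = df[[e_col]])
  if (all(d$scheme == 3L))
    stop("both omics are missing for every individual: no information")
  d
}

#' Write a trio dataset to a delimited text file
#'
#' Columns: `id`, `y` (0/1), covariates, `G`, `M`, `E`; missing omics are
#' written as the `na` token. [read_trio_data()] round-trips the output.
#'
#' @param data A [trio_data()] object.
#' @param path Output file path.
#' @param sep Field separator (default tab).
#' @param na Missing-value token.
#' @return `path`, invisibly.
#' @export
write_trio_data <- function(data, path, sep = "\t", na = "NA") {
  df <- cbind(id = seq_along(data$y), as_data_frame_trio(data))
  utils::write.table(df, path, sep = sep, na = na, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
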