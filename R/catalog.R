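#' Build a gene / cis-SNP / cis-CpG trio catalog
#'
#' Forms, for each gene, the Cartesian product of its cis-SNPs and its
#' cis-CpGs. A SNP is cis to a gene when its position falls within
#' `window` base pairs of the gene body, i.e. inside the closed interval
#' `[start - window, end + window]` on the same chromosome (coordinates are
#' 1-based inclusive; strand is ignored). CpGs are taken from a
#' gene-mapped annotation table (the usual methylation-array convention);
#' alternatively, if `cpgs` has no `gene_id` column, the same positional
#' window rule is applied to CpG positions.
#'
#' @param genes Data frame with columns `gene_id`, `chrom`, `start`, `end`.
#' @param snps Data frame with columns `snp_id`, `chrom`, `pos`.
#' @param cpgs Data frame with columns `cpg_id` and either `gene_id`
#'   (mapped annotation) or `chrom`, `pos` (positional rule).
#' @param window Cis window in base pairs (default 2000), applied
#'   symmetrically upstream and downstream.
#' @return An object of class `"trio_catalog"`: a data frame with columns
#'   `gene_id`, `snp_id`, `cpg_id`, ordered by gene, SNP position, CpG;
#'   the window and input sizes are kept in attribute `"provenance"`.
#' @examples
#' genes <- data.frame(gene_id = "g1", chrom = "1", start = 1000, end = 2000)
#' snps <- data.frame(snp_id = c("s1", "s2"), chrom = "1", pos = c(500, 9000))
#' cpgs <- data.frame(cpg_id = "c1", gene_id = "g1")
#' build_trio_catalog(genes, snps, cpgs)  # s1 is cis, s2 is not
#' @export
build_trio_catalog <- function(genes, snps, cpgs, window = 2000) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)),
            all(c("snp_id", "chrom", "pos") %in% names(snps)),
            "cpg_id" %in% names(cpgs))
  mapped <- "gene_id" %in% names(cpgs)
  if (!mapped && !all(c("chrom", "pos") %in% names(cpgs)))
    stop("cpgs must have either a gene_id column or chrom/pos columns")
  rows <- lapply(order(genes$gene_id), function(gi) {
    g <- genes[gi, ]
    cis_snp <- snps[snps$chrom == g$chrom &
                      snps$pos >= g$start - window &
                      snps$pos <= g$end + window, , drop = FALSE]
    cis_cpg <- if (mapped) cpgs[cpgs$gene_id == g$gene_id, , drop = FALSE]
    else cpgs[cpgs$chrom == g$chrom &
                cpgs$pos >= g$start - window &
                cpgs$pos <= g$end + window, , drop = FALSE]
    if (nrow(cis_snp) == 0L || nrow(cis_cpg) == 0L) return(NULL)
    cis_snp <- cis_snp[order(cis_snp$pos, cis_snp$snp_id), ]
    cis_cpg <- cis_cpg[order(if (mapped) cis_cpg$cpg_id else cis_cpg$pos), ]
    expand.grid(gene_id = g$gene_id, snp_id = cis_snp$snp_id,
                cpg_id = cis_cpg$cpg_id, KEEP.OUT.ATTRS = FALSE,
                stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(gene_id = character(0), snp_id = character(0),
                      cpg_id = character(0))
  structure(out, class = c("trio_catalog", "data.frame"),
            provenance = list(window = window, n_genes = nrow(genes),
                              n_snps = nrow(snps), n_cpgs = nrow(cpgs)))
}

#' Filter genes by expression missingness
#'
#' Keeps genes whose expression is fully observed in controls and missing
#' in at most `max_case_missing` of the cases (boundary included).
#'
#' @param expr Numeric matrix of expression values, genes in rows,
#'   individuals in columns; `NA` marks missing.
#' @param is_case Logical vector over columns marking case individuals.
#' @param max_case_missing Maximum tolerated fraction of missing case
#'   values.
#' @return Character vector (or row indices when `expr` has no rownames)
#'   of retained genes.
#' @export
filter_expression_missingness <- function(expr, is_case,
                                          max_case_missing = 0.5) {
  stopifnot(ncol(expr) == length(is_case))
  ctrl_ok <- rowSums(is.na(expr[, !is_case, drop = FALSE])) == 0
  case_frac <- rowMeans(is.na(expr[, is_case, drop = FALSE]))
  keep <- ctrl_ok & case_frac <= max_case_missing
  if (!is.null(rownames(expr))) rownames(expr)[keep] else which(keep)
}
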