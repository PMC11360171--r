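#' Kruskal-Wallis differential-expression test for one gene
#'
#' Rank-based comparison of a gene's z-scores between active and inactive
#' chemicals (tie-corrected H, chi-square p with 1 df for two groups), chosen
#' because z-score signatures are not normally distributed. The direction
#' annotation compares group medians: `up_in_active`, `down_in_active`, or
#' `none` when the medians coincide. When every value is identical across
#' both groups the test is degenerate and `H = 0`, `p = 1`.
#'
#' @param values_active,values_inactive numeric z-scores per group (both
#'   non-empty).
#' @param gene_id optional id carried into the record.
#' @return data.frame row: `gene_id`, `H`, `p_value`, `direction`.
#' @export
kruskal_wallis_gene <- function(values_active, values_inactive,
                                gene_id = NA_character_) {
  if (!length(values_active) || !length(values_inactive))
    stop("both groups must be non-empty", call. = FALSE)
  vals <- c(values_active, values_inactive)
  if (length(unique(vals)) == 1L) {
    H <- 0; p <- 1
  } else {
    g <- rep(1:2, c(length(values_active), length(values_inactive)))
    kt <- kruskal.test(vals, g)
    H <- unname(kt$statistic); p <- kt$p.value
  }
  dm <- median(values_active) - median(values_inactive)
  data.frame(gene_id = gene_id, H = H, p_value = p,
             direction = if (dm > 0) "up_in_active"
                         else if (dm < 0) "down_in_active" else "none")
}

#' Per-gene Kruskal-Wallis importance over a signature matrix
#'
#' @param x numeric matrix (chemicals x genes) or a [signature_matrix()].
#' @param labels binary activity labels aligned with rows.
#' @return data.frame with one row per gene: `gene_id`, `H`, `p_value`,
#'   `direction`, in catalog order.
#' @export
kruskal_wallis_genes <- function(x, labels) {
  if (inherits(x, "signature_matrix")) x <- x$values
  y <- as_binary_labels(labels)
  if (!any(y == 1L) || !any(y == 0L))
    stop("both classes must be present", call. = FALSE)
  ids <- colnames(x)
  if (is.null(ids)) ids <- sprintf("f%03d", seq_len(ncol(x)))
  out <- lapply(seq_len(ncol(x)), function(j)
    kruskal_wallis_gene(x[y == 1L, j], x[y == 0L, j], ids[j]))
  do.call(rbind, out)
}

#' Count significant genes at a raw p-value cutoff
#'
#' Counts genes with `p < alpha`, strictly. No multiple-testing correction is
#' applied: the count is a descriptive tally of raw per-gene tests, so under
#' the null about `alpha` of all genes are expected to pass by chance.
#'
#' @param records data.frame from [kruskal_wallis_genes()].
#' @param alpha cutoff (default 0.05).
#' @return integer count.
#' @export
count_significant <- function(records, alpha = 0.05) {
  sum(records$p_value < alpha)
}

#' Top-k differentially expressed genes
#'
#' @param records data.frame from [kruskal_wallis_genes()].
#' @param k number of genes (default 10); if `k` exceeds the record count all
#'   records are returned.
#' @return the `k` records with the lowest p-values, ties broken by
#'   ascending gene id.
#' @export
top_k_genes <- function(records, k = 10L) {
  ord <- order(records$p_value, records$gene_id)
  records[head(ord, k), , drop = FALSE]
}

#' Fraction of selected genes that are significantly differential
#'
#' How much of a feature selection is backed by univariate
#' differential-expression evidence:
#' `|selected intersect significant| / |selected|`.
#'
#' @param selected_genes character vector of selected gene ids (non-empty).
#' @param significant_genes character vector of significant gene ids.
#' @return fraction in \[0, 1\].
#' @export
selection_capture_rate <- function(selected_genes, significant_genes) {
  if (!length(selected_genes))
    stop("capture rate undefined for an empty selection", call. = FALSE)
  length(intersect(selected_genes, significant_genes)) /
    length(unique(selected_genes))
}
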