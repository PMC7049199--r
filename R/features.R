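#' Collapse an adjusted SNV matrix into gene-level counts
#'
#' The gene-level value for sample s and gene g is the literal sum of the
#' adjusted (signed, possibly negative) values of all variants mapped to g.
#' Set `absolute = TRUE` to sum absolute values instead. Genes whose column is
#' all zero are retained and flagged in the `all_zero_genes` field. Gene order
#' is lexicographic. Variants without a gene mapping are dropped with a
#' warning; a variant mapped to several genes (comma/semicolon separated) is
#' an error unless `multi_gene = "first"`.
#'
#' @param A an `adjusted_matrix`
#' @param variant_to_gene named character vector (defaults to the map carried
#'   by `A`)
#' @param absolute sum absolute values instead of signed values
#' @param multi_gene `"error"` (default) or `"first"`
#' @return list of class `gene_count_matrix` with `sample_ids`, `gene_ids`,
#'   `values`, `adjusted_phenotype`, `labels`, `all_zero_genes`
#' @export
gene_counts <- function(A, variant_to_gene = A$variant_to_gene,
                        absolute = FALSE,
                        multi_gene = c("error", "first")) {
  multi_gene <- match.arg(multi_gene)
  genes <- variant_to_gene[A$feature_ids]
  unmapped <- is.na(genes) | genes == ""
  if (any(unmapped)) {
    warning(sum(unmapped), " variant(s) without gene mapping dropped")
  }
  multi <- grepl("[,;]", genes)
  if (any(multi & !unmapped)) {
    if (multi_gene == "error")
      stop("variant mapped to multiple genes: ",
           A$feature_ids[which(multi)[1]],
           " (set multi_gene = \"first\" to keep the first mapping)")
    genes[multi] <- sub("[,;].*$", "", genes[multi])
  }
  keep <- !unmapped
  V <- A$values[, keep, drop = FALSE]
  if (absolute) V <- abs(V)
  g <- factor(genes[keep], levels = sort(unique(genes[keep])))
  sums <- t(rowsum(t(V), g))
  storage.mode(sums) <- "integer"
  rownames(sums) <- A$sample_ids
  structure(list(sample_ids = A$sample_ids,
                 gene_ids = colnames(sums),
                 values = sums,
                 adjusted_phenotype = A$adjusted_phenotype,
                 labels = A$labels,
                 all_zero_genes = colnames(sums)[colSums(sums != 0L) == 0L]),
            class = "gene_count_matrix")
}
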