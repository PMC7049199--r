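#' Variant selection thresholds
#'
#' Defaults are the published selection rules: the six qualifying coding
#' variant types, the three qualifying functional types, annotated MAF <=
#' 0.01, and per-individual read support of at least 4 alternate reads, depth
#' 10 and genotype quality 90. Every threshold is inclusive.
#'
#' @param allowed_coding_types character set of qualifying coding types
#' @param allowed_functional_types character set of qualifying functional types
#' @param max_maf inclusive MAF ceiling
#' @param min_alt_reads,min_depth,min_gq inclusive per-call floors
#' @return list of class `filter_thresholds`
#' @export
filter_thresholds <- function(allowed_coding_types = c("frameshift_deletion",
                                                       "frameshift_insertion",
                                                       "frameshift_substitution",
                                                       "nonsynonymous_SNV",
                                                       "stopgain", "stoploss"),
                              allowed_functional_types = c("exonic",
                                                           "exonic_splicing",
                                                           "intronic_splicing"),
                              max_maf = 0.01,
                              min_alt_reads = 4L,
                              min_depth = 10L,
                              min_gq = 90L) {
  structure(list(allowed_coding_types = allowed_coding_types,
                 allowed_functional_types = allowed_functional_types,
                 max_maf = max_maf,
                 min_alt_reads = as.integer(min_alt_reads),
                 min_depth = as.integer(min_depth),
                 min_gq = as.integer(min_gq)),
            class = "filter_thresholds")
}

#' Apply the variant selection rules to an annotated call table
#'
#' Retains exactly the calls whose coding and functional types are in the
#' allowed sets, whose annotated MAF is at or below the ceiling, and whose
#' per-individual read support meets every floor. Each criterion's rejection
#' count (calls failing that criterion, counted independently, so a call
#' failing two criteria appears in both tallies) is logged and attached as the
#' `rejection_counts` attribute.
#'
#' @param calls annotated call table (data.frame/data.table)
#' @param thresholds a [filter_thresholds()] object
#' @param verbose log per-criterion rejection counts (default TRUE)
#' @return the retained calls, with attribute `rejection_counts`
#' @export
filter_calls <- function(calls, thresholds = filter_thresholds(),
                         verbose = TRUE) {
  calls <- data.table::as.data.table(calls)
  stopifnot(inherits(thresholds, "filter_thresholds"))
  req <- c("sample_id", "variant_id", "gene", "coding_type", "functional_type",
           "maf", "genotype", "alt_reads", "depth", "gq")
  missing_cols <- setdiff(req, names(calls))
  if (length(missing_cols))
    stop("call table lacks columns: ", paste(missing_cols, collapse = ", "))

  bad_ct <- !(calls$coding_type %in% coding_type_levels())
  if (any(bad_ct))
    stop(sprintf("unknown coding_type '%s' in record (sample %s, variant %s)",
                 calls$coding_type[which(bad_ct)[1]],
                 calls$sample_id[which(bad_ct)[1]],
                 calls$variant_id[which(bad_ct)[1]]))
  bad_ft <- !(calls$functional_type %in% functional_type_levels())
  if (any(bad_ft))
    stop(sprintf("unknown functional_type '%s' in record (sample %s, variant %s)",
                 calls$functional_type[which(bad_ft)[1]],
                 calls$sample_id[which(bad_ft)[1]],
                 calls$variant_id[which(bad_ft)[1]]))
  if (any(calls$alt_reads > calls$depth))
    stop("malformed call: alt_reads exceeds depth")

  fail <- list(
    coding = !(calls$coding_type %in% thresholds$allowed_coding_types),
    functional = !(calls$functional_type %in% thresholds$allowed_functional_types),
    maf = calls$maf > thresholds$max_maf,
    alt_reads = calls$alt_reads < thresholds$min_alt_reads,
    depth = calls$depth < thresholds$min_depth,
    gq = calls$gq < thresholds$min_gq)
  rejection_counts <- vapply(fail, sum, integer(1))
  keep <- !Reduce(`|`, fail)
  if (verbose) {
    for (crit in names(rejection_counts))
      msg("filter: %d call(s) fail %s criterion", rejection_counts[[crit]], crit)
    msg("filter: retained %d of %d calls", sum(keep), nrow(calls))
  }
  out <- calls[keep]
  data.table::setattr(out, "rejection_counts", rejection_counts)
  out
}

#' Assemble the wide 0/1/2 genotype matrix from filtered calls
#'
#' One row per sample in `all_samples` (samples with no retained call keep an
#' all-zero row), one column per variant retained in at least one sample.
#' Cells default to 0 (wildtype); missing genotypes (NA) are treated as 0 and
#' logged. Row and column orders are lexicographic, hence deterministic.
#'
#' @param calls filtered annotated call table
#' @param all_samples the full sample universe (character)
#' @param labels named character vector mapping sample_id to class label
#' @return list of class `genotype_matrix` with `sample_ids`, `variant_ids`,
#'   `values` (integer matrix), `labels`, `variant_to_gene`, `rsid`
#' @export
build_genotype_matrix <- function(calls, all_samples, labels) {
  calls <- data.table::as.data.table(calls)
  if (!all(calls$sample_id %in% all_samples))
    stop("call table contains samples outside the sample universe")
  if (!all(all_samples %in% names(labels)))
    stop("every sample needs a class label")
  dup <- calls[, .N, by = list(sample_id, variant_id)][N > 1L]
  if (nrow(dup)) {
    conf <- merge(calls, dup[, list(sample_id, variant_id)],
                  by = c("sample_id", "variant_id"))
    ng <- conf[, data.table::uniqueN(genotype), by = list(sample_id, variant_id)]
    if (any(ng$V1 > 1L))
      stop("conflicting duplicate genotype for sample ",
           ng$sample_id[ng$V1 > 1L][1], " at ", ng$variant_id[ng$V1 > 1L][1])
    calls <- unique(calls, by = c("sample_id", "variant_id"))
  }
  n_missing <- sum(is.na(calls$genotype))
  if (n_missing) {
    msg("matrix: %d missing genotype(s) treated as 0", n_missing)
    calls <- calls[!is.na(genotype)]
  }
  sample_ids <- sort(all_samples)
  variant_ids <- sort(unique(calls$variant_id))
  values <- matrix(0L, length(sample_ids), length(variant_ids),
                   dimnames = list(sample_ids, variant_ids))
  values[cbind(match(calls$sample_id, sample_ids),
               match(calls$variant_id, variant_ids))] <- as.integer(calls$genotype)
  v2g <- calls[!duplicated(variant_id), list(variant_id, gene)]
  variant_to_gene <- stats::setNames(v2g$gene, v2g$variant_id)[variant_ids]
  rsid <- NULL
  if ("rsid" %in% names(calls)) {
    r <- calls[!duplicated(variant_id), list(variant_id, rsid)]
    rsid <- stats::setNames(r$rsid, r$variant_id)[variant_ids]
  }
  structure(list(sample_ids = sample_ids,
                 variant_ids = variant_ids,
                 values = values,
                 labels = labels[sample_ids],
                 variant_to_gene = variant_to_gene,
                 rsid = rsid),
            class = "genotype_matrix")
}

#' Write a genotype (or adjusted/gene) matrix as TSV
#'
#' Samples in rows; the first column is the class label (and, when present,
#' the second column the adjusted phenotype), mirroring the tabular layout of
#' the analysis dataset. A companion variant-to-gene map can be written with
#' `write_variant_gene_map`.
#'
#' @param G a `genotype_matrix`-like object
#' @param path output path
#' @export
write_genotype_matrix <- function(G, path) {
  dt <- data.table::data.table(sample_id = G$sample_ids,
                               label = unname(G$labels))
  if (!is.null(G$adjusted_phenotype))
    dt[, adjusted_phenotype := G$adjusted_phenotype]
  out <- cbind(dt, data.table::as.data.table(G$values))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_genotype_matrix
#' @param variant_to_gene named character vector
#' @export
write_variant_gene_map <- function(variant_to_gene, path) {
  data.table::fwrite(data.table::data.table(variant_id = names(variant_to_gene),
                                            gene = unname(variant_to_gene)),
                     path, sep = "\t")
  invisible(path)
}

#' Read annotated calls from a minimal VCF 4.2 file
#'
#' Ingests a multi-sample VCF with FORMAT `GT:AD:DP:GQ` and INFO fields
#' GENE/CODING/FUNC/MAF as written by [export_vcf()]. Non-reference genotypes
#' become rows of the long-format call table; `0/0` and missing genotypes are
#' skipped (hom-ref cells are implicit in the long format).
#'
#' @param path VCF path
#' @return annotated call data.table in the documented column order
#' @export
read_vcf_calls <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("VCF ingestion requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  ad <- VariantAnnotation::geno(vcf)$AD
  dp <- VariantAnnotation::geno(vcf)$DP
  gq <- VariantAnnotation::geno(vcf)$GQ
  info <- VariantAnnotation::info(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  variant_id <- sprintf("%s:%d:%s:%s",
                        as.character(GenomeInfoDb::seqnames(rr)),
                        BiocGenerics::start(rr),
                        as.character(rr$REF),
                        vapply(rr$ALT, function(a) as.character(a)[1],
                               character(1)))
  rsid <- names(rr)
  carrier <- which(matrix(gt %in% c("0/1", "1/0", "0|1", "1|0", "1/1", "1|1"),
                          nrow(gt)), arr.ind = TRUE)
  geno <- ifelse(gt[carrier] %in% c("1/1", "1|1"), 2L, 1L)
  vi <- carrier[, 1]
  si <- carrier[, 2]
  alt_reads <- vapply(seq_len(nrow(carrier)), function(k) {
    a <- ad[[vi[k], si[k]]]
    as.integer(a[2])
  }, integer(1))
  out <- data.table::data.table(
    sample_id = colnames(gt)[si],
    variant_id = variant_id[vi],
    rsid = rsid[vi],
    gene = info$GENE[vi],
    coding_type = info$CODING[vi],
    functional_type = info$FUNC[vi],
    maf = info$MAF[vi],
    genotype = geno,
    alt_reads = alt_reads,
    depth = as.integer(dp[carrier]),
    gq = as.integer(gq[carrier]))
  data.table::setorder(out, sample_id, variant_id)
  out[]
}
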