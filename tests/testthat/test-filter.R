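test_that("thresholds are inclusive at every boundary", {
  call <- passing_call(maf = 0.01, alt_reads = 4L, depth = 10L, gq = 90L)
  kept <- filter_calls(call, verbose = FALSE)
  expect_identical(nrow(kept), 1L)

  expect_identical(nrow(filter_calls(passing_call(coding_type = "other"),
                                     verbose = FALSE)), 0L)
  expect_identical(nrow(filter_calls(passing_call(alt_reads = 3L),
                                     verbose = FALSE)), 0L)
  expect_identical(nrow(filter_calls(passing_call(maf = 0.0101),
                                     verbose = FALSE)), 0L)
  expect_identical(nrow(filter_calls(passing_call(depth = 9L, alt_reads = 4L),
                                     verbose = FALSE)), 0L)
  expect_identical(nrow(filter_calls(passing_call(gq = 89L),
                                     verbose = FALSE)), 0L)
  expect_identical(nrow(filter_calls(passing_call(functional_type = "other"),
                                     verbose = FALSE)), 0L)
})

test_that("unknown enum values raise a parse error naming the record", {
  expect_error(filter_calls(passing_call(coding_type = "missense"),
                            verbose = FALSE),
               "unknown coding_type 'missense'.*S1")
  expect_error(filter_calls(passing_call(functional_type = "utr5"),
                            verbose = FALSE),
               "unknown functional_type 'utr5'.*S1")
})

test_that("relaxing any single threshold never shrinks the retained set", {
  sim <- small_sim(seed = 17L)
  base_thr <- filter_thresholds()
  base_ids <- with(filter_calls(sim$calls, base_thr, verbose = FALSE),
                   paste(sample_id, variant_id))
  relaxed <- list(
    filter_thresholds(max_maf = 0.5),
    filter_thresholds(min_alt_reads = 0L),
    filter_thresholds(min_depth = 0L),
    filter_thresholds(min_gq = 0L),
    filter_thresholds(allowed_coding_types =
                        c("frameshift_deletion", "frameshift_insertion",
                          "frameshift_substitution", "nonsynonymous_SNV",
                          "stopgain", "stoploss", "other")))
  for (thr in relaxed) {
    ids <- with(filter_calls(sim$calls, thr, verbose = FALSE),
                paste(sample_id, variant_id))
    expect_true(all(base_ids %in% ids))
    expect_gte(length(ids), length(base_ids))
  }
})

test_that("filtering is idempotent", {
  sim <- small_sim(seed = 17L)
  once <- filter_calls(sim$calls, verbose = FALSE)
  twice <- filter_calls(once, verbose = FALSE)
  expect_equal(as.data.frame(twice), as.data.frame(once),
               ignore_attr = TRUE)
  expect_true(all(attr(twice, "rejection_counts") == 0L))
})

test_that("genotype matrix is built correctly on toy input", {
  # 2 samples, one retained het call for sample A
  calls <- passing_call(sample_id = "A")
  labels <- c(A = "ASD", B = "SCZ")
  G <- build_genotype_matrix(calls, c("A", "B"), labels)
  expect_identical(unname(G$values), matrix(c(1L, 0L), 2, 1))
  expect_identical(G$sample_ids, c("A", "B"))   # zero-call sample kept

  # 3 samples x 4 calls with one hom-alt; column count = distinct variants
  toy <- rbind(passing_call("A", "1:1:A:T", gene = "G1"),
               passing_call("A", "1:2:C:G", gene = "G1", genotype = 2L),
               passing_call("B", "1:2:C:G", gene = "G1"),
               passing_call("C", "1:3:G:A", gene = "G2"))
  G2 <- build_genotype_matrix(toy, c("A", "B", "C"),
                              c(A = "ASD", B = "ASD", C = "SCZ"))
  expect_identical(dim(G2$values), c(3L, 3L))
  expect_identical(G2$values["A", "1:2:C:G"], 2L)
  expect_identical(G2$values["B", "1:2:C:G"], 1L)
  expect_identical(G2$values["C", "1:2:C:G"], 0L)
  expect_identical(unname(G2$variant_to_gene[G2$variant_ids]),
                   c("G1", "G1", "G2"))
})

test_that("matrix construction rejects conflicts and foreign samples", {
  dup <- rbind(passing_call("A", "1:1:A:T", genotype = 1L),
               passing_call("A", "1:1:A:T", genotype = 2L))
  expect_error(build_genotype_matrix(dup, "A", c(A = "ASD")), "conflicting")
  expect_error(build_genotype_matrix(passing_call("Z"), "A", c(A = "ASD")),
               "outside the sample universe")
})

test_that("row and column order are deterministic regardless of input order", {
  sim <- small_sim(seed = 30L)
  kept <- filter_calls(sim$calls, verbose = FALSE)
  shuffled <- kept[sample(nrow(kept)), ]
  g1 <- build_genotype_matrix(kept, names(sim$truth$class_labels),
                              sim$truth$class_labels)
  g2 <- build_genotype_matrix(shuffled, names(sim$truth$class_labels),
                              sim$truth$class_labels)
  expect_identical(g1$values, g2$values)
})

test_that("VCF export/ingest round-trips and matches the TSV path", {
  sim <- simulate_cohorts(sim_config(n_cases_per_class = 40L,
                                     n_genes_total = 60L,
                                     n_discriminative_genes_per_class = 6L,
                                     n_hub_genes_per_class = 3L,
                                     seed = 12L))
  all_samples <- names(sim$truth$class_labels)
  vcf_path <- withr::local_tempfile(fileext = ".vcf")
  export_vcf(sim$calls, vcf_path, sample_ids = all_samples)
  back <- read_vcf_calls(vcf_path)

  via_tsv <- filter_calls(sim$calls, verbose = FALSE)
  via_vcf <- filter_calls(back, verbose = FALSE)
  g_tsv <- build_genotype_matrix(via_tsv, all_samples, sim$truth$class_labels)
  g_vcf <- build_genotype_matrix(via_vcf, all_samples, sim$truth$class_labels)
  expect_identical(g_vcf$values, g_tsv$values)
  expect_identical(g_vcf$variant_to_gene, g_tsv$variant_to_gene)
})
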