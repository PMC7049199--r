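#' Configuration for the synthetic two-cohort exome simulator
#'
#' Builds and validates the full set of generator knobs. Defaults describe the
#' scenario the rest of the package is exercised against: two cohorts of 600
#' cases (ASD vs. SCZ), 2000 genes of which 40 per class are discriminative and
#' the first 12 of those form a co-mutation "hub" module targeted to cover 90%
#' of that class's cases, rare annotated MAFs (<= 0.01) for signal variants,
#' two confounded ancestry axes shifting allele frequencies of a structure
#' variant subset, and a 4% planted failure rate per filter criterion.
#'
#' @param n_cases_per_class cases per diagnostic class
#' @param n_genes_total total genes simulated
#' @param n_discriminative_genes_per_class class-enriched genes per class
#' @param n_hub_genes_per_class leading discriminative genes forming the
#'   planted co-mutation module (must not exceed the discriminative count)
#' @param hub_coverage_target fraction in (0,1] of a class's cases that must
#'   carry at least one filter-surviving hub-gene variant
#' @param n_noise_genes background genes; defaults to the remainder
#' @param variants_per_gene inclusive integer range (lo, hi)
#' @param maf_range annotated reference-MAF range for signal variants; the
#'   upper bound may not exceed 0.01 so signal survives the MAF filter
#' @param ancestry_axes number of planted ancestry axes
#' @param ancestry_effect per-axis allele-frequency shift magnitude applied to
#'   structure variants (0 disables structure entirely)
#' @param read_depth_model list with `mean` and `dispersion` for the negative
#'   binomial sequencing depth of emitted calls
#' @param gq_model list with `lambda`: genotype qualities of passing calls are
#'   `99 - min(9, Pois(lambda))`, i.e. in 90..99
#' @param fail_fractions named fractions (coding, maf, alt_reads, depth, gq)
#'   of deliberately filter-failing calls planted per criterion, each call
#'   violating exactly one criterion
#' @param disc_carrier_freq per-variant allele-frequency range in the enriched
#'   class for discriminative (non-hub) variants
#' @param hub_genes_per_case list with `size` and `prob`: a covered case
#'   carries `1 + Binomial(size, prob)` distinct hub genes
#' @param structure_fraction fraction of noise-gene variants designated as
#'   ancestry-structure variants
#' @param structure_base_freq cohort base allele-frequency range of structure
#'   variants (their *annotated* MAF stays rare: frequent in an
#'   under-represented ancestry, rare in the reference panel)
#' @param class_sep per-axis separation of class means on the ancestry score,
#'   recycled over axes; this is what confounds class with ancestry
#' @param seed integer seed; identical configs produce byte-identical tables
#' @return a validated list of class `sim_config`
#' @export
sim_config <- function(n_cases_per_class = 600L,
                       n_genes_total = 2000L,
                       n_discriminative_genes_per_class = 40L,
                       n_hub_genes_per_class = 12L,
                       hub_coverage_target = 0.9,
                       n_noise_genes = NULL,
                       variants_per_gene = c(2L, 4L),
                       maf_range = c(5e-4, 0.01),
                       ancestry_axes = 2L,
                       ancestry_effect = 0.15,
                       read_depth_model = list(mean = 60, dispersion = 8),
                       gq_model = list(lambda = 1),
                       fail_fractions = c(coding = 0.04, maf = 0.04,
                                          alt_reads = 0.04, depth = 0.04,
                                          gq = 0.04),
                       disc_carrier_freq = c(0.01, 0.025),
                       hub_genes_per_case = list(size = 2, prob = 0.5),
                       structure_fraction = 0.08,
                       structure_base_freq = c(0.05, 0.30),
                       class_sep = c(0.5, 0.25),
                       seed = 1L) {
  if (is.null(n_noise_genes))
    n_noise_genes <- n_genes_total - 2L * n_discriminative_genes_per_class
  cfg <- list(n_cases_per_class = as.integer(n_cases_per_class),
              n_genes_total = as.integer(n_genes_total),
              n_discriminative_genes_per_class =
                as.integer(n_discriminative_genes_per_class),
              n_hub_genes_per_class = as.integer(n_hub_genes_per_class),
              hub_coverage_target = hub_coverage_target,
              n_noise_genes = as.integer(n_noise_genes),
              variants_per_gene = as.integer(variants_per_gene),
              maf_range = maf_range,
              ancestry_axes = as.integer(ancestry_axes),
              ancestry_effect = ancestry_effect,
              read_depth_model = read_depth_model,
              gq_model = gq_model,
              fail_fractions = fail_fractions,
              disc_carrier_freq = disc_carrier_freq,
              hub_genes_per_case = hub_genes_per_case,
              structure_fraction = structure_fraction,
              structure_base_freq = structure_base_freq,
              class_sep = class_sep,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_cases_per_class < 2L || n_genes_total < 1L ||
        n_discriminative_genes_per_class < 1L || n_hub_genes_per_class < 1L)
      stop("all counts must be positive (and >= 2 cases per class)")
    if (n_hub_genes_per_class > n_discriminative_genes_per_class)
      stop("configuration error: hub genes per class exceed discriminative genes")
    if (2L * n_discriminative_genes_per_class > n_genes_total)
      stop("configuration error: discriminative genes exceed total genes")
    if (n_noise_genes != n_genes_total - 2L * n_discriminative_genes_per_class)
      stop("configuration error: n_noise_genes inconsistent with totals")
    if (!(hub_coverage_target > 0 && hub_coverage_target <= 1))
      stop("configuration error: hub_coverage_target must lie in (0, 1]")
    if (length(variants_per_gene) != 2L || variants_per_gene[1] < 1L ||
        variants_per_gene[2] < variants_per_gene[1])
      stop("configuration error: bad variants_per_gene range")
    if (maf_range[2] > 0.01)
      stop("configuration error: signal maf_range must stay within MAF <= 0.01")
    if (ancestry_axes < 1L) stop("configuration error: ancestry_axes >= 1")
    if (any(fail_fractions < 0) || any(fail_fractions >= 1))
      stop("configuration error: fail_fractions must lie in [0, 1)")
    invisible(TRUE)
  })
}

coding_type_levels <- function() {
  c("frameshift_deletion", "frameshift_insertion", "frameshift_substitution",
    "nonsynonymous_SNV", "stopgain", "stoploss", "other")
}
functional_type_levels <- function() {
  c("exonic", "exonic_splicing", "intronic_splicing", "other")
}

#' Simulate two labeled exome cohorts as a long-format annotated call table
#'
#' Emits one row per non-reference genotype call (hom-ref cells are implicit)
#' with annotation, genotype and read-support fields, plus a truth record
#' describing everything that was planted: discriminative genes, hub modules
#' and their covered cases, ancestry scores, structure variants and the exact
#' per-criterion counts of deliberately filter-failing calls.
#'
#' Genotypes are drawn per variant as Binomial(2, f), with f shifted by class
#' for discriminative variants and by ancestry score for structure variants.
#' Hub-module carriers are planted directly so the module's case coverage hits
#' the configured target exactly: each covered case receives 1 + Binomial
#' hub genes with a guaranteed filter-passing heterozygous call. The annotated
#' MAF is a reference-panel annotation and is never recomputed from the
#' cohort, so structure variants can be common in the cohort yet survive the
#' rare-variant filter, exactly the confound the adjustment stage must remove.
#'
#' @param config a [sim_config()] object
#' @return list with elements `calls` (data.table with columns sample_id,
#'   variant_id, rsid, gene, coding_type, functional_type, maf, genotype,
#'   alt_reads, depth, gq) and `truth` (see details)
#' @export
simulate_cohorts <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)

  npc <- config$n_cases_per_class
  n <- 2L * npc
  classes <- c("ASD", "SCZ")
  sample_ids <- sprintf("S%05d", seq_len(n))
  labels <- rep(classes, each = npc)
  names(labels) <- sample_ids

  ## ancestry scores, confounded with class through shifted means
  sep <- rep_len(config$class_sep, config$ancestry_axes)
  scores <- vapply(seq_len(config$ancestry_axes), function(a) {
    mu <- ifelse(labels == "ASD", +sep[a] / 2, -sep[a] / 2)
    rnorm(n, mean = mu, sd = 1)
  }, numeric(n))
  dimnames(scores) <- list(sample_ids,
                           paste0("axis", seq_len(config$ancestry_axes)))

  ## gene roles
  ndisc <- config$n_discriminative_genes_per_class
  nhub <- config$n_hub_genes_per_class
  gene_ids <- sprintf("GENE%04d", seq_len(config$n_genes_total))
  disc <- list(ASD = gene_ids[seq_len(ndisc)],
               SCZ = gene_ids[ndisc + seq_len(ndisc)])
  hub <- list(ASD = disc$ASD[seq_len(nhub)], SCZ = disc$SCZ[seq_len(nhub)])
  noise_genes <- gene_ids[(2L * ndisc + 1L):config$n_genes_total]

  ## variant catalogue
  vpg <- config$variants_per_gene
  k_per_gene <- sample(vpg[1]:vpg[2], config$n_genes_total, replace = TRUE)
  vgene <- rep(gene_ids, k_per_gene)
  nv <- length(vgene)
  vmeta <- data.table::data.table(
    gene = vgene,
    chrom = sample(1:22, nv, replace = TRUE),
    pos = sample(1e6:5e7, nv, replace = TRUE),
    ref = sample(c("A", "C", "G", "T"), nv, replace = TRUE),
    rsid = sprintf("rs%08d", sample.int(9.9e7, nv)),
    maf = 10^runif(nv, log10(config$maf_range[1]), log10(config$maf_range[2])),
    coding_type = sample(coding_type_levels()[1:6], nv, replace = TRUE,
                         prob = c(0.08, 0.07, 0.02, 0.70, 0.10, 0.03)),
    functional_type = sample(functional_type_levels()[1:3], nv, replace = TRUE,
                             prob = c(0.90, 0.06, 0.04)))
  vmeta[, alt := vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))]
  vmeta[, variant_id := sprintf("%d:%d:%s:%s", chrom, pos, ref, alt)]
  ## guard against (vanishingly unlikely) id collisions
  dup <- duplicated(vmeta$variant_id)
  if (any(dup)) {
    vmeta[dup, pos := pos + sample.int(1000, sum(dup))]
    vmeta[, variant_id := sprintf("%d:%d:%s:%s", chrom, pos, ref, alt)]
  }

  role <- rep("noise", nv)
  role[vmeta$gene %in% disc$ASD] <- "disc_ASD"
  role[vmeta$gene %in% disc$SCZ] <- "disc_SCZ"
  role[vmeta$gene %in% hub$ASD] <- "hub_ASD"
  role[vmeta$gene %in% hub$SCZ] <- "hub_SCZ"
  vmeta[, role := role]

  ## designate structure variants among noise-gene variants
  noise_idx <- which(vmeta$role == "noise")
  n_struct <- floor(config$structure_fraction * length(noise_idx))
  struct_idx <- sort(sample(noise_idx, n_struct))
  vmeta[, structure := FALSE]
  vmeta[struct_idx, structure := TRUE]
  struct_axis <- rep_len(seq_len(config$ancestry_axes), n_struct)
  struct_dir <- sample(c(-1, 1), n_struct, replace = TRUE)
  struct_f0 <- runif(n_struct, config$structure_base_freq[1],
                     config$structure_base_freq[2])

  is_asd <- labels == "ASD"
  own_freq <- runif(nv, config$disc_carrier_freq[1], config$disc_carrier_freq[2])

  ## per-variant genotype draws (binomial model); hub variants get background
  ## only in the *other* class -- own-class hub carriers are planted below
  geno_rows <- vector("list", nv)
  struct_no <- 0L
  for (j in seq_len(nv)) {
    p <- rep(vmeta$maf[j], n)
    rj <- vmeta$role[j]
    if (rj == "disc_ASD") p[is_asd] <- own_freq[j]
    if (rj == "disc_SCZ") p[!is_asd] <- own_freq[j]
    if (rj == "hub_ASD") p[is_asd] <- 0
    if (rj == "hub_SCZ") p[!is_asd] <- 0
    if (vmeta$structure[j]) {
      struct_no <- struct_no + 1L
      p <- struct_f0[struct_no] + config$ancestry_effect *
        struct_dir[struct_no] * scores[, struct_axis[struct_no]]
      p <- pmin(pmax(p, 0.001), 0.99)
    }
    g <- rbinom(n, 2L, p)
    nz <- which(g > 0L)
    if (length(nz))
      geno_rows[[j]] <- data.table::data.table(si = nz, vi = j,
                                               genotype = g[nz])
  }
  calls <- data.table::rbindlist(geno_rows)

  ## plant hub-module carriers: per covered case, 1 + Binomial(size, prob)
  ## distinct hub genes, one het call each, in partially overlapping subsets
  hub_covered <- list()
  hpc <- config$hub_genes_per_case
  for (cl in classes) {
    class_rows <- which(labels == cl)
    ncov <- round(config$hub_coverage_target * npc)
    if (ncov < 1L)
      stop("configuration error: hub_coverage_target unreachable")
    covered <- sort(sample(class_rows, ncov))
    hub_covered[[cl]] <- sample_ids[covered]
    hub_variant_idx <- split(which(vmeta$role == paste0("hub_", cl)),
                             vmeta$gene[vmeta$role == paste0("hub_", cl)])
    ngenes_hub <- length(hub_variant_idx)
    planted <- vector("list", length(covered))
    for (i in seq_along(covered)) {
      m <- 1L + rbinom(1L, hpc$size, hpc$prob)
      m <- min(m, ngenes_hub)
      gsel <- sample(ngenes_hub, m)
      vsel <- vapply(hub_variant_idx[gsel], function(ix)
        if (length(ix) == 1L) ix else sample(ix, 1L), integer(1))
      planted[[i]] <- data.table::data.table(si = covered[i], vi = vsel,
                                             genotype = 1L)
    }
    calls <- data.table::rbindlist(c(list(calls), planted))
  }

  ## read support for all calls so far: guaranteed to pass every threshold
  add_passing_reads <- function(dt) {
    m <- nrow(dt)
    depth <- pmax(10L, rnbinom(m, size = config$read_depth_model$dispersion,
                               mu = config$read_depth_model$mean))
    alt <- integer(m)
    het <- dt$genotype == 1L
    alt[het] <- pmin(pmax(rbinom(sum(het), depth[het], 0.5), 4L), depth[het])
    alt[!het] <- pmax(depth[!het] - rbinom(sum(!het), depth[!het], 0.03), 4L)
    dt[, depth := depth]
    dt[, alt_reads := alt]
    dt[, gq := 99L - pmin(9L, rpois(m, config$gq_model$lambda))]
    dt
  }
  calls <- add_passing_reads(calls)

  ## deliberately failing calls: each violates exactly one criterion, at new
  ## noise-gene variants so truth counts are exact and signal is untouched
  n_base <- nrow(calls)
  fail_counts <- round(config$fail_fractions * n_base)
  fail_tables <- list()
  fail_pos0 <- 51000000L  # positions above the signal range, strictly increasing
  for (crit in names(fail_counts)) {
    m <- fail_counts[[crit]]
    if (m == 0L) next
    fgene <- sample(noise_genes, m, replace = TRUE)
    fchrom <- sample(1:22, m, replace = TRUE)
    fpos <- fail_pos0 + seq_len(m)
    fail_pos0 <- fail_pos0 + m
    fref <- sample(c("A", "C", "G", "T"), m, replace = TRUE)
    falt <- vapply(fref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))
    ft <- data.table::data.table(
      sample_id = sample(sample_ids, m, replace = TRUE),
      variant_id = sprintf("%d:%d:%s:%s", fchrom, fpos, fref, falt),
      rsid = sprintf("rs%08d", 1e8 - sample.int(1e6, m)),
      gene = fgene,
      coding_type = if (crit == "coding") rep("other", m) else
        sample(coding_type_levels()[1:6], m, replace = TRUE),
      functional_type = "exonic",
      maf = if (crit == "maf") runif(m, 0.02, 0.5) else
        runif(m, config$maf_range[1], config$maf_range[2]),
      genotype = 1L)
    ft <- add_passing_reads(ft)
    if (crit == "alt_reads") ft[, alt_reads := sample(0:3, m, replace = TRUE)]
    if (crit == "depth") {
      ft[, depth := sample(5:9, m, replace = TRUE)]
      ft[, alt_reads := 4L]
    }
    if (crit == "gq") ft[, gq := sample(50:89, m, replace = TRUE)]
    fail_tables[[crit]] <- ft
  }

  calls[, sample_id := sample_ids[si]]
  calls <- cbind(calls[, list(sample_id)],
                 vmeta[calls$vi,
                       list(variant_id, rsid, gene, coding_type,
                            functional_type, maf)],
                 calls[, list(genotype, alt_reads, depth, gq)])
  calls <- data.table::rbindlist(c(list(calls), unname(fail_tables)),
                                 use.names = TRUE)
  ## planted hub call may duplicate a pre-existing background call for the
  ## same (sample, variant) in rare collisions; keep the planted het
  calls <- unique(calls, by = c("sample_id", "variant_id"))
  data.table::setorder(calls, sample_id, variant_id)
  data.table::setcolorder(calls, c("sample_id", "variant_id", "rsid", "gene",
                                   "coding_type", "functional_type", "maf",
                                   "genotype", "alt_reads", "depth", "gq"))

  truth <- list(
    classes = classes,
    class_labels = labels,
    ancestry_scores = scores,
    discriminative_genes = disc,
    hub_genes = hub,
    hub_covered_cases = hub_covered,
    noise_genes = noise_genes,
    structure_variants = vmeta$variant_id[vmeta$structure],
    filter_fail_counts = as.integer(fail_counts),
    n_base_calls = n_base,
    seed = config$seed)
  names(truth$filter_fail_counts) <- names(fail_counts)

  list(calls = calls[], truth = truth)
}

#' Write / read the long-format annotated call table as TSV
#'
#' Column order is fixed and documented: sample_id, variant_id, rsid, gene,
#' coding_type, functional_type, maf, genotype, alt_reads, depth, gq.
#'
#' @param calls data.table of annotated calls
#' @param path output path
#' @export
write_calls_tsv <- function(calls, path) {
  data.table::fwrite(calls, path, sep = "\t")
  invisible(path)
}

#' @rdname write_calls_tsv
#' @export
read_calls_tsv <- function(path) {
  data.table::fread(path, sep = "\t",
                    colClasses = list(character = c("sample_id", "variant_id",
                                                    "rsid", "gene",
                                                    "coding_type",
                                                    "functional_type")))
}

#' Write the simulation truth record as JSON
#' @param truth truth record from [simulate_cohorts()]
#' @param path output path
#' @export
write_truth_json <- function(truth, path) {
  truth$ancestry_scores <- as.data.frame(truth$ancestry_scores)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Export annotated calls as a minimal multi-sample VCF 4.2
#'
#' One row per variant with INFO fields GENE/CODING/FUNC/MAF/RSID and
#' per-sample FORMAT `GT:AD:DP:GQ`. Samples without a call at a variant are
#' written as `0/0:.:.:.`. Intended for round-trip testing of
#' [read_vcf_calls()], not as a faithful variant-call representation.
#'
#' @param calls annotated call table
#' @param path output path (plain text, not bgzipped)
#' @param sample_ids optional full sample universe (defaults to samples seen)
#' @export
export_vcf <- function(calls, path, sample_ids = NULL) {
  calls <- data.table::as.data.table(calls)
  if (is.null(sample_ids)) sample_ids <- sort(unique(calls$sample_id))
  v <- unique(calls[, list(variant_id, rsid, gene, coding_type,
                           functional_type, maf)])
  parts <- data.table::tstrsplit(v$variant_id, ":", fixed = TRUE)
  v[, `:=`(chrom = parts[[1]], pos = as.integer(parts[[2]]),
           ref = parts[[3]], alt = parts[[4]])]
  data.table::setorder(v, chrom, pos, ref, alt)
  key <- paste(calls$sample_id, calls$variant_id)
  gt_of <- c("0/0", "0/1", "1/1")
  lines <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
             "##INFO=<ID=CODING,Number=1,Type=String,Description=\"Coding variant type\">",
             "##INFO=<ID=FUNC,Number=1,Type=String,Description=\"Functional type\">",
             "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Annotated reference MAF\">",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
             "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
             "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sample_ids), collapse = "\t"))
  idx <- split(seq_len(nrow(calls)), calls$variant_id)
  body <- vapply(seq_len(nrow(v)), function(i) {
    vid <- v$variant_id[i]
    cells <- rep("0/0:.:.:.", length(sample_ids))
    rows <- idx[[vid]]
    pos_in <- match(calls$sample_id[rows], sample_ids)
    cells[pos_in] <- sprintf("%s:%d,%d:%d:%d",
                             gt_of[calls$genotype[rows] + 1L],
                             calls$depth[rows] - calls$alt_reads[rows],
                             calls$alt_reads[rows], calls$depth[rows],
                             calls$gq[rows])
    paste(c(v$chrom[i], v$pos[i], v$rsid[i], v$ref[i], v$alt[i], ".", "PASS",
            sprintf("GENE=%s;CODING=%s;FUNC=%s;MAF=%.6g", v$gene[i],
                    v$coding_type[i], v$functional_type[i], v$maf[i]),
            "GT:AD:DP:GQ", cells), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}
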