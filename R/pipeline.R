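#' Pipeline run configuration
#'
#' Bundles the per-stage settings with the published defaults: MAF <= 0.01,
#' read support 4/10/90, 4 axes of variation, residual-plus-intercept
#' adjustment capped to +/-4, class balancing with a 70:30 split, five-fold
#' cross-validation, and auto-cut hub clustering. A single master seed fans
#' out to per-stage seeds via [derive_seed()].
#'
#' @param sim a [sim_config()] (the synthetic cohort to analyse)
#' @param thresholds a [filter_thresholds()]
#' @param n_axes axes of variation (default 4)
#' @param adjust_mode residual mode (default `"residual_plus_intercept"`)
#' @param train_fraction training share (default 0.7)
#' @param cv_folds folds for cross-validation, 0 to skip (default 5)
#' @param hyperparams explicit model hyperparameters or NULL for the grid
#' @param top_n_genes genes taken from each model's importance ranking when
#'   forming the overlapping list (default 100)
#' @param cluster_k hub cluster count or `"auto"`
#' @param k_max auto-selection ceiling
#' @param seed master seed
#' @return list of class `run_config`
#' @export
run_config <- function(sim = sim_config(),
                       thresholds = filter_thresholds(),
                       n_axes = 4L,
                       adjust_mode = "residual_plus_intercept",
                       train_fraction = 0.70,
                       cv_folds = 5L,
                       hyperparams = list(max_depth = 6L, eta = 0.1,
                                          nrounds = 200L),
                       top_n_genes = 100L,
                       cluster_k = "auto",
                       k_max = 6L,
                       seed = 1L) {
  structure(list(sim = sim, thresholds = thresholds, n_axes = n_axes,
                 adjust_mode = adjust_mode, train_fraction = train_fraction,
                 cv_folds = cv_folds, hyperparams = hyperparams,
                 top_n_genes = top_n_genes, cluster_k = cluster_k,
                 k_max = k_max, seed = seed),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; the `sim` and
#' `thresholds` keys take the corresponding constructor arguments as nested
#' maps.
#'
#' @param path YAML file
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("YAML configuration requires the yaml package")
  y <- yaml::read_yaml(path)
  sim <- do.call(sim_config, y$sim %||% list())
  thr <- do.call(filter_thresholds, y$thresholds %||% list())
  args <- y[setdiff(names(y), c("sim", "thresholds"))]
  do.call(run_config, c(list(sim = sim, thresholds = thr), args))
}

#' Run the full pipeline: simulate, filter, adjust, collapse, train, cluster
#'
#' Executes every stage on a synthetic cohort and, when `out_dir` is given,
#' writes all intermediate artifacts (TSV/JSON/Newick) plus a JSON manifest
#' recording the configuration, seeds, per-stage row/column counts and the
#' summary metrics.
#'
#' @param config a [run_config()]
#' @param out_dir optional output directory (created if missing)
#' @return list with `genotype`, `adjusted`, `genes`, `split`, `models`
#'   (per-representation fit/report), `cv`, `overlap`, `hubs` (per class),
#'   `manifest`
#' @export
run_all <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  stages <- character(0)
  note <- function(s) { stages <<- c(stages, s); msg("stage: %s", s) }

  ## 1: simulate
  note("simulate")
  config$sim$seed <- derive_seed(config$seed, "simulate")
  sim <- simulate_cohorts(config$sim)

  ## 2: filter
  note("filter")
  kept <- filter_calls(sim$calls, config$thresholds)
  G <- build_genotype_matrix(kept, names(sim$truth$class_labels),
                             sim$truth$class_labels)

  ## 3: adjust
  note("adjust")
  axes <- compute_axes(G, n_axes = config$n_axes)
  A <- adjust_dataset(G, axes, mode = config$adjust_mode)

  ## 4: features
  note("features")
  C <- gene_counts(A)

  ## 5: train both representations
  note("train")
  split <- balance_and_split(unname(A$labels),
                             train_fraction = config$train_fraction,
                             seed = derive_seed(config$seed, "split"))
  reps <- list(snv = A$values, gene = C$values)
  models <- list()
  for (kind in names(reps)) {
    X <- reps[[kind]]
    fit <- train_regressor(X[split$train_idx, , drop = FALSE],
                           A$adjusted_phenotype[split$train_idx],
                           hyperparams = config$hyperparams,
                           seed = derive_seed(config$seed, paste0("train_", kind)))
    report <- evaluate(fit, X[split$test_idx, , drop = FALSE],
                       unname(A$labels[split$test_idx]))
    genes <- important_genes(fit, feature_kind = ifelse(kind == "snv", "snv",
                                                        "gene"),
                             variant_to_gene = A$variant_to_gene)
    models[[kind]] <- list(fit = fit, report = report, genes = genes)
  }
  cv <- NULL
  if (config$cv_folds >= 2L) {
    keep <- split$kept_idx
    cv <- list()
    for (kind in names(reps)) {
      cv[[kind]] <- cross_validate(reps[[kind]][keep, , drop = FALSE],
                                   A$adjusted_phenotype[keep],
                                   unname(A$labels[keep]),
                                   k = config$cv_folds,
                                   seed = derive_seed(config$seed, "cv"),
                                   hyperparams = config$hyperparams %||%
                                     list(max_depth = 6L, eta = 0.1))
    }
  }

  ## 6: overlap + hub clustering per class
  note("hub")
  top <- function(g) head(g, config$top_n_genes)
  overlap <- overlap_genes(top(models$snv$genes), top(models$gene$genes))
  hubs <- list()
  for (cl in c("SCZ", "ASD")) {
    hubs[[cl]] <- tryCatch(
      hub_cluster(C, cl, gene_subset = intersect(overlap, C$gene_ids),
                  k = config$cluster_k, k_max = config$k_max),
      error = function(e) {
        msg("hub clustering for %s skipped: %s", cl, conditionMessage(e))
        NULL
      })
  }

  manifest <- list(
    seed = config$seed,
    stage_seeds = list(simulate = derive_seed(config$seed, "simulate"),
                       split = derive_seed(config$seed, "split"),
                       cv = derive_seed(config$seed, "cv")),
    stages_completed = stages,
    counts = list(n_samples = length(G$sample_ids),
                  n_calls_simulated = nrow(sim$calls),
                  n_calls_retained = nrow(kept),
                  rejection_counts = as.list(attr(kept, "rejection_counts")),
                  n_variants = length(G$variant_ids),
                  n_genes = length(C$gene_ids),
                  n_train_per_class = split$n_train_per_class,
                  n_test_per_class = split$n_test_per_class,
                  n_overlap_genes = length(overlap)),
    metrics = list(
      test = lapply(models, function(m)
        m$report[c("accuracy", "precision", "recall", "nir",
                   "p_value_acc_gt_nir", "ci95")]),
      cv = if (!is.null(cv)) lapply(cv, function(x)
        x[c("accuracy", "precision", "recall", "nir")])),
    hubs = lapply(hubs, function(h) if (is.null(h)) NULL else
      list(clusters = h$clusters, selected_cluster = h$selected_cluster,
           selected_genes = h$selected_genes)),
    versions = list(exomehub = as.character(utils::packageVersion("exomehub")),
                    r = R.version.string))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_calls_tsv(sim$calls, file.path(out_dir, "calls.tsv"))
    write_truth_json(sim$truth, file.path(out_dir, "truth.json"))
    write_calls_tsv(kept, file.path(out_dir, "calls.filtered.tsv"))
    write_genotype_matrix(G, file.path(out_dir, "genotype_matrix.tsv"))
    write_variant_gene_map(G$variant_to_gene,
                           file.path(out_dir, "variant_gene_map.tsv"))
    write_axes_tsv(axes, file.path(out_dir, "axes.tsv"))
    write_genotype_matrix(A, file.path(out_dir, "adjusted_matrix.tsv"))
    CG <- list(sample_ids = C$sample_ids, labels = C$labels,
               adjusted_phenotype = C$adjusted_phenotype, values = C$values)
    write_genotype_matrix(CG, file.path(out_dir, "gene_counts.tsv"))
    data.table::fwrite(data.table::data.table(gene = overlap),
                       file.path(out_dir, "overlap_genes.tsv"), sep = "\t",
                       col.names = FALSE)
    for (cl in names(hubs)) {
      if (is.null(hubs[[cl]])) next
      data.table::fwrite(hubs[[cl]]$clusters,
                         file.path(out_dir, sprintf("hub_%s_clusters.tsv", cl)),
                         sep = "\t")
      if (requireNamespace("ape", quietly = TRUE))
        write_newick(hubs[[cl]]$tree,
                     file.path(out_dir, sprintf("hub_%s_dendrogram.nwk", cl)))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }

  list(sim = sim, genotype = G, axes = axes, adjusted = A, genes = C,
       split = split, models = models, cv = cv, overlap = overlap,
       hubs = hubs, manifest = manifest)
}
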