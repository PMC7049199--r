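#' Balance two classes and split per class into train and test
#'
#' The larger class is subsampled to the smaller class's size —
#' `selection = "first_n"` takes the first samples in deterministic input
#' order (the published convention), `"random"` samples with the seed. Each
#' class is then partitioned with `round(train_fraction * n)` training
#' samples; the train/test assignment within a class is a seeded permutation.
#'
#' @param labels per-sample class labels (character), in input order
#' @param train_fraction training share (default 0.70)
#' @param seed integer seed for the permutation (and random selection)
#' @param selection `"first_n"` (default) or `"random"`
#' @return list of class `split_plan`: `train_idx`, `test_idx` (indices into
#'   the input), `kept_idx`, per-class counts
#' @export
balance_and_split <- function(labels, train_fraction = 0.70, seed = 1L,
                              selection = c("first_n", "random")) {
  selection <- match.arg(selection)
  classes <- unique(labels)
  if (length(classes) != 2L) stop("exactly two classes required")
  idx_by_class <- split(seq_along(labels), labels)
  sizes <- lengths(idx_by_class)
  if (any(sizes < 2L)) stop("each class needs at least 2 samples")
  n_bal <- min(sizes)
  set.seed(seed)
  kept <- lapply(idx_by_class, function(ix) {
    if (length(ix) == n_bal) ix
    else if (selection == "first_n") ix[seq_len(n_bal)]
    else sort(sample(ix, n_bal))
  })
  n_train <- as.integer(round(train_fraction * n_bal))
  if (n_train < 1L || n_train >= n_bal)
    stop("train_fraction leaves an empty train or test set")
  train_idx <- integer(0)
  test_idx <- integer(0)
  for (cl in names(kept)) {
    perm <- sample(kept[[cl]])
    train_idx <- c(train_idx, perm[seq_len(n_train)])
    test_idx <- c(test_idx, perm[(n_train + 1L):n_bal])
  }
  structure(list(train_idx = sort(train_idx),
                 test_idx = sort(test_idx),
                 kept_idx = sort(unlist(kept, use.names = FALSE)),
                 n_per_class = n_bal,
                 n_train_per_class = n_train,
                 n_test_per_class = n_bal - n_train,
                 train_fraction = train_fraction,
                 seed = seed,
                 selection = selection),
            class = "split_plan")
}

#' Train the boosted-regression-trees model, tuning a small fixed grid
#'
#' With `hyperparams = NULL` a fixed grid (depth in {3, 6}, learning rate in
#' {0.1, 0.3}) is evaluated with early stopping on a seeded 20% validation
#' slice of the training data, and the best configuration is refit on the full
#' training set for its best number of rounds. Passing explicit `hyperparams`
#' (a list with `max_depth`, `eta` and optionally `nrounds`) skips the grid.
#' The chosen settings and seed are recorded on the returned model.
#'
#' @param X_train integer feature matrix
#' @param y_train adjusted integer phenotype (regression target)
#' @param hyperparams optional explicit hyperparameters
#' @param seed seed for the validation slice
#' @param nrounds cap on boosting rounds
#' @return an `exomehub_gbrt` model with a `tuning` field
#' @export
train_regressor <- function(X_train, y_train, hyperparams = NULL, seed = 1L,
                            nrounds = 300L) {
  if (anyNA(X_train)) stop("NaN/NA in features")
  if (!is.null(hyperparams)) {
    m <- gbrt(X_train, y_train,
              nrounds = hyperparams$nrounds %||% nrounds,
              eta = hyperparams$eta %||% 0.1,
              max_depth = hyperparams$max_depth %||% 6L)
    m$tuning <- list(grid = NULL, chosen = hyperparams, seed = seed)
    return(m)
  }
  set.seed(seed)
  n <- nrow(X_train)
  val <- sort(sample(n, max(1L, round(0.2 * n))))
  tr <- setdiff(seq_len(n), val)
  grid <- expand.grid(max_depth = c(3L, 6L), eta = c(0.1, 0.3))
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    fit <- gbrt(X_train[tr, , drop = FALSE], y_train[tr],
                nrounds = nrounds, eta = grid$eta[i],
                max_depth = grid$max_depth[i],
                X_valid = X_train[val, , drop = FALSE],
                y_valid = y_train[val])
    rmse <- min(fit$valid_rmse)
    if (is.null(best) || rmse < best$rmse - 1e-10)
      best <- list(rmse = rmse, max_depth = grid$max_depth[i],
                   eta = grid$eta[i], nrounds = fit$best_iter)
  }
  m <- gbrt(X_train, y_train, nrounds = best$nrounds, eta = best$eta,
            max_depth = best$max_depth)
  m$tuning <- list(grid = grid, chosen = best, seed = seed)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Map continuous predictions to diagnostic classes
#'
#' Predictions above 0 map to the positive class (ASD), below 0 to the other
#' class (SCZ). A prediction of exactly 0 maps to the "below" class (SCZ) and
#' is logged as a tie; the count is attached as attribute `n_ties`.
#'
#' @param pred finite numeric predictions
#' @param positive_class class for predictions above zero
#' @param negative_class class for predictions below (or at) zero
#' @return character vector of mapped classes with attribute `n_ties`
#' @export
map_prediction <- function(pred, positive_class = "ASD",
                           negative_class = "SCZ") {
  if (any(!is.finite(pred))) stop("predictions must be finite")
  ties <- sum(pred == 0)
  if (ties > 0) msg("map_prediction: %d tie(s) at 0 mapped to %s", ties,
                    negative_class)
  out <- ifelse(pred > 0, positive_class, negative_class)
  attr(out, "n_ties") <- ties
  out
}

#' Evaluate mapped predictions against true class labels
#'
#' Accuracy is correct/total over mapped classes. Precision and recall are
#' computed for the positive class. NIR is the majority-class share of the
#' test labels; the p-value is a one-sided exact binomial test of accuracy
#' exceeding NIR, and the 95% CI on accuracy is exact Clopper-Pearson.
#'
#' @param model fitted model (or NULL when `predictions` given)
#' @param X_test test features
#' @param labels_test true class labels of the test samples
#' @param positive_class positive class for precision/recall (default ASD)
#' @param predictions optional precomputed continuous predictions
#' @return list of class `model_report`
#' @export
evaluate <- function(model, X_test, labels_test, positive_class = "ASD",
                     predictions = NULL) {
  if (is.null(predictions)) predictions <- predict(model, X_test)
  if (length(labels_test) == 0L) stop("empty test set")
  classes <- sort(unique(labels_test))
  negative_class <- setdiff(c("ASD", "SCZ", classes), positive_class)[1]
  mapped <- map_prediction(predictions, positive_class, negative_class)
  n <- length(labels_test)
  correct <- sum(mapped == labels_test)
  tp <- sum(mapped == positive_class & labels_test == positive_class)
  fp <- sum(mapped == positive_class & labels_test != positive_class)
  fn <- sum(mapped != positive_class & labels_test == positive_class)
  nir <- max(table(labels_test)) / n
  if (length(unique(labels_test)) == 1L)
    warning("single-class test set: degenerate report (NIR = 1)")
  bt_p <- stats::binom.test(correct, n, p = min(nir, 1 - 1e-12),
                            alternative = "greater")$p.value
  ci <- stats::binom.test(correct, n)$conf.int
  structure(list(predictions = predictions,
                 mapped = as.character(mapped),
                 n_ties = attr(mapped, "n_ties"),
                 accuracy = correct / n,
                 precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 nir = nir,
                 p_value_acc_gt_nir = bt_p,
                 ci95 = c(ci[1], ci[2]),
                 n_test = n,
                 positive_class = positive_class),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf(paste0("model report: accuracy %.3f (95%% CI %.3f-%.3f), ",
                     "precision %.3f, recall %.3f, NIR %.3f, p(acc>NIR) %.3g\n"),
              x$accuracy, x$ci95[1], x$ci95[2], x$precision, x$recall,
              x$nir, x$p_value_acc_gt_nir))
  invisible(x)
}

#' Stratified k-fold cross-validation of the boosted-trees classifier
#'
#' Folds are stratified by class (per-fold class imbalance at most one
#' sample). Each fold is trained with the supplied hyperparameters (default:
#' depth 6, eta 0.1, up to 200 rounds with early stopping on a 20% slice of
#' the fold's training data) and evaluated as in [evaluate()]; fold metrics
#' are arithmetically averaged.
#'
#' @param X feature matrix (balanced dataset)
#' @param y adjusted phenotype
#' @param labels class labels
#' @param k folds (default 5)
#' @param seed seed controlling fold assignment
#' @param hyperparams list passed to [gbrt()]
#' @param positive_class positive class
#' @return list of class `cv_report`: per-fold reports plus averaged metrics
#' @export
cross_validate <- function(X, y, labels, k = 5L, seed = 1L,
                           hyperparams = list(max_depth = 6L, eta = 0.1,
                                              nrounds = 200L),
                           positive_class = "ASD") {
  if (k < 2L) stop("k must be at least 2")
  if (k > min(table(labels))) stop("k exceeds the size of a class")
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    ix <- which(labels == cl)
    fold[ix] <- sample(rep_len(seq_len(k), length(ix)))
  }
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    ntr <- length(tr)
    val <- sort(sample(ntr, max(1L, round(0.2 * ntr))))
    fit <- gbrt(X[tr[-val], , drop = FALSE], y[tr[-val]],
                nrounds = hyperparams$nrounds %||% 200L,
                eta = hyperparams$eta %||% 0.1,
                max_depth = hyperparams$max_depth %||% 6L,
                X_valid = X[tr[val], , drop = FALSE], y_valid = y[tr[val]])
    reports[[f]] <- evaluate(fit, X[te, , drop = FALSE], labels[te],
                             positive_class = positive_class)
  }
  avg <- function(field) mean(vapply(reports, `[[`, numeric(1), field))
  structure(list(folds = reports,
                 k = k,
                 accuracy = avg("accuracy"),
                 precision = avg("precision"),
                 recall = avg("recall"),
                 nir = avg("nir"),
                 seed = seed,
                 hyperparams = hyperparams),
            class = "cv_report")
}

#' Extract the ranked important genes used by a model
#'
#' Features with strictly positive gain importance, in descending order. For
#' SNV-based models the features are variants and are mapped to genes through
#' `variant_to_gene`, collapsing duplicates while keeping each gene's best
#' rank.
#'
#' @param model an `exomehub_gbrt`
#' @param feature_kind `"snv"` or `"gene"`
#' @param variant_to_gene named map, required for `feature_kind = "snv"`
#' @return character vector of genes, most important first; the feature-level
#'   ranking is attached as attribute `features`
#' @export
important_genes <- function(model, feature_kind = c("gene", "snv"),
                            variant_to_gene = NULL) {
  feature_kind <- match.arg(feature_kind)
  imp <- model$importance[model$importance > 0]
  imp <- imp[order(-imp, names(imp))]
  feats <- names(imp)
  if (feature_kind == "snv") {
    if (is.null(variant_to_gene)) stop("variant_to_gene required for snv kind")
    genes <- unname(variant_to_gene[feats])
    genes <- genes[!is.na(genes)]
    genes <- genes[!duplicated(genes)]
  } else {
    genes <- feats
  }
  attr(genes, "features") <- data.frame(feature = feats,
                                        importance = unname(imp),
                                        stringsAsFactors = FALSE)
  genes
}

#' Overlap two ranked gene lists
#'
#' Set intersection of the two lists, ordered by the mean of each gene's ranks
#' in the two inputs (best first; ties broken lexicographically).
#'
#' @param list_snv,list_gene ranked character vectors
#' @return ordered character vector of shared genes
#' @export
overlap_genes <- function(list_snv, list_gene) {
  common <- intersect(list_snv, list_gene)
  if (!length(common)) return(character(0))
  mean_rank <- (match(common, list_snv) + match(common, list_gene)) / 2
  common[order(mean_rank, common)]
}
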