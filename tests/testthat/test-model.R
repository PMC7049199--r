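test_that("balance_and_split reproduces the published arithmetic", {
  labels <- rep(c("ASD", "SCZ"), each = 598L)
  sp <- balance_and_split(labels, train_fraction = 0.70, seed = 1L)
  expect_identical(sp$n_train_per_class, 419L)
  expect_identical(sp$n_test_per_class, 179L)
  expect_length(sp$train_idx, 838L)
  expect_length(sp$test_idx, 358L)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0L)
  expect_setequal(c(sp$train_idx, sp$test_idx), seq_len(1196L))
})

test_that("first_n balancing keeps the first samples of the larger class", {
  labels <- c(rep("ASD", 10L), rep("SCZ", 7L))
  sp <- balance_and_split(labels, train_fraction = 0.7, seed = 2L,
                          selection = "first_n")
  expect_setequal(setdiff(seq_len(10L), sp$kept_idx), 8:10)
  expect_error(balance_and_split(labels, train_fraction = 1.0), "empty")
  expect_error(balance_and_split(rep("ASD", 5L)), "two classes")
})

test_that("map_prediction applies the sign rule with a logged tie at zero", {
  expect_identical(as.character(map_prediction(0.3)), "ASD")
  expect_identical(as.character(map_prediction(-1.2)), "SCZ")
  suppressMessages(m <- map_prediction(c(0, 0.1, 0)))
  expect_identical(as.character(m), c("SCZ", "ASD", "SCZ"))
  expect_identical(attr(m, "n_ties"), 2L)
  expect_error(map_prediction(c(1, Inf)), "finite")
})

test_that("evaluate reproduces confusion-matrix arithmetic and binomial p", {
  # perfect predictions on a balanced 20-sample set
  labels <- rep(c("ASD", "SCZ"), each = 10L)
  perfect <- evaluate(NULL, NULL, labels,
                      predictions = ifelse(labels == "ASD", 1, -1))
  expect_equal(perfect$accuracy, 1.0)
  expect_equal(perfect$precision, 1.0)
  expect_equal(perfect$recall, 1.0)
  expect_equal(perfect$nir, 0.5)
  expect_true(perfect$ci95[1] <= 1 & perfect$ci95[2] >= 1)

  # TP=90 FN=10 TN=80 FP=20
  labels2 <- c(rep("ASD", 100L), rep("SCZ", 100L))
  preds2 <- c(rep(1, 90), rep(-1, 10), rep(-1, 80), rep(1, 20))
  r <- evaluate(NULL, NULL, labels2, predictions = preds2)
  expect_equal(r$accuracy, 0.85)
  expect_equal(r$precision, 90 / 110)
  expect_equal(r$recall, 0.90)
  expect_equal(r$p_value_acc_gt_nir, oracle_binom_tail(170, 200, 0.5),
               tolerance = 1e-12)

  # all-one-class predictions on a balanced set: accuracy = NIR
  suppressMessages(r2 <- evaluate(NULL, NULL, labels,
                                  predictions = rep(-1, 20)))
  expect_equal(r2$accuracy, 0.5)
  expect_equal(r2$nir, 0.5)
  expect_equal(r2$p_value_acc_gt_nir, oracle_binom_tail(10, 20, 0.5),
               tolerance = 1e-12)
})

test_that("gbrt nails a separable toy and records importance", {
  set.seed(1)
  n <- 120L
  x <- sample(c(-2L, -1L, 1L, 2L), n, replace = TRUE)
  X <- cbind(sig = x, noise = sample(-1:1, n, replace = TRUE))
  y <- ifelse(x > 0, 1, -1)
  fit <- gbrt(X, y, nrounds = 50L, eta = 0.3, max_depth = 2L)
  labels <- ifelse(y > 0, "ASD", "SCZ")
  r <- evaluate(fit, X, labels)
  expect_equal(r$accuracy, 1.0)
  expect_gt(fit$importance["sig"], 0)
  expect_gt(fit$importance["sig"], fit$importance["noise"])
  expect_error(gbrt(matrix(c(1, NA), 2, 1), c(1, -1)), "NaN|NA")
})

test_that("gbrt is deterministic and early stopping truncates the model", {
  set.seed(2)
  X <- matrix(sample(-2:2, 400L, replace = TRUE), 100L, 4L)
  colnames(X) <- paste0("f", 1:4)
  y <- X[, 1] * 0.5 + stats::rnorm(100L, sd = 0.2)
  f1 <- gbrt(X, y, nrounds = 80L)
  f2 <- gbrt(X, y, nrounds = 80L)
  expect_equal(predict(f1, X), predict(f2, X))
  fv <- gbrt(X[1:70, ], y[1:70], nrounds = 400L,
             X_valid = X[71:100, ], y_valid = y[71:100], patience = 10L)
  expect_lte(fv$best_iter, length(fv$valid_rmse))
  expect_identical(length(fv$trees), as.integer(fv$best_iter))
})

test_that("pure-noise features stay near chance accuracy", {
  accs <- vapply(1:10, function(seed) {
    set.seed(seed)
    n <- 200L
    X <- matrix(sample(-1:1, n * 50L, replace = TRUE), n, 50L)
    colnames(X) <- paste0("f", 1:50)
    y <- rep(c(1, -1), each = n / 2L)
    labels <- ifelse(y > 0, "ASD", "SCZ")
    sp <- balance_and_split(labels, seed = seed)
    fit <- gbrt(X[sp$train_idx, ], y[sp$train_idx], nrounds = 60L)
    evaluate(fit, X[sp$test_idx, ], labels[sp$test_idx])$accuracy
  }, numeric(1))
  expect_true(all(accs >= 0.35 & accs <= 0.65))
})

test_that("cross_validate stratifies, averages and is seed-stable", {
  set.seed(7)
  n <- 110L
  X <- matrix(sample(-2:2, n * 6L, replace = TRUE), n, 6L)
  colnames(X) <- paste0("f", 1:6)
  y <- ifelse(seq_len(n) <= 55L, 1, -1) # class 1 slightly larger fold sizes
  labels <- ifelse(y > 0, "ASD", "SCZ")
  X[, 1] <- as.integer(y * 2L)  # make it learnable
  cv1 <- cross_validate(X, y, labels, k = 5L, seed = 3L,
                        hyperparams = list(max_depth = 3L, eta = 0.3,
                                           nrounds = 40L))
  cv2 <- cross_validate(X, y, labels, k = 5L, seed = 3L,
                        hyperparams = list(max_depth = 3L, eta = 0.3,
                                           nrounds = 40L))
  expect_equal(cv1$accuracy, cv2$accuracy)
  expect_equal(cv1$accuracy,
               mean(vapply(cv1$folds, `[[`, numeric(1), "accuracy")))
  sizes <- vapply(cv1$folds, `[[`, numeric(1), "n_test")
  expect_lte(max(sizes) - min(sizes), 2)
  expect_error(cross_validate(X, y, labels, k = 60L), "exceeds")
})

test_that("important_genes ranks by gain and collapses variants to genes", {
  fake <- structure(list(importance = c(v1 = 3.0, v2 = 0.0, v3 = 5.0,
                                        v4 = 1.0)),
                    class = "exomehub_gbrt")
  v2g <- c(v1 = "GA", v2 = "GB", v3 = "GC", v4 = "GA")
  genes <- important_genes(fake, "snv", v2g)
  expect_identical(as.character(genes), c("GC", "GA"))  # zero-gain v2 dropped
  feats <- attr(genes, "features")
  expect_identical(feats$feature, c("v3", "v1", "v4"))
  expect_true(all(feats$importance > 0))

  none <- structure(list(importance = c(v1 = 0.0)), class = "exomehub_gbrt")
  expect_length(important_genes(none, "snv", v2g), 0L)
  expect_error(important_genes(fake, "snv"), "variant_to_gene")
})

test_that("overlap_genes intersects with deterministic mean-rank order", {
  expect_length(overlap_genes(c("A", "B"), c("C", "D")), 0L)
  expect_identical(overlap_genes(c("A", "B", "C"), c("A", "B", "C")),
                   c("A", "B", "C"))
  expect_identical(overlap_genes(c("A", "B", "C"), c("B", "C", "D")),
                   c("B", "C"))
  # C ranks (3,1) mean 2; B ranks (2,3) mean 2.5 -> C first
  expect_identical(overlap_genes(c("A", "B", "C"), c("C", "A", "B")),
                   c("A", "C", "B"))
})
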