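make_gene_matrix <- function(values, labels) {
  structure(list(sample_ids = rownames(values), gene_ids = colnames(values),
                 values = values,
                 adjusted_phenotype = ifelse(labels == "ASD", 1L, -1L),
                 labels = labels, all_zero_genes = character(0)),
            class = "gene_count_matrix")
}

test_that("carrier sets use the strict greater-than-zero rule", {
  vals <- matrix(c(1L, 0L, -1L,
                   0L, 2L, 0L,
                   0L, 0L, 0L), 3, 3,
                 dimnames = list(c("case1", "case2", "case3"),
                                 c("g1", "g2", "g3")))
  labels <- stats::setNames(rep("SCZ", 3), rownames(vals))
  cs <- carrier_sets(make_gene_matrix(vals, labels), "SCZ")
  expect_identical(cs$sets$g1, "case1")
  expect_identical(cs$sets$g2, "case2")
  expect_length(cs$sets$g3, 0L)
  expect_identical(cs$n_cases_total, 3L)
  expect_error(carrier_sets(make_gene_matrix(vals, labels), "ASD"), "no cases")
})

test_that("jaccard and the distance matrix follow the definitions", {
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard(c("a"), c("b")), 0)
  expect_equal(jaccard(c(1, 2, 3), c(2, 3, 4)), 0.5)
  expect_equal(jaccard(character(0), character(0)), 0)  # declared convention
  sets <- list(g1 = c("a", "b", "c"), g2 = c("b", "c", "d"),
               g3 = c("a", "b", "c"), g4 = "z")
  D <- distance_matrix(sets)
  expect_equal(D["g1", "g2"], 0.5)
  expect_equal(D["g1", "g3"], 0)
  expect_equal(D["g1", "g4"], 1)
  expect_identical(D, t(D))
  expect_true(all(diag(D) == 0))
})

test_that("jaccard properties hold on random triples", {
  set.seed(42)
  for (i in 1:300) {
    s <- random_sets(3)
    j12 <- jaccard(s[[1]], s[[2]])
    expect_identical(j12, jaccard(s[[2]], s[[1]]))
    expect_true(j12 >= 0 && j12 <= 1)
    d <- function(a, b) 1 - jaccard(a, b)
    expect_lte(d(s[[1]], s[[3]]),
               d(s[[1]], s[[2]]) + d(s[[2]], s[[3]]) + 1e-12)
  }
})

test_that("ward linkage merges the closest pair first and is well-formed", {
  D <- matrix(c(0, 0.1, 0.9,
                0.1, 0, 0.9,
                0.9, 0.9, 0), 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  tree <- ward_linkage(D)
  expect_identical(tree$merge[1, ], c(-1L, -2L))
  expect_identical(nrow(tree$merge), 2L)
  expect_true(all(diff(tree$height) >= -1e-12))
  expect_equal(tree$height[1], 0.1)
  expect_error(ward_linkage(matrix(c(0, NA, NA, 0), 2, 2)), "NaN|NA")
})

test_that("ward linkage agrees with the naive recompute-from-scratch oracle", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    pts <- matrix(stats::rnorm(n * 3), n)
    D <- as.matrix(stats::dist(pts))
    dimnames(D) <- list(paste0("g", 1:n), paste0("g", 1:n))
    tree <- ward_linkage(D)
    or <- oracle_ward(D)
    expect_identical(tree$merge, or$merge)
    expect_equal(tree$height, or$height, tolerance = 1e-9)
  }
})

test_that("ward linkage on Euclidean input matches hclust ward.D2 heights", {
  set.seed(9)
  pts <- matrix(stats::rnorm(14), 7)
  D <- as.matrix(stats::dist(pts))
  dimnames(D) <- list(paste0("g", 1:7), paste0("g", 1:7))
  tree <- ward_linkage(D)
  hc <- stats::hclust(stats::dist(pts), method = "ward.D2")
  expect_equal(sort(tree$height), sort(hc$height), tolerance = 1e-9)
})

test_that("cut_clusters covers the degenerate and auto cases", {
  set.seed(5)
  # two well-separated planted modules
  sets <- c(lapply(1:5, function(i) sample(paste0("x", 1:20), 15)),
            lapply(1:5, function(i) sample(paste0("y", 1:20), 15)))
  names(sets) <- paste0("g", 1:10)
  tree <- ward_linkage(distance_matrix(sets))
  expect_identical(unname(cut_clusters(tree, k = 1L)),
                   rep(1L, 10L))
  expect_identical(unname(cut_clusters(tree, k = 10L)), 1:10)
  auto <- cut_clusters(tree, k = "auto")
  expect_identical(max(auto), 2L)
  expect_identical(unname(auto[1:5]), rep(auto[[1]], 5))
  expect_identical(unname(auto[6:10]), rep(auto[[6]], 5))
  expect_error(cut_clusters(tree, k = 99L), "unattainable")
})

test_that("rank_clusters computes a, b, ratio, coverage and selects the hub", {
  sets <- structure(list(sets = list(g1 = c("c1", "c2", "c3"),
                                     g2 = c("c2", "c4"),
                                     g3 = "c5"),
                         class = "SCZ", n_cases_total = 10L),
                    class = "carrier_sets")
  assignments <- c(g1 = 1L, g2 = 1L, g3 = 2L)
  res <- rank_clusters(assignments, sets)
  expect_identical(res$clusters$a, c(2L, 1L))
  expect_identical(res$clusters$b, c(4L, 1L))
  expect_equal(res$clusters$ratio, c(2, 1))
  expect_equal(res$clusters$coverage, c(0.4, 0.1))
  expect_identical(res$selected_cluster, 1L)
  # singleton cluster with a single carrier has ratio 1
  expect_equal(res$clusters$ratio[2], 1.0)
  # union bounds: b between max and sum of per-gene carrier counts
  expect_gte(res$clusters$b[1], 3L)
  expect_lte(res$clusters$b[1], 5L)
})

test_that("hub_cluster excludes carrier-free genes and recovers a module", {
  set.seed(11)
  cases <- paste0("s", 1:60)
  labels <- stats::setNames(rep("SCZ", 60), cases)
  vals <- matrix(0L, 60, 12,
                 dimnames = list(cases, paste0("g", 1:12)))
  # genes 1-5: dense overlapping module; 6-11: sparse scattered; 12: empty
  for (g in 1:5) vals[sample(1:40, 25), g] <- 1L
  for (g in 6:11) vals[sample(41:60, 4), g] <- 1L
  C <- make_gene_matrix(vals, labels)
  res <- hub_cluster(C, "SCZ", k = 2L)
  expect_identical(res$excluded_genes, "g12")
  expect_setequal(res$selected_genes, paste0("g", 1:5))
  expect_equal(res$clusters$b[res$clusters$cluster == res$selected_cluster],
               length(unique(unlist(
                 lapply(1:5, function(g) rownames(vals)[vals[, g] > 0])))))
})

test_that("newick export writes a readable tree", {
  skip_if_not_installed("ape")
  D <- as.matrix(stats::dist(matrix(stats::rnorm(10), 5)))
  dimnames(D) <- list(paste0("g", 1:5), paste0("g", 1:5))
  tree <- ward_linkage(D)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, paste0("g", 1:5))
})
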