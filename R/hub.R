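#' Per-gene carrier sets within one class's cases
#'
#' A case carries a gene when its gene-level count is strictly greater than
#' zero (signed adjusted sums: a zero or negative sum is not a carrier).
#' Restricted to the cases of one class.
#'
#' @param C a `gene_count_matrix`
#' @param class_filter class whose cases to use (e.g. `"SCZ"`)
#' @param gene_subset genes to consider (default: all genes in `C`)
#' @return list of class `carrier_sets`: `sets` (named list of case-id
#'   character vectors), `class`, `n_cases_total`
#' @export
carrier_sets <- function(C, class_filter, gene_subset = C$gene_ids) {
  if (!all(gene_subset %in% C$gene_ids))
    stop("gene_subset contains genes absent from the matrix")
  cases <- C$sample_ids[C$labels == class_filter]
  if (!length(cases)) stop("no cases with class ", class_filter)
  V <- C$values[cases, gene_subset, drop = FALSE]
  sets <- lapply(gene_subset, function(g) cases[V[, g] > 0L])
  names(sets) <- gene_subset
  structure(list(sets = sets, class = class_filter,
                 n_cases_total = length(cases)),
            class = "carrier_sets")
}

#' Jaccard similarity of two carrier sets
#'
#' |intersection| / |union|; two empty sets have similarity 0 by convention
#' (genes never mutated cannot co-occur).
#'
#' @param setU,setV vectors of case identifiers
#' @return similarity in \[0, 1\]
#' @export
jaccard <- function(setU, setV) {
  u <- length(union(setU, setV))
  if (u == 0L) return(0)
  length(intersect(setU, setV)) / u
}

#' Pairwise co-mutation distance matrix (one minus Jaccard)
#'
#' @param sets a `carrier_sets` object (or a plain named list of sets)
#' @return symmetric matrix with zero diagonal
#' @export
distance_matrix <- function(sets) {
  s <- if (inherits(sets, "carrier_sets")) sets$sets else sets
  ng <- length(s)
  if (ng < 2L) stop("need at least 2 genes")
  D <- matrix(0, ng, ng, dimnames = list(names(s), names(s)))
  for (i in seq_len(ng - 1L)) {
    for (j in (i + 1L):ng) {
      d <- 1 - jaccard(s[[i]], s[[j]])
      D[i, j] <- d
      D[j, i] <- d
    }
  }
  D
}

#' Agglomerative Ward linkage over a precomputed distance matrix
#'
#' Lance-Williams recursion with Ward coefficients applied to squared input
#' distances (the convention that reduces to classical Ward when distances
#' are Euclidean; heights are reported on the original distance scale as the
#' square root of the merge cost). Applied here directly to the non-Euclidean
#' Jaccard distances — the generic usage for co-mutation clustering, with the
#' usual geometric caveat. Ties in the minimum merge cost are broken
#' deterministically by the smallest leaf index contained in the candidate
#' pair.
#'
#' @param D symmetric distance matrix with zero diagonal (or a `dist`)
#' @return list of class `linkage_tree` with `merge` (hclust convention),
#'   `height`, `labels`, `order`
#' @export
ward_linkage <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (anyNA(D)) stop("NaN/NA distances")
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 items")
  if (max(abs(D - t(D))) > 1e-12 || any(diag(D) != 0))
    stop("distance matrix must be symmetric with zero diagonal")
  labels <- rownames(D)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  S <- D^2                     # working squared distances
  active <- seq_len(n)
  sizes <- rep(1L, n)
  node_id <- -seq_len(n)       # hclust convention: negative leaves
  min_leaf <- seq_len(n)       # smallest original leaf per active cluster
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    best <- NULL
    for (ii in seq_along(active)) {
      i <- active[ii]
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        j <- active[jj]
        s <- S[i, j]
        key <- sort(c(min_leaf[i], min_leaf[j]))
        if (is.null(best) || s < best$s - 1e-12 ||
            (abs(s - best$s) <= 1e-12 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, s = s, key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    a <- node_id[i]; b <- node_id[j]
    ## hclust-style row: leaves (negative) before internal nodes; within a
    ## kind, ascending leaf label / merge index
    if ((a > 0 && b < 0) || (a > 0 && b > 0 && a > b) ||
        (a < 0 && b < 0 && -a > -b)) {
      merge[step, ] <- c(b, a)
    } else {
      merge[step, ] <- c(a, b)
    }
    height[step] <- sqrt(best$s)

    ni <- sizes[i]; nj <- sizes[j]
    for (k in active) {
      if (k == i || k == j) next
      nk <- sizes[k]
      S[i, k] <- S[k, i] <- ((ni + nk) * S[i, k] + (nj + nk) * S[j, k] -
                               nk * S[i, j]) / (ni + nj + nk)
    }
    sizes[i] <- ni + nj
    node_id[i] <- step
    min_leaf[i] <- min(min_leaf[i], min_leaf[j])
    active <- active[active != j]
  }

  ord <- order_leaves(merge, n)
  structure(list(merge = merge, height = height, labels = labels,
                 order = ord, method = "ward", n = n),
            class = "linkage_tree")
}

order_leaves <- function(merge, n) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(n - 1L)
}

#' Convert a linkage tree to a base `hclust` object
#' @param x a `linkage_tree`
#' @param ... unused
#' @return an object of class `hclust`
#' @export
as.hclust.linkage_tree <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = "ward",
                 call = match.call(), dist.method = "1 - Jaccard"),
            class = "hclust")
}

#' Cut a linkage tree into flat clusters
#'
#' `k` may be an integer or `"auto"`: auto picks the number of clusters (from
#' 2 to `k_max`) at the largest gap between successive merge heights — the cut
#' that removes the most separated top merges.
#'
#' @param tree a `linkage_tree`
#' @param k cluster count or `"auto"`
#' @param k_max ceiling for auto selection (default 6)
#' @return named integer vector of cluster ids (1-based, in order of first
#'   appearance over the label order)
#' @export
cut_clusters <- function(tree, k = "auto", k_max = 6L) {
  n <- tree$n
  if (identical(k, "auto")) {
    ks <- 2:min(k_max, n)
    if (length(ks) == 0L) ks <- 1L
    h <- tree$height
    gap <- vapply(ks, function(kk) {
      if (kk >= n) return(h[1])
      h[n - kk + 1L] - h[n - kk]
    }, numeric(1))
    k <- ks[which.max(gap)]
  }
  if (k < 1L || k > n) stop("unattainable cluster count k = ", k)
  stats::cutree(as.hclust.linkage_tree(tree), k = k)
}

#' Rank flat clusters by their unique-carriers-per-gene ratio
#'
#' For each cluster: `a` is the gene count, `b` the number of unique cases of
#' the target class carrying a qualifying change in at least one cluster gene
#' (the size of the union of the carrier sets), `ratio = b / a`, and
#' `coverage = b / n_cases_total`. The cluster with the highest ratio is
#' selected as the hub cluster; ties go to the larger `b`, then the smaller
#' cluster id, and are logged.
#'
#' @param assignments named cluster assignment vector from [cut_clusters()]
#' @param sets a `carrier_sets` covering the clustered genes
#' @return list of class `hub_cluster_result` with `clusters` (data.frame of
#'   a, b, ratio, coverage per cluster), `assignments`, `selected_cluster`,
#'   `selected_genes`
#' @export
rank_clusters <- function(assignments, sets) {
  stopifnot(inherits(sets, "carrier_sets"))
  genes <- names(assignments)
  if (!all(genes %in% names(sets$sets)))
    stop("assignments cover genes without carrier sets")
  ids <- sort(unique(assignments))
  stats_df <- data.frame(cluster = ids, a = NA_integer_, b = NA_integer_,
                         ratio = NA_real_, coverage = NA_real_)
  for (r in seq_along(ids)) {
    g <- genes[assignments == ids[r]]
    union_cases <- unique(unlist(sets$sets[g], use.names = FALSE))
    stats_df$a[r] <- length(g)
    stats_df$b[r] <- length(union_cases)
    stats_df$ratio[r] <- length(union_cases) / length(g)
    stats_df$coverage[r] <- length(union_cases) / sets$n_cases_total
  }
  o <- order(-stats_df$ratio, -stats_df$b, stats_df$cluster)
  sel <- stats_df$cluster[o[1]]
  if (nrow(stats_df) > 1L &&
      abs(stats_df$ratio[o[1]] - stats_df$ratio[o[2]]) < 1e-12)
    msg("rank_clusters: ratio tie broken by carrier count / cluster id")
  structure(list(clusters = stats_df,
                 assignments = assignments,
                 selected_cluster = sel,
                 selected_genes = genes[assignments == sel],
                 class_label = sets$class,
                 n_cases_total = sets$n_cases_total),
            class = "hub_cluster_result")
}

#' @export
print.hub_cluster_result <- function(x, ...) {
  cat(sprintf("hub clustering (%s cases, n = %d):\n", x$class_label,
              x$n_cases_total))
  df <- x$clusters
  df$ratio <- round(df$ratio, 2)
  df$coverage <- sprintf("%.2f%%", 100 * df$coverage)
  print(df, row.names = FALSE)
  cat(sprintf("selected hub cluster: %d (%d genes)\n", x$selected_cluster,
              length(x$selected_genes)))
  invisible(x)
}

#' Run the full hub-gene clustering for one class
#'
#' Carrier sets on the gene-level matrix restricted to one class's cases,
#' Jaccard distances, Ward linkage, a flat cut and ratio-based hub selection.
#' Genes with empty carrier sets in the class carry no co-mutation
#' information and are excluded (and reported in `excluded_genes`).
#'
#' @param C a `gene_count_matrix`
#' @param class_filter target class
#' @param gene_subset genes to cluster (e.g. the overlapping ML gene list)
#' @param k cluster count or `"auto"`
#' @param k_max auto-selection ceiling
#' @return a `hub_cluster_result` with extra fields `tree` and
#'   `excluded_genes`
#' @export
hub_cluster <- function(C, class_filter, gene_subset = C$gene_ids,
                        k = "auto", k_max = 6L) {
  cs <- carrier_sets(C, class_filter, gene_subset)
  empty <- names(cs$sets)[lengths(cs$sets) == 0L]
  if (length(empty)) {
    msg("hub_cluster: excluding %d gene(s) with no %s carriers",
        length(empty), class_filter)
    cs$sets <- cs$sets[lengths(cs$sets) > 0L]
  }
  if (length(cs$sets) < 2L) stop("fewer than 2 genes with carriers")
  D <- distance_matrix(cs)
  tree <- ward_linkage(D)
  assignments <- cut_clusters(tree, k = k, k_max = k_max)
  res <- rank_clusters(assignments, cs)
  res$tree <- tree
  res$excluded_genes <- empty
  res
}

#' Export a linkage tree as Newick (heights as branch lengths)
#'
#' @param tree a `linkage_tree`
#' @param path output path
#' @export
write_newick <- function(tree, path) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("Newick export requires the ape package")
  phy <- ape::as.phylo(as.hclust.linkage_tree(tree))
  ape::write.tree(phy, file = path)
  invisible(path)
}
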