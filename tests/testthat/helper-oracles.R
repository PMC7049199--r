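# Independent oracles and small fixture builders. These deliberately avoid
# the package's own code paths: the Ward oracle recomputes merge costs from
# the original distances at every step instead of using the Lance-Williams
# recursion, and the binomial-tail oracle sums dbinom directly.

# Naive O(n^3) agglomerative Ward oracle. Cluster criterion computed from the
# ORIGINAL squared distances via the centroid identities
#   SS(A)          = sum_{a<a'} d^2(a,a') / |A|
#   ||cA - cB||^2  = mean cross d^2 - SS(A)/|A| - SS(B)/|B|
#   cost(A,B)      = 2|A||B|/(|A|+|B|) * ||cA - cB||^2
# with the same smallest-leaf-index tie-break as the implementation.
oracle_ward <- function(D) {
  n <- nrow(D)
  S <- D^2
  clusters <- as.list(seq_len(n))
  node_id <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  cost <- function(A, B) {
    ssa <- if (length(A) > 1) sum(S[A, A][upper.tri(S[A, A])]) / length(A) else 0
    ssb <- if (length(B) > 1) sum(S[B, B][upper.tri(S[B, B])]) / length(B) else 0
    cc <- mean(S[A, B, drop = FALSE]) - ssa / length(A) - ssb / length(B)
    2 * length(A) * length(B) / (length(A) + length(B)) * cc
  }
  for (step in seq_len(n - 1L)) {
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        cc <- cost(clusters[[i]], clusters[[j]])
        key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        if (is.null(best) || cc < best$cost - 1e-12 ||
            (abs(cc - best$cost) <= 1e-12 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, cost = cc, key = key)
        }
      }
    }
    a <- node_id[best$i]; b <- node_id[best$j]
    if ((a > 0 && b < 0) || (a > 0 && b > 0 && a > b) ||
        (a < 0 && b < 0 && -a > -b)) {
      merge[step, ] <- c(b, a)
    } else {
      merge[step, ] <- c(a, b)
    }
    height[step] <- sqrt(best$cost)
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    node_id[best$i] <- step
    clusters[[best$j]] <- NULL
    node_id <- node_id[-best$j]
  }
  list(merge = merge, height = height)
}

# Upper-tail binomial probability P(X >= k), summed directly.
oracle_binom_tail <- function(k, n, p) {
  sum(stats::dbinom(k:n, n, p))
}

# A single annotated call row passing every default threshold.
passing_call <- function(sample_id = "S1", variant_id = "1:100:A:T",
                         gene = "G1", coding_type = "nonsynonymous_SNV",
                         functional_type = "exonic", maf = 0.005,
                         genotype = 1L, alt_reads = 20L, depth = 40L,
                         gq = 99L, rsid = "rs1") {
  data.table::data.table(sample_id = sample_id, variant_id = variant_id,
                         rsid = rsid, gene = gene, coding_type = coding_type,
                         functional_type = functional_type, maf = maf,
                         genotype = genotype, alt_reads = alt_reads,
                         depth = depth, gq = gq)
}

# Small cohort used by several unit tests (kept light; signal-strength tests
# use the generator defaults instead).
small_sim <- function(seed = 42L, ...) {
  simulate_cohorts(sim_config(n_cases_per_class = 120L, n_genes_total = 300L,
                              n_discriminative_genes_per_class = 15L,
                              n_hub_genes_per_class = 8L, seed = seed, ...))
}

# Random carrier-set list over a small case universe.
random_sets <- function(n_sets, universe = paste0("c", 1:30),
                        min_size = 1, max_size = 20) {
  sets <- lapply(seq_len(n_sets), function(i)
    sample(universe, sample(min_size:max_size, 1)))
  names(sets) <- paste0("g", seq_len(n_sets))
  sets
}
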