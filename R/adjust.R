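#' Compute top axes of variation of a genotype matrix
#'
#' Principal axes of the samples x variants matrix, for population-structure
#' correction. Monomorphic columns are excluded. With `normalize = TRUE`
#' (default) each column is centered and scaled by sqrt(p(1-p)), p being half
#' the column mean genotype — the classical normalization for genotype PCA.
#' Scores are orthonormal over samples (left singular vectors); each axis is
#' given a deterministic sign by making its largest-magnitude variant loading
#' positive. A partial SVD (irlba) is used on large matrices.
#'
#' @param G a `genotype_matrix`
#' @param n_axes number of axes (default 4); must be < number of samples
#' @param normalize apply the allele-frequency normalization (default TRUE)
#' @return list of class `axes_of_variation`: `scores` (samples x n_axes,
#'   orthonormal), `eigenvalues`, `n_axes`, `used_variants`
#' @export
compute_axes <- function(G, n_axes = 4L, normalize = TRUE) {
  X <- G$values
  if (nrow(X) < 2L) stop("need at least 2 samples")
  if (n_axes >= nrow(X)) stop("n_axes must be smaller than the sample count")
  v <- matrixStats_colVars(X)
  poly <- v > 0
  if (!any(poly)) stop("no polymorphic variant columns: zero-variance input")
  Xp <- X[, poly, drop = FALSE]
  mu <- colMeans(Xp)
  Xc <- sweep(Xp, 2L, mu)
  if (normalize) {
    p <- mu / 2
    sc <- sqrt(p * (1 - p))
    Xc <- sweep(Xc, 2L, sc, "/")
  }
  if (min(dim(Xc)) > 150L) {
    s <- irlba::irlba(Xc, nv = n_axes, nu = n_axes)
  } else {
    s <- svd(Xc, nu = n_axes, nv = n_axes)
    s$d <- s$d[seq_len(n_axes)]
  }
  scores <- s$u
  loadings <- s$v
  for (a in seq_len(n_axes)) {
    i <- which.max(abs(loadings[, a]))
    if (loadings[i, a] < 0) {
      loadings[, a] <- -loadings[, a]
      scores[, a] <- -scores[, a]
    }
  }
  dimnames(scores) <- list(G$sample_ids, paste0("axis", seq_len(n_axes)))
  structure(list(scores = scores,
                 eigenvalues = s$d[seq_len(n_axes)]^2 / (nrow(X) - 1L),
                 n_axes = as.integer(n_axes),
                 used_variants = colnames(X)[poly]),
            class = "axes_of_variation")
}

## base-R column variances (avoids a matrixStats dependency)
matrixStats_colVars <- function(X) {
  n <- nrow(X)
  (colSums(X^2) - n * colMeans(X)^2) / (n - 1L)
}

#' Approximate Tracy-Widom significance of leading axes
#'
#' Patterson-style test statistic for each leading eigenvalue of the
#' normalized genotype covariance, with p-values interpolated from tabulated
#' quantiles of the Tracy-Widom (beta = 1) distribution. Reported for
#' inspection only; axis count selection is a configuration knob, not
#' automatic.
#'
#' @param G a `genotype_matrix`
#' @param n_axes number of leading axes to test
#' @return data.frame with eigenvalue, TW statistic and approximate p-value
#' @export
axis_significance <- function(G, n_axes = 4L) {
  X <- G$values
  v <- matrixStats_colVars(X)
  Xp <- X[, v > 0, drop = FALSE]
  mu <- colMeans(Xp)
  p <- mu / 2
  Xc <- sweep(sweep(Xp, 2L, mu), 2L, sqrt(p * (1 - p)), "/")
  ev <- svd(Xc, nu = 0, nv = 0)$d^2
  m <- nrow(Xc) - 1L
  out <- data.frame(axis = seq_len(n_axes), eigenvalue = NA_real_,
                    twstat = NA_real_, p_value = NA_real_)
  ## tabulated TW1 quantiles (x, upper-tail probability)
  twq <- cbind(x = c(-3.90, -3.18, -2.78, -2.42, -1.91, -1.27, -0.59, 0.45,
                     0.98, 1.45, 2.02, 3.27, 4.21),
               p = c(0.99, 0.95, 0.90, 0.80, 0.60, 0.40, 0.20, 0.05,
                     0.025, 0.01, 0.005, 0.001, 1e-4))
  for (a in seq_len(min(n_axes, length(ev) - 1L))) {
    lam <- ev[a:length(ev)]
    k <- length(lam)
    n_eff <- (m + 1) * sum(lam)^2 / sum(lam^2)  # effective marker count
    lam1 <- lam[1] * k / sum(lam)               # normalized leading eigenvalue
    mu_tw <- (sqrt(n_eff - 1) + sqrt(k))^2 / n_eff
    sig_tw <- (sqrt(n_eff - 1) + sqrt(k)) / n_eff *
      (1 / sqrt(n_eff - 1) + 1 / sqrt(k))^(1 / 3)
    tw <- (lam1 - mu_tw) / sig_tw
    pv <- stats::approx(twq[, "x"], twq[, "p"], xout = tw, rule = 2)$y
    out$eigenvalue[a] <- ev[a] / m
    out$twstat[a] <- tw
    out$p_value[a] <- pv
  }
  out
}

#' Regress a per-sample vector on the axes of variation and take residuals
#'
#' Ordinary least squares of `column` on the axis scores with an intercept.
#' `mode = "residual"` returns raw residuals; `mode = "residual_plus_intercept"`
#' adds the fitted intercept back, so only the axis effects are removed.
#' Collinear axes are dropped with a warning. Residuals are orthogonal to
#' every retained axis.
#'
#' @param column numeric vector, one value per sample
#' @param axes an `axes_of_variation`
#' @param mode `"residual"` or `"residual_plus_intercept"`
#' @return numeric vector of the same length
#' @export
regress_residual <- function(column, axes,
                             mode = c("residual_plus_intercept", "residual")) {
  mode <- match.arg(mode)
  if (length(column) != nrow(axes$scores))
    stop("column length must equal sample count")
  design <- cbind(intercept = 1, axes$scores)
  fit <- stats::lm.fit(design, column)
  if (any(is.na(fit$coefficients))) {
    warning("rank-deficient design: dropping collinear axis/axes")
    fit$coefficients[is.na(fit$coefficients)] <- 0
  }
  res <- column - drop(design %*% fit$coefficients)
  if (mode == "residual_plus_intercept") res <- res + fit$coefficients[1]
  unname(res)
}

#' Eigenstrat-style adjustment of a genotype matrix and its phenotype
#'
#' Regresses every variant column of the raw 0/1/2 matrix on the axes of
#' variation, takes residuals (optionally re-adding the intercept), rounds
#' half-away-from-zero to the nearest integer and caps to `[-4, +4]`. The
#' phenotype, encoded +1 for the positive class and -1 for the other, is
#' adjusted in exactly the same fashion.
#'
#' @param G a `genotype_matrix`
#' @param axes an `axes_of_variation` computed from the same samples
#' @param mode residual mode, see [regress_residual()]
#' @param positive_class class encoded +1 (default `"ASD"`)
#' @param cap inclusive integer cap (default `c(-4L, 4L)`)
#' @return list of class `adjusted_matrix`: `sample_ids`, `feature_ids`,
#'   `values` (integer matrix), `adjusted_phenotype`, `labels`,
#'   `variant_to_gene`, plus the pre-rounding residual matrix in
#'   attribute-free field `residuals` for diagnostics
#' @export
adjust_dataset <- function(G, axes,
                           mode = c("residual_plus_intercept", "residual"),
                           positive_class = "ASD", cap = c(-4L, 4L)) {
  mode <- match.arg(mode)
  if (!identical(rownames(axes$scores), G$sample_ids))
    stop("axes were not computed from the same samples")
  design <- cbind(intercept = 1, axes$scores)
  fit <- stats::lm.fit(design, G$values)
  coefs <- fit$coefficients
  if (any(is.na(coefs))) {
    warning("rank-deficient design: dropping collinear axis/axes")
    coefs[is.na(coefs)] <- 0
  }
  resid <- G$values - design %*% coefs
  if (mode == "residual_plus_intercept")
    resid <- sweep(resid, 2L, coefs[1L, ], "+")
  values <- matrix(round_and_cap(resid, cap[1], cap[2]),
                   nrow(resid), ncol(resid), dimnames = dimnames(G$values))

  y <- ifelse(G$labels == positive_class, 1, -1)
  yres <- regress_residual(y, axes, mode)
  structure(list(sample_ids = G$sample_ids,
                 feature_ids = G$variant_ids,
                 values = values,
                 adjusted_phenotype = round_and_cap(yres, cap[1], cap[2]),
                 labels = G$labels,
                 variant_to_gene = G$variant_to_gene,
                 residuals = resid,
                 mode = mode,
                 positive_class = positive_class,
                 cap = cap),
            class = "adjusted_matrix")
}

#' Write axes scores and eigenvalues as TSV
#' @param axes an `axes_of_variation`
#' @param path output path
#' @export
write_axes_tsv <- function(axes, path) {
  dt <- data.table::data.table(sample_id = rownames(axes$scores))
  out <- cbind(dt, data.table::as.data.table(axes$scores))
  data.table::fwrite(out, path, sep = "\t")
  ev_path <- sub("(\\.tsv)?$", ".eigenvalues.tsv", path)
  data.table::fwrite(data.table::data.table(axis = seq_along(axes$eigenvalues),
                                            eigenvalue = axes$eigenvalues),
                     ev_path, sep = "\t")
  invisible(path)
}
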