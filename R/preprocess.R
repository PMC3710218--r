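#' Call expressed features
#'
#' Retains features with a non-missing fraction of at least `min_frac`
#' across samples (default 0.75, i.e. expression values for at least 75%
#' of the samples).
#'
#' @param e an [expression_matrix()].
#' @param min_frac minimum non-missing fraction in `(0, 1]`.
#' @return the filtered [expression_matrix()].
#' @export
call_expressed <- function(e, min_frac = 0.75) {
  stopifnot(inherits(e, "expression_matrix"))
  if (min_frac <= 0 || min_frac > 1) stop("min_frac must lie in (0, 1]")
  frac <- rowMeans(!is.na(e$values))
  keep <- frac >= min_frac
  message(sprintf("call_expressed: retained %d of %d features (min_frac = %g)",
                  sum(keep), length(keep), min_frac))
  if (!any(keep)) warning("no feature passes the expressed call")
  sig <- attr(e, "signal")
  out <- expression_matrix(e$values[keep, , drop = FALSE], e$kind)
  if (!is.null(sig)) attr(out, "signal") <- sig[, keep, drop = FALSE]
  out
}

#' Log2-transform expression values
#'
#' @param e an [expression_matrix()] on the raw intensity scale.
#' @param offset non-negative value added before taking logs.
#' @return the transformed [expression_matrix()]; missing stays missing.
#' @export
log2_transform <- function(e, offset = 0) {
  stopifnot(inherits(e, "expression_matrix"), offset >= 0)
  v <- e$values + offset
  bad <- which(!is.na(v) & v <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-positive value at feature '%s', sample '%s' (offset %g)",
                 rownames(e$values)[bad[1, 1]], colnames(e$values)[bad[1, 2]],
                 offset))
  expression_matrix(log2(v), e$kind)
}

#' Quantile-normalize an expression matrix across samples
#'
#' Every sample's sorted values are replaced by the across-sample mean of
#' order statistics; ranks within a sample are preserved, and tied values
#' receive the average of the reference values over their tied ranks. The
#' input must be fully observed.
#'
#' @param e an [expression_matrix()] without missing values.
#' @return the normalized [expression_matrix()].
#' @export
quantile_normalize <- function(e) {
  stopifnot(inherits(e, "expression_matrix"))
  if (anyNA(e$values))
    stop("quantile_normalize requires a fully observed matrix")
  x <- e$values  # features x samples; normalize each sample (column)
  ref <- rowMeans(apply(x, 2, sort))
  out <- apply(x, 2, function(col) {
    ord <- order(col)
    res <- numeric(length(col))
    sorted <- col[ord]
    # group tied runs in sorted order, average reference over the run
    runs <- rle(sorted)
    pos <- 1L
    for (len in runs$lengths) {
      idx <- pos:(pos + len - 1L)
      res[ord[idx]] <- mean(ref[idx])
      pos <- pos + len
    }
    res
  })
  dimnames(out) <- dimnames(x)
  expression_matrix(out, e$kind)
}

#' Exact test of Hardy-Weinberg equilibrium (Levene-Haldane)
#'
#' Conditional on the observed minor-allele count, heterozygote counts
#' follow the Levene-Haldane distribution under HWE. The two-sided p-value
#' sums the probabilities of all heterozygote counts whose probability does
#' not exceed that of the observed count. Monomorphic SNPs return p = 1 by
#' convention.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (reference homozygote,
#'   heterozygote, alternate homozygote).
#' @return the exact p-value in `(0, 1]`.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotype observation required")
  m <- 2 * min(n_AA, n_aa) + n_Aa  # minor allele count
  if (m == 0) return(1)
  probs <- .hwe_het_probs(n, m)
  h_obs <- n_Aa
  i_obs <- (h_obs - m %% 2) / 2 + 1
  p_obs <- probs[i_obs]
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

# Levene-Haldane pmf over heterozygote counts h with h == m (mod 2),
# h in [m %% 2, min(m, 2n - m)], given n individuals and minor count m
.hwe_het_probs <- function(n, m) {
  h <- seq(m %% 2, min(m, 2 * n - m), by = 2)
  n_aa <- (m - h) / 2
  n_AA <- n - n_aa - h
  logp <- lgamma(n + 1) - lgamma(n_AA + 1) - lgamma(h + 1) - lgamma(n_aa + 1) +
    h * log(2) + lgamma(m + 1) + lgamma(2 * n - m + 1) - lgamma(2 * n + 1)
  p <- exp(logp)
  p / sum(p)
}

#' Filter SNPs on minor allele frequency and Hardy-Weinberg equilibrium
#'
#' Retains SNPs with `maf > maf_min` (strict, an allele-frequency threshold
#' of >15% by default) and exact-test `hwe_p >= hwe_alpha`. SNPs with
#' undefined MAF (all calls missing) are dropped. `hwe_p` is computed from
#' the dosage hard-call counts where not already present.
#'
#' @param g a [genotype_matrix()] with `maf` computed.
#' @param maf_min MAF threshold (default 0.15, strict inequality).
#' @param hwe_alpha HWE exact-test significance cut (default 0.001).
#' @return the filtered [genotype_matrix()].
#' @export
filter_snps <- function(g, maf_min = 0.15, hwe_alpha = 0.001) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (all(is.na(g$snps$maf))) g <- compute_maf(g)
  if (any(is.na(g$snps$hwe_p))) {
    need <- which(is.na(g$snps$hwe_p))
    g$snps$hwe_p[need] <- vapply(need, function(j) {
      d <- g$dosage[, j]
      hwe_exact_test(sum(d == 0, na.rm = TRUE), sum(d == 1, na.rm = TRUE),
                     sum(d == 2, na.rm = TRUE))
    }, numeric(1))
  }
  maf_ok <- !is.na(g$snps$maf) & g$snps$maf > maf_min
  hwe_ok <- g$snps$hwe_p >= hwe_alpha
  keep <- maf_ok & hwe_ok
  message(sprintf(
    "filter_snps: %d of %d retained (%d failed maf > %g, %d failed HWE p >= %g)",
    sum(keep), length(keep), sum(!maf_ok), maf_min, sum(maf_ok & !hwe_ok),
    hwe_alpha))
  if (!any(keep)) warning("no SNP passes the filters")
  subset_genotypes(g, keep)
}

#' Subset a genotype matrix by SNP
#' @param g a [genotype_matrix()].
#' @param keep logical or integer index over SNPs.
#' @return the subsetted [genotype_matrix()].
#' @export
subset_genotypes <- function(g, keep) {
  g$dosage <- g$dosage[, keep, drop = FALSE]
  g$snps <- g$snps[keep, , drop = FALSE]
  rownames(g$snps) <- NULL
  g
}

#' Genotype principal components
#'
#' Top-`k` principal component scores of the sample x SNP dosage matrix
#' after per-SNP centering and unit-variance scaling. Missing dosages are
#' mean-imputed per SNP for this computation only; monomorphic SNPs are
#' dropped. Signs are fixed by making each component's largest-magnitude
#' SNP loading positive, so reruns are reproducible.
#'
#' @param g a [genotype_matrix()].
#' @param k number of components (default 3).
#' @return a [covariate_table()] with columns `PC1..PCk`.
#' @export
genotype_pcs <- function(g, k = 3) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- nrow(g$dosage)
  if (k >= n) stop("k must be smaller than the number of samples")
  x <- g$dosage
  mu <- colMeans(x, na.rm = TRUE)
  idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(idx) > 0) x[idx] <- mu[idx[, 2]]
  sds <- apply(x, 2, stats::sd)
  x <- x[, sds > 0, drop = FALSE]
  if (ncol(x) == 0) {
    scores <- matrix(0, n, k)
  } else {
    pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
    kk <- min(k, ncol(pc$x))
    scores <- matrix(0, n, k)
    for (c in seq_len(kk)) {
      load <- pc$rotation[, c]
      flip <- if (load[which.max(abs(load))] < 0) -1 else 1
      scores[, c] <- flip * pc$x[, c]
    }
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  covariate_table(g$sample_ids, as.data.frame(scores))
}

#' Remove hidden expression factors by PCA residualization
#'
#' Estimates `k` latent factors as the top-`k` principal components of the
#' feature-centered expression matrix (after regressing out any supplied
#' covariates) and returns per-feature residuals from regression on the
#' factor scores. Missing values are imputed to feature means for factor
#' estimation only and remain missing in the output. The per-feature
#' correlation between pre- and post-adjustment values is reported as a
#' diagnostic of how much structure was removed.
#'
#' @param e an [expression_matrix()].
#' @param k number of factors to remove (default 4); `k = 0` is the
#'   identity transform.
#' @param covariates optional [covariate_table()] regressed out before
#'   factor estimation.
#' @return list with `expr` (residualized [expression_matrix()]) and
#'   `adjustment`: `k`, `factor_scores` (samples x k), and
#'   `per_feature_correlation`.
#' @export
remove_hidden_factors <- function(e, k = 4, covariates = NULL) {
  stopifnot(inherits(e, "expression_matrix"), k >= 0)
  n <- ncol(e$values)
  if (k >= n) stop("k must be smaller than the number of samples")
  if (k == 0)
    return(list(expr = e,
                adjustment = list(k = 0L,
                                  factor_scores = matrix(numeric(0), n, 0),
                                  per_feature_correlation = numeric(0))))
  x <- e$values  # features x samples
  mu <- rowMeans(x, na.rm = TRUE)
  idx <- which(is.na(x), arr.ind = TRUE)
  ximp <- x
  if (nrow(idx) > 0) ximp[idx] <- mu[idx[, 1]]
  xc <- ximp - rowMeans(ximp)
  if (!is.null(covariates)) {
    C <- cbind(1, covariate_values(covariates))
    qc <- qr(C)
    xc <- t(qr.resid(qc, t(xc)))
  }
  sv <- La.svd(xc, nu = 0, nv = k)
  scores <- t(sv$vt)[, seq_len(k), drop = FALSE]  # samples x k, orthonormal
  # deterministic sign: largest-magnitude sample score positive
  for (c in seq_len(k)) {
    s <- scores[, c]
    if (s[which.max(abs(s))] < 0) scores[, c] <- -s
  }
  design <- cbind(1, scores)
  qd <- qr(design)
  resid <- x
  pfc <- numeric(nrow(x))
  for (j in seq_len(nrow(x))) {
    obs <- which(!is.na(x[j, ]))
    if (length(obs) > k + 1) {
      fit <- stats::lm.fit(design[obs, , drop = FALSE], x[j, obs])
      resid[j, obs] <- fit$residuals
    } else {
      resid[j, obs] <- x[j, obs] - mean(x[j, obs])
    }
    pfc[j] <- if (length(obs) > 2 && stats::sd(x[j, obs]) > 0 &&
                  stats::sd(resid[j, obs]) > 0)
      stats::cor(x[j, obs], resid[j, obs]) else NA_real_
  }
  rownames(scores) <- colnames(x)
  colnames(scores) <- paste0("F", seq_len(k))
  names(pfc) <- rownames(x)
  out <- expression_matrix(resid, e$kind)
  list(expr = out,
       adjustment = list(k = as.integer(k), factor_scores = scores,
                         per_feature_correlation = pfc))
}
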