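# Shared OLS scan kernel
#
# Regresses y on each column of X (plus intercept and optional covariates),
# complete-case per pair. One code path serves linear_assoc (single-column
# X) and eqtl_scan (genome-wide X), so per-pair results are identical by
# construction. With covariates and a fully observed X the slope and its
# standard error come from Frisch-Waugh residualization, which reproduces
# the full-model OLS quantities exactly; an X column with missing values is
# fitted by QR on its own complete cases.
.scan_block <- function(y, X, C = NULL) {
  X <- as.matrix(X)
  o <- which(!is.na(y))
  S <- ncol(X)
  out <- list(beta = rep(NA_real_, S), se = rep(NA_real_, S),
              t = rep(NA_real_, S), p = rep(NA_real_, S),
              n = rep(NA_integer_, S))
  if (length(o) < 3) return(out)
  y0 <- y[o]
  X0 <- X[o, , drop = FALSE]
  q <- 0L
  if (!is.null(C)) {
    C0 <- as.matrix(C)[o, , drop = FALSE]
    q <- ncol(C0)
    if (q == 0) { C <- NULL } else {
      qc <- qr(cbind(1, C0))
      if (anyNA(X0)) {
        # per-column complete-case fit with the full design
        for (j in seq_len(S)) {
          oo <- which(!is.na(X0[, j]))
          nj <- length(oo)
          if (nj < q + 3) next
          D <- cbind(1, C0[oo, , drop = FALSE], X0[oo, j])
          fit <- .ols_last(D, y0[oo])
          out$beta[j] <- fit$beta; out$se[j] <- fit$se
          out$t[j] <- fit$t; out$p[j] <- fit$p; out$n[j] <- nj
        }
        return(out)
      }
      y0 <- qr.resid(qc, y0)
      X0 <- qr.resid(qc, X0)
    }
  }
  M <- !is.na(X0)
  Xz <- X0
  Xz[!M] <- 0
  npair <- colSums(M)
  Sy <- colSums(M * y0)
  Syy <- colSums(M * y0^2)
  Sx <- colSums(Xz)
  Sxx <- colSums(Xz^2)
  Sxy <- colSums(Xz * y0)
  Sxx_c <- Sxx - Sx^2 / npair
  Sxy_c <- Sxy - Sx * Sy / npair
  Syy_c <- Syy - Sy^2 / npair
  df <- npair - 2 - q
  ok <- df >= 1 & Sxx_c > 1e-10
  beta <- ifelse(ok, Sxy_c / Sxx_c, NA_real_)
  SSE <- pmax(Syy_c - beta * Sxy_c, 0)
  se <- ifelse(ok, sqrt(SSE / df / Sxx_c), NA_real_)
  tt <- beta / se
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  p[ok & se == 0] <- 0
  p <- pmax(p, .Machine$double.xmin)
  p[!ok] <- NA_real_
  out$beta <- unname(beta); out$se <- unname(se); out$t <- unname(tt)
  out$p <- unname(p)
  out$n <- unname(ifelse(ok, as.integer(npair), NA_integer_))
  out
}

# OLS on design D, reporting the last coefficient
.ols_last <- function(D, yv) {
  qd <- qr(D)
  if (qd$rank < ncol(D))
    return(list(beta = NA_real_, se = NA_real_, t = NA_real_, p = NA_real_))
  coef <- qr.coef(qd, yv)
  res <- qr.resid(qd, yv)
  df <- length(yv) - ncol(D)
  s2 <- sum(res^2) / df
  R <- qr.R(qd)
  xtx_inv <- chol2inv(R)
  se <- sqrt(s2 * xtx_inv[ncol(D), ncol(D)])
  b <- coef[ncol(D)]
  if (se == 0) return(list(beta = b, se = 0, t = Inf,
                           p = .Machine$double.xmin))
  tt <- b / se
  p <- max(2 * stats::pt(abs(tt), df, lower.tail = FALSE),
           .Machine$double.xmin)
  list(beta = b, se = se, t = tt, p = p)
}

#' Single linear association test
#'
#' Ordinary least squares of `y` on an intercept, `x`, and optional
#' covariates, complete-case over observations where `x`, `y` and all
#' covariates are observed. Reports the slope on `x`, its standard error,
#' the t statistic, and the two-sided p-value from the t distribution.
#'
#' @param x numeric predictor (e.g. dosage or miRNA expression).
#' @param y numeric response.
#' @param covariates optional [covariate_table()] or numeric matrix aligned
#'   to `x`/`y`.
#' @param x_id,y_id identifiers recorded in the result.
#' @return one-row association-record data frame (`x_id`, `y_id`, `beta`,
#'   `se`, `t`, `p`, `n`, `q`); `beta`/`p` are `NA` when `x` is constant or
#'   too few complete cases remain.
#' @export
linear_assoc <- function(x, y, covariates = NULL, x_id = "x", y_id = "y") {
  stopifnot(length(x) == length(y))
  C <- NULL
  if (!is.null(covariates)) {
    C <- if (inherits(covariates, "covariate_table"))
      covariate_values(covariates) else as.matrix(covariates)
    stopifnot(nrow(C) == length(y))
  }
  # fold missing x into y's mask so the kernel's complete-case set matches
  r <- .scan_block(y, matrix(x, ncol = 1), C)
  data.frame(x_id = x_id, y_id = y_id, beta = r$beta, se = r$se, t = r$t,
             p = r$p, n = r$n, q = NA_real_, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjusted p-values: `q_i = min over j with p_(j) >= p_(i) of
#' m p_(j) / j`, capped at 1.
#'
#' @param p vector of p-values in `(0, 1]`.
#' @return vector of q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Scan all miRNA-mRNA pairs for expression association
#'
#' One simple regression of each mRNA on each miRNA over their complete
#' cases. Records are partitioned by the sign of the slope and
#' Benjamini-Hochberg q-values are computed within the negative-slope
#' partition (the direction expected of miRNA target repression); the
#' significant set is the negative-slope records with `q < fdr_alpha`.
#'
#' @param mirna miRNA [expression_matrix()] (predictors).
#' @param mrna mRNA [expression_matrix()] (responses).
#' @param fdr_alpha FDR level (default 0.05).
#' @param fdr_scope `"negative"` (default) computes q-values within the
#'   negative-slope partition; `"all"` computes family-wide q-values.
#' @return association-record data frame over all testable pairs, `x_id` =
#'   miRNA, `y_id` = mRNA, with `q` filled according to `fdr_scope`;
#'   attribute `"fdr_alpha"` records the level used.
#' @export
mirna_mrna_scan <- function(mirna, mrna, fdr_alpha = 0.05,
                            fdr_scope = c("negative", "all")) {
  stopifnot(inherits(mirna, "expression_matrix"),
            inherits(mrna, "expression_matrix"))
  fdr_scope <- match.arg(fdr_scope)
  shared <- intersect(mirna$sample_ids, mrna$sample_ids)
  if (length(shared) == 0) stop("no shared samples between the matrices")
  X <- t(mirna$values[, shared, drop = FALSE])  # n x P predictors
  Y <- t(mrna$values[, shared, drop = FALSE])   # n x Q responses
  res <- .pair_scan(X, Y)
  tab <- data.frame(
    x_id = rep(colnames(X), times = ncol(Y)),
    y_id = rep(colnames(Y), each = ncol(X)),
    beta = as.vector(res$beta), se = as.vector(res$se),
    t = as.vector(res$t), p = as.vector(res$p),
    n = as.vector(res$n), q = NA_real_, stringsAsFactors = FALSE)
  ok <- !is.na(tab$p)
  if (fdr_scope == "negative") {
    neg <- ok & tab$beta < 0
    if (any(neg)) tab$q[neg] <- bh_fdr(tab$p[neg])
  } else {
    if (any(ok)) tab$q[ok] <- bh_fdr(tab$p[ok])
  }
  attr(tab, "fdr_alpha") <- fdr_alpha
  tab
}

# all-pairs simple OLS via masked cross-products (pairwise complete cases)
.pair_scan <- function(X, Y) {
  Mx <- !is.na(X); My <- !is.na(Y)
  Xz <- X; Xz[!Mx] <- 0
  Yz <- Y; Yz[!My] <- 0
  storage.mode(Mx) <- "numeric"; storage.mode(My) <- "numeric"
  N <- crossprod(Mx, My)
  Sx <- crossprod(Xz, My)
  Sy <- crossprod(Mx, Yz)
  Sxx <- crossprod(Xz^2, My)
  Syy <- crossprod(Mx, Yz^2)
  Sxy <- crossprod(Xz, Yz)
  Sxx_c <- Sxx - Sx^2 / N
  Sxy_c <- Sxy - Sx * Sy / N
  Syy_c <- Syy - Sy^2 / N
  df <- N - 2
  ok <- df >= 1 & Sxx_c > 1e-10
  beta <- ifelse(ok, Sxy_c / Sxx_c, NA_real_)
  SSE <- pmax(Syy_c - beta * Sxy_c, 0)
  se <- ifelse(ok, sqrt(SSE / df / Sxx_c), NA_real_)
  tt <- beta / se
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  p[ok & se == 0] <- 0
  p <- pmax(p, .Machine$double.xmin)
  p[!ok] <- NA_real_
  n <- N; n[!ok] <- NA
  list(beta = beta, se = se, t = tt, p = p, n = n)
}

#' The significant negative-association subset of a pair scan
#' @param records output of [mirna_mrna_scan()].
#' @param fdr_alpha FDR level; defaults to the level recorded on `records`.
#' @return the subset of records with `beta < 0` and `q < fdr_alpha`.
#' @export
significant_negative <- function(records,
                                 fdr_alpha = attr(records, "fdr_alpha") %||% 0.05) {
  records[!is.na(records$q) & !is.na(records$beta) &
            records$beta < 0 & records$q < fdr_alpha, , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Genome-wide miR-eQTL scan
#'
#' Each miRNA, treated as a quantitative trait, is tested against every SNP
#' by linear regression. Covariates are screened per miRNA: each candidate
#' covariate is included only if its marginal regression on the miRNA
#' expression has `p < covariate_screen_alpha`. The genotype matrix is
#' expected to have passed [filter_snps()], and the expression matrix to be
#' hidden-factor residualized where configured.
#'
#' @param expr miRNA [expression_matrix()].
#' @param g a [genotype_matrix()].
#' @param covariates optional [covariate_table()] of candidate covariates.
#' @param covariate_screen_alpha inclusion threshold (default 0.05).
#' @return association-record data frame (`x_id` = SNP, `y_id` = miRNA)
#'   with a `covariates_used` attribute: a named list of the covariate
#'   names selected per miRNA.
#' @export
eqtl_scan <- function(expr, g, covariates = NULL,
                      covariate_screen_alpha = 0.05) {
  stopifnot(inherits(expr, "expression_matrix"), inherits(g, "genotype_matrix"))
  shared <- intersect(expr$sample_ids, g$sample_ids)
  if (length(shared) == 0) stop("no shared samples")
  E <- expr$values[, shared, drop = FALSE]
  D <- g$dosage[shared, , drop = FALSE]
  C <- NULL
  if (!is.null(covariates)) {
    stopifnot(inherits(covariates, "covariate_table"))
    C <- covariate_values(covariates)[match(shared, covariates$sample_id), ,
                                      drop = FALSE]
    if (anyNA(C)) stop("covariates missing for some shared samples")
  }
  used <- vector("list", nrow(E))
  names(used) <- rownames(E)
  tabs <- vector("list", nrow(E))
  for (i in seq_len(nrow(E))) {
    y <- E[i, ]
    sel <- NULL
    if (!is.null(C) && ncol(C) > 0) {
      keep <- logical(ncol(C))
      for (cc in seq_len(ncol(C))) {
        pr <- .scan_block(y, C[, cc, drop = FALSE], NULL)
        keep[cc] <- !is.na(pr$p) && pr$p < covariate_screen_alpha
      }
      if (any(keep)) sel <- C[, keep, drop = FALSE]
      used[[i]] <- colnames(C)[keep]
    } else {
      used[[i]] <- character(0)
    }
    r <- .scan_block(y, D, sel)
    tabs[[i]] <- data.frame(x_id = colnames(D), y_id = rownames(E)[i],
                            beta = r$beta, se = r$se, t = r$t, p = r$p,
                            n = r$n, q = NA_real_, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  skipped <- sum(is.na(out$p))
  if (skipped > 0)
    message("eqtl_scan: ", skipped, " SNP-miRNA pair(s) skipped (constant or too few cases)")
  attr(out, "covariates_used") <- used
  out
}

#' Bonferroni significance threshold for the eQTL scan
#'
#' `alpha / (n_snps * n_traits)`, the family-wise threshold over all
#' SNP-trait pairs. Fixed tiers (e.g. a suggestive `1e-8`) can be supplied
#' downstream instead.
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param n_snps,n_traits numbers of SNPs and expression traits tested.
#' @return the per-test threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_snps, n_traits) {
  if (n_snps < 1 || n_traits < 1) stop("counts must be >= 1")
  alpha / (n_snps * n_traits)
}

#' Effect-size summary over significant associations
#'
#' Mean and standard deviation of slopes over records passing `q < q_max`
#' and the sign restriction; the summary the global negative-regulation
#' effect distribution is judged by.
#'
#' @param records association-record data frame with `q` filled.
#' @param q_max FDR cut (default 0.05).
#' @param sign `"negative"` (default) restricts to `beta < 0`; `"all"`
#'   keeps both signs.
#' @return list with `mean`, `sd`, `n` (`mean`/`sd` are `NA` when `n = 0`).
#' @export
effect_size_summary <- function(records, q_max = 0.05,
                                sign = c("negative", "all")) {
  sign <- match.arg(sign)
  keep <- !is.na(records$q) & records$q < q_max & !is.na(records$beta)
  if (sign == "negative") keep <- keep & records$beta < 0
  b <- records$beta[keep]
  if (length(b) == 0) return(list(mean = NA_real_, sd = NA_real_, n = 0L))
  list(mean = mean(b), sd = stats::sd(b), n = length(b))
}
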