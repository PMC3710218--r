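#' Allele-frequency matched null SNP sets
#'
#' The MAF axis `[0, 0.5]` is cut into bins of `bin_width`; each of the `B`
#' null sets reproduces the query's per-bin counts exactly, drawing without
#' replacement (within a set) from pool SNPs in the same bin. Query SNPs
#' themselves are excluded from the pool by default, so a null set can
#' never trivially overlap the query.
#'
#' @param query character vector of query SNP ids.
#' @param pool data frame with `snp_id` and `maf` for every SNP eligible
#'   for matching (must contain the query).
#' @param B number of null sets (default 1000).
#' @param bin_width MAF bin width (default 0.05).
#' @param seed integer seed for reproducible draws.
#' @param include_query if `TRUE`, query SNPs stay in the sampling pool.
#' @return object of class `null_set_collection`: `query_ids`, `bin_edges`,
#'   `bin_profile`, `sets` (list of `B` character vectors), `seed`.
#' @export
maf_matched_null_sets <- function(query, pool, B = 1000, bin_width = 0.05,
                                  seed = 1L, include_query = FALSE) {
  stopifnot(is.data.frame(pool), all(c("snp_id", "maf") %in% names(pool)))
  query <- unique(as.character(query))
  miss <- setdiff(query, pool$snp_id)
  if (length(miss) > 0)
    stop("query SNP(s) absent from pool: ", paste(utils::head(miss, 3), collapse = ", "))
  qmaf <- pool$maf[match(query, pool$snp_id)]
  if (anyNA(qmaf)) stop("query SNP(s) with undefined maf")
  edges <- seq(0, 0.5, by = bin_width)
  if (edges[length(edges)] < 0.5) edges <- c(edges, 0.5)
  bin_of <- function(m) {
    b <- findInterval(m, edges, rightmost.closed = TRUE)
    pmin(b, length(edges) - 1L)
  }
  qbin <- bin_of(qmaf)
  profile <- tabulate(qbin, nbins = length(edges) - 1L)
  avail <- pool
  if (!include_query) avail <- pool[!(pool$snp_id %in% query), , drop = FALSE]
  avail <- avail[!is.na(avail$maf), , drop = FALSE]
  abin <- bin_of(avail$maf)
  bin_members <- split(avail$snp_id, factor(abin, levels = seq_len(length(edges) - 1L)))
  for (b in which(profile > 0)) {
    if (length(bin_members[[b]]) < profile[b])
      stop(sprintf(
        "bin [%.2f, %.2f) holds %d pool SNP(s) but the query needs %d; try a larger bin_width",
        edges[b], edges[b + 1], length(bin_members[[b]]), profile[b]))
  }
  set.seed(seed)
  occupied <- which(profile > 0)
  sets <- vector("list", B)
  for (i in seq_len(B)) {
    parts <- lapply(occupied, function(b) {
      mem <- bin_members[[b]]
      mem[sample.int(length(mem), profile[b])]
    })
    sets[[i]] <- unlist(parts, use.names = FALSE)
  }
  structure(list(query_ids = query, bin_edges = edges, bin_profile = profile,
                 sets = sets, seed = as.integer(seed),
                 bin_width = bin_width, include_query = include_query),
            class = "null_set_collection")
}

#' @export
print.null_set_collection <- function(x, ...) {
  cat(sprintf("null_set_collection: %d sets of %d SNPs, bin width %.2f\n",
              length(x$sets), length(x$query_ids), x$bin_width))
  invisible(x)
}

# empirical p with the matches-or-exceeds rule; optional +1 pseudocount
.empirical_p <- function(observed, null_values, pseudocount = FALSE) {
  B <- length(null_values)
  cnt <- sum(null_values >= observed)
  p <- if (pseudocount) (cnt + 1) / (B + 1) else cnt / B
  reported <- if (cnt == 0 && !pseudocount)
    sprintf("< %g", 1 / B) else format(p)
  list(p = p, reported = reported, B = B)
}

#' Overlap enrichment against MAF-matched null sets
#'
#' Observed statistic is the size of the query/target intersection; the
#' empirical p-value is the fraction of null sets whose overlap with the
#' target matches or exceeds it (a tie counts toward the numerator).
#'
#' @param query character vector of query SNP ids.
#' @param target character vector of target SNP ids.
#' @param nulls a [maf_matched_null_sets()] collection built for `query`.
#' @param pseudocount add-one smoothing of the empirical p (default off; a
#'   zero count is reported as `"< 1/B"`).
#' @return object of class `enrichment_result`: `observed`, `null_values`,
#'   `empirical_p`, `reported`, `B`.
#' @export
overlap_enrichment <- function(query, target, nulls, pseudocount = FALSE) {
  stopifnot(inherits(nulls, "null_set_collection"))
  target <- unique(as.character(target))
  observed <- length(intersect(query, target))
  null_values <- vapply(nulls$sets, function(s) sum(s %in% target), numeric(1))
  ep <- .empirical_p(observed, null_values, pseudocount)
  structure(list(observed = observed, null_values = null_values,
                 empirical_p = ep$p, reported = ep$reported, B = ep$B),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment: observed %g, null mean %.2f (B = %d), empirical p %s\n",
              x$observed, mean(x$null_values), x$B, x$reported))
  invisible(x)
}

#' Multi-miRNA targeting enrichment
#'
#' Statistic: the number of SNPs in a set associated (`p < p_max`) with at
#' least two distinct miRNAs. Compares the query against MAF-matched null
#' sets; with `statistic = "mean_targets"` the statistic is instead the
#' mean per-SNP count of associated miRNAs.
#'
#' @param query character vector of query SNP ids.
#' @param assoc association-record data frame from [eqtl_scan()] covering
#'   the pool SNPs.
#' @param p_max association threshold.
#' @param nulls a [maf_matched_null_sets()] collection built for `query`.
#' @param statistic `"multi_count"` (default) or `"mean_targets"`.
#' @return an `enrichment_result`.
#' @export
multi_target_enrichment <- function(query, assoc, p_max, nulls,
                                    statistic = c("multi_count", "mean_targets")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(nulls, "null_set_collection"))
  hits <- assoc[!is.na(assoc$p) & assoc$p < p_max, c("x_id", "y_id")]
  n_mirnas <- tapply(hits$y_id, hits$x_id, function(v) length(unique(v)))
  stat_of <- function(ids) {
    cnt <- n_mirnas[ids]
    cnt[is.na(cnt)] <- 0
    if (statistic == "multi_count") sum(cnt >= 2) else mean(cnt)
  }
  observed <- stat_of(query)
  null_values <- vapply(nulls$sets, stat_of, numeric(1))
  ep <- .empirical_p(observed, null_values)
  structure(list(observed = observed, null_values = null_values,
                 empirical_p = ep$p, reported = ep$reported, B = ep$B),
            class = "enrichment_result")
}

#' Gene-set regulation test
#'
#' Tests whether a focal gene set (e.g. pharmacogenes) is under stronger
#' negative miRNA regulation than random gene sets of the same size. Each
#' universe gene is summarized by its best (smallest) negative-association
#' p-value; the observed statistic is the median of the focal genes' best
#' p-values, and the null distribution consists of medians from `B` random
#' same-size gene sets. The empirical p-value is the fraction of null
#' medians less than or equal to the observed one (a smaller median means
#' stronger regulation). When the number of possible subsets is at most
#' `enumeration_limit`, all subsets are enumerated instead of sampled.
#'
#' @param assoc association-record data frame from [mirna_mrna_scan()]
#'   (`y_id` = gene).
#' @param focal_genes character vector, a subset of `universe`.
#' @param universe character vector of eligible gene ids.
#' @param B number of random sets (default 1000).
#' @param seed integer seed.
#' @param exclude_focal draw null sets from the universe excluding the
#'   focal genes (default `TRUE`).
#' @param statistic `"best_p"` (default): per-gene best negative p;
#'   `"all_pairs"`: the median over all negative-pair p-values of the set.
#' @param enumeration_limit switch to exhaustive enumeration when
#'   `choose(pool, set size)` is at most this (default 1e4).
#' @return object of class `geneset_test_result`: `focal_best_p`,
#'   `observed_median`, `null_medians`, `empirical_p`, `reported`,
#'   `qq_pairs` (data frame of observed/expected -log10 quantiles),
#'   `n_excluded` (genes with no tested negative association), `B`,
#'   `enumerated`.
#' @export
geneset_regulation_test <- function(assoc, focal_genes, universe, B = 1000,
                                    seed = 1L, exclude_focal = TRUE,
                                    statistic = c("best_p", "all_pairs"),
                                    enumeration_limit = 1e4) {
  statistic <- match.arg(statistic)
  focal_genes <- unique(as.character(focal_genes))
  universe <- unique(as.character(universe))
  if (!all(focal_genes %in% universe))
    stop("focal genes must be a subset of the universe")
  if (length(focal_genes) > length(universe))
    stop("focal set larger than universe")
  neg <- assoc[!is.na(assoc$p) & !is.na(assoc$beta) & assoc$beta < 0, ,
               drop = FALSE]
  neg <- neg[neg$y_id %in% universe, , drop = FALSE]
  best_p <- tapply(neg$p, neg$y_id, min)
  all_p <- split(neg$p, neg$y_id)
  tested <- names(best_p)
  n_excluded <- sum(!(universe %in% tested))
  if (n_excluded > 0)
    message("geneset_regulation_test: ", n_excluded,
            " universe gene(s) with no tested negative association excluded")
  focal_av <- intersect(focal_genes, tested)
  if (length(focal_av) == 0) stop("no focal gene has a tested negative association")
  set_stat <- if (statistic == "best_p") {
    function(genes) stats::median(best_p[genes])
  } else {
    function(genes) stats::median(unlist(all_p[genes], use.names = FALSE))
  }
  observed_median <- set_stat(focal_av)
  pool <- if (exclude_focal) setdiff(tested, focal_genes) else tested
  k <- length(focal_av)
  if (length(pool) < k) stop("null pool smaller than the focal set")
  n_subsets <- suppressWarnings(choose(length(pool), k))
  enumerated <- is.finite(n_subsets) && n_subsets <= enumeration_limit
  sorted_null_sum <- numeric(k)
  if (enumerated) {
    combos <- utils::combn(pool, k)
    null_medians <- apply(combos, 2, set_stat)
    if (statistic == "best_p")
      for (j in seq_len(ncol(combos)))
        sorted_null_sum <- sorted_null_sum + sort(best_p[combos[, j]])
    Bdraws <- ncol(combos)
  } else {
    set.seed(seed)
    null_medians <- numeric(B)
    for (i in seq_len(B)) {
      g <- pool[sample.int(length(pool), k)]
      null_medians[i] <- set_stat(g)
      if (statistic == "best_p")
        sorted_null_sum <- sorted_null_sum + sort(best_p[g])
    }
    Bdraws <- B
  }
  cnt <- sum(null_medians <= observed_median)
  empirical_p <- cnt / Bdraws
  reported <- if (cnt == 0) sprintf("< %g", 1 / Bdraws) else format(empirical_p)
  qq_pairs <- if (statistic == "best_p") {
    data.frame(observed = -log10(sort(best_p[focal_av], decreasing = TRUE)),
               expected = -log10(rev(sorted_null_sum / Bdraws)))
  } else NULL
  structure(list(focal_best_p = best_p[focal_av],
                 observed_median = observed_median,
                 null_medians = null_medians, empirical_p = empirical_p,
                 reported = reported, qq_pairs = qq_pairs,
                 n_excluded = n_excluded, B = Bdraws,
                 enumerated = enumerated),
            class = "geneset_test_result")
}

#' @export
print.geneset_test_result <- function(x, ...) {
  cat(sprintf(
    "gene-set regulation test: median best p %.3g over %d genes, empirical p %s (B = %d%s)\n",
    x$observed_median, length(x$focal_best_p), x$reported, x$B,
    if (x$enumerated) ", enumerated" else ""))
  invisible(x)
}

#' Quantile-quantile curve for association p-values
#'
#' Sorted observed p-values paired against either uniform expected
#' quantiles `(i - 0.5) / m` or the sorted mean-order-statistic curve of
#' supplied null p-value vectors, on the -log10 scale.
#'
#' @param observed_p vector of p-values.
#' @param expected `"uniform"` or a matrix/list of null p-value vectors
#'   (each the same length as `observed_p`).
#' @return data frame with columns `expected` and `observed` (-log10
#'   scale), ascending in `expected`.
#' @export
qq_curve <- function(observed_p, expected = "uniform") {
  if (length(observed_p) == 0) stop("observed_p must be non-empty")
  if (any(observed_p == 0)) {
    warning("p = 0 entries clamped to the smallest representable positive")
    observed_p[observed_p == 0] <- .Machine$double.xmin
  }
  m <- length(observed_p)
  obs <- sort(observed_p, decreasing = TRUE)
  if (identical(expected, "uniform")) {
    exp_q <- rev((seq_len(m) - 0.5) / m)
  } else {
    if (is.list(expected)) expected <- do.call(cbind, expected)
    expected <- as.matrix(expected)
    if (nrow(expected) != m) stop("null vectors must match observed length")
    exp_q <- rev(rowMeans(apply(expected, 2, sort)))
  }
  data.frame(expected = -log10(exp_q), observed = -log10(obs))
}

#' Tail-proportion test for large negative effects
#'
#' Proportion of focal genes whose best negative effect lies below
#' `beta_cut`, tested one-sided against the genome-wide background
#' proportion by the exact binomial tail.
#'
#' @param focal_betas best (most negative) slope per focal gene.
#' @param beta_cut effect cut (default -4).
#' @param background_prop genome-wide background proportion (default 0.05).
#' @return list with `n_below`, `n`, `proportion`, `p` (one-sided exact).
#' @export
tail_proportion_test <- function(focal_betas, beta_cut = -4,
                                 background_prop = 0.05) {
  if (length(focal_betas) == 0) stop("focal_betas must be non-empty")
  k <- sum(focal_betas < beta_cut)
  n <- length(focal_betas)
  p <- stats::pbinom(k - 1, n, background_prop, lower.tail = FALSE)
  list(n_below = k, n = n, proportion = k / n, p = p)
}

#' Group effect-size comparison (Welch t-test)
#'
#' One-sided Welch two-sample t-test of whether records whose miRNA belongs
#' to `member_mirnas` have larger absolute slopes than the remaining
#' records.
#'
#' @param assoc significant negative association-record data frame.
#' @param member_mirnas character vector of miRNA ids forming the group.
#' @return list with `t`, `df`, `p`, `mean_member`, `mean_other`, group
#'   sizes; `t`/`p` are `NA` when either group has fewer than two records.
#' @export
group_effectsize_test <- function(assoc, member_mirnas) {
  in_grp <- assoc$x_id %in% member_mirnas
  a <- abs(assoc$beta[in_grp & !is.na(assoc$beta)])
  b <- abs(assoc$beta[!in_grp & !is.na(assoc$beta)])
  if (length(a) < 2 || length(b) < 2) {
    message("group_effectsize_test: a group has fewer than 2 records; undefined")
    return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                mean_member = mean(a), mean_other = mean(b),
                n_member = length(a), n_other = length(b)))
  }
  ht <- stats::t.test(a, b, alternative = "greater", var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_member = mean(a), mean_other = mean(b),
       n_member = length(a), n_other = length(b))
}

#' Sign-balance test for risk-allele effect directions
#'
#' Two-sided exact binomial test of whether risk-allele-oriented effect
#' directions are balanced around one half (no tendency of the risk allele
#' to associate with lower or higher expression). Zeros are excluded.
#'
#' @param directions vector of signed effects or directions.
#' @return the two-sided exact binomial p-value.
#' @export
sign_balance_test <- function(directions) {
  directions <- directions[!is.na(directions) & directions != 0]
  if (length(directions) == 0) stop("no non-zero directions supplied")
  stats::binom.test(sum(directions > 0), length(directions),
                    p = 0.5, alternative = "two.sided")$p.value
}
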