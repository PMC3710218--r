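make_pool <- function(n = 500, seed = 1) {
  set.seed(seed)
  data.frame(snp_id = sprintf("s%04d", seq_len(n)),
             maf = runif(n, 0.05, 0.5), stringsAsFactors = FALSE)
}

test_that("null sets reproduce the query's per-bin MAF profile exactly", {
  pool <- make_pool(500)
  query <- pool$snp_id[c(5, 50, 100, 200, 300)]
  nulls <- maf_matched_null_sets(query, pool, B = 200, seed = 3)
  bin_of <- function(m) pmin(findInterval(m, nulls$bin_edges,
                                          rightmost.closed = TRUE),
                             length(nulls$bin_edges) - 1L)
  for (s in nulls$sets) {
    prof <- tabulate(bin_of(pool$maf[match(s, pool$snp_id)]),
                     nbins = length(nulls$bin_edges) - 1L)
    expect_identical(prof, nulls$bin_profile)
    expect_false(any(s %in% query))        # exclusion by default
    expect_false(anyDuplicated(s) > 0)     # without replacement within a set
  }
  # seed fixes the whole collection
  nulls2 <- maf_matched_null_sets(query, pool, B = 200, seed = 3)
  expect_identical(nulls$sets, nulls2$sets)
})

test_that("specific-bin matching: mafs {0.21, 0.43} occupy their own bins", {
  pool <- data.frame(snp_id = paste0("s", 1:40),
                     maf = c(0.21, 0.43, rep(c(0.22, 0.44), 19)),
                     stringsAsFactors = FALSE)
  nulls <- maf_matched_null_sets(c("s1", "s2"), pool, B = 25, seed = 1)
  for (s in nulls$sets) {
    m <- sort(pool$maf[match(s, pool$snp_id)])
    expect_true(m[1] >= 0.20 && m[1] < 0.25)
    expect_true(m[2] >= 0.40 && m[2] < 0.45)
  }
})

test_that("an under-populated bin raises an informative error", {
  pool <- data.frame(snp_id = c("q1", "other"), maf = c(0.12, 0.31),
                     stringsAsFactors = FALSE)
  expect_error(maf_matched_null_sets("q1", pool, B = 5, seed = 1),
               "bin_width")
  # restoring the query to the pool resolves it
  nulls <- maf_matched_null_sets("q1", pool, B = 5, seed = 1,
                                 include_query = TRUE)
  expect_true(all(vapply(nulls$sets, identical, logical(1), "q1")))
})

test_that("overlap enrichment applies the matches-or-exceeds rule", {
  pool <- make_pool(2000)
  query <- sample(pool$snp_id, 50)
  nulls <- maf_matched_null_sets(query, pool, B = 1000, seed = 7)
  # constructed case: observed 10 with 49 of 1000 nulls >= 10 -> p = 0.049
  fake <- nulls
  fake$sets <- c(lapply(1:49, function(i) pool$snp_id[1:15]),
                 lapply(1:951, function(i) pool$snp_id[1600:1604]))
  target <- c(query[1:10], pool$snp_id[1:15])
  res <- overlap_enrichment(query, target, fake)
  expect_equal(res$observed, 10)
  expect_equal(res$empirical_p, 0.049)
  # ties count toward the numerator: 5 of 10 sets tie the observed overlap
  fake$sets <- c(lapply(1:5, function(i) query[1:10]),
                 lapply(1:5, function(i) setdiff(pool$snp_id, query)[1:3]))
  res_tie <- overlap_enrichment(query, query[1:10], fake)
  expect_equal(res_tie$observed, 10)
  expect_equal(res_tie$empirical_p, 0.5)
  # disjoint target
  res0 <- overlap_enrichment(query, c("zz1", "zz2"), nulls)
  expect_equal(res0$observed, 0)
  expect_equal(res0$empirical_p, 1)
  # target = query: maximal observed, no null can tie under exclusion
  res_self <- overlap_enrichment(query, query, nulls)
  expect_equal(res_self$observed, 50)
  expect_equal(res_self$empirical_p, 0)
  expect_match(res_self$reported, "^< ")
})

test_that("multi-target enrichment counts SNPs with >= 2 associated miRNAs", {
  pool <- make_pool(200)
  assoc <- rbind(
    make_assoc(rep("s0001", 3), c("mA", "mB", "mC"), beta = -1, p = 1e-6),
    make_assoc("s0002", "mA", beta = -1, p = 1e-6),
    make_assoc(rep("s0003", 2), c("mA", "mA"), beta = -1, p = 1e-6),
    make_assoc("s0004", "mB", beta = -1, p = 0.5))
  nulls <- maf_matched_null_sets(c("s0001", "s0002"), pool, B = 10, seed = 2)
  res <- multi_target_enrichment(c("s0001", "s0002"), assoc, 1e-4, nulls)
  expect_equal(res$observed, 1)  # s0001 has 3 distinct miRNAs; s0002 one;
                                 # s0003's duplicate miRNA does not count
  res0 <- multi_target_enrichment(c("s0001", "s0002"), assoc, 0, nulls)
  expect_equal(res0$observed, 0)
  expect_equal(res0$empirical_p, 1)
})

test_that("gene-set test matches exhaustive enumeration on small universes", {
  set.seed(12)
  universe <- paste0("g", 1:6)
  assoc <- make_assoc(x_id = rep("m1", 6), y_id = universe,
                      beta = -1, p = c(0.01, 0.2, 0.4, 0.6, 0.8, 0.9))
  focal <- c("g1", "g2")
  # independent oracle: enumerate all 15 same-size subsets of the universe
  best_p <- c(0.01, 0.2, 0.4, 0.6, 0.8, 0.9)
  names(best_p) <- universe
  combos <- combn(universe, 2)
  null_meds <- apply(combos, 2, function(gs) median(best_p[gs]))
  obs <- median(best_p[focal])
  p_incl <- mean(null_meds <= obs)
  res_incl <- geneset_regulation_test(assoc, focal, universe,
                                      exclude_focal = FALSE)
  expect_true(res_incl$enumerated)
  expect_equal(res_incl$B, 15)
  expect_equal(res_incl$empirical_p, p_incl)
  # default excludes the focal genes from the null pool: C(4, 2) = 6 subsets
  combos_ex <- combn(setdiff(universe, focal), 2)
  p_ex <- mean(apply(combos_ex, 2, function(gs) median(best_p[gs])) <= obs)
  res_ex <- geneset_regulation_test(assoc, focal, universe)
  expect_equal(res_ex$B, 6)
  expect_equal(res_ex$empirical_p, p_ex)
  # sampling converges to the enumerated value
  res_samp <- geneset_regulation_test(assoc, focal, universe, B = 2000,
                                      seed = 4, exclude_focal = FALSE,
                                      enumeration_limit = 0)
  tol <- 3 * sqrt(p_incl * (1 - p_incl) / 2000)
  expect_lt(abs(res_samp$empirical_p - p_incl), tol)
})

test_that("gene-set test flags planted regulation and validates input", {
  set.seed(30)
  universe <- paste0("g", 1:300)
  focal <- paste0("g", 1:20)
  p <- runif(300, 0.01, 1)
  p[1:20] <- 1e-8  # strong planted signal on the focal set
  assoc <- make_assoc(rep("m1", 300), universe, beta = -1, p = p)
  res <- geneset_regulation_test(assoc, focal, universe, B = 500, seed = 2)
  expect_equal(res$empirical_p, 0)
  expect_match(res$reported, "^< ")
  expect_equal(nrow(res$qq_pairs), 20)
  # the planted set's observed curve dominates the expected curve
  expect_true(all(res$qq_pairs$observed >= res$qq_pairs$expected))
  expect_error(geneset_regulation_test(assoc, "absent", universe), "subset")
  # genes with positive slopes only are excluded with a message
  assoc2 <- assoc
  assoc2$beta[21] <- 1
  expect_message(geneset_regulation_test(assoc2, focal, universe, B = 50,
                                         seed = 1),
                 "excluded")
})

test_that("qq curve uses (i - 0.5)/m expected quantiles and flags signal", {
  obs <- (seq_len(100) - 0.5) / 100
  qq <- qq_curve(obs)
  expect_equal(qq$observed, qq$expected, tolerance = 1e-12)
  qq1 <- qq_curve(0.5)
  expect_equal(qq1$expected, -log10(0.5))
  # supplied null vectors define the expected curve
  nulls <- cbind(c(0.1, 0.5, 0.9), c(0.3, 0.7, 0.5))
  qq2 <- qq_curve(c(0.2, 0.4, 0.6), expected = nulls)
  # mean order statistics (0.2, 0.5, 0.8) paired largest-p-first
  expect_equal(qq2$expected, -log10(c(0.8, 0.5, 0.2)))
  expect_equal(qq2$observed, -log10(c(0.6, 0.4, 0.2)))
  expect_warning(qq_curve(c(0, 0.5)), "clamped")
  # planted signal lifts the top of the curve above the diagonal
  set.seed(3)
  p <- c(runif(900), rexp(100, 50))
  qq3 <- qq_curve(p)
  top <- qq3[order(qq3$expected, decreasing = TRUE)[1:100], ]
  n_above <- sum(top$observed > top$expected)
  expect_lt(stats::binom.test(n_above, 100,
                              alternative = "greater")$p.value, 0.01)
})

test_that("tail-proportion test computes exact binomial tails", {
  set.seed(2)
  betas <- rnorm(41, -2, 1)
  cut12 <- sort(betas)[12] + 1e-9  # force exactly 12 below the cut
  res <- tail_proportion_test(betas, beta_cut = cut12)
  expect_equal(res$n_below, 12)
  expect_equal(res$p, sum(dbinom(12:41, 41, 0.05)), tolerance = 1e-12)
  expect_equal(res$p,
               stats::binom.test(12, 41, 0.05,
                                 alternative = "greater")$p.value,
               tolerance = 1e-12)
  expect_equal(tail_proportion_test(rep(-1, 41))$p, 1)
  expect_equal(tail_proportion_test(rep(-5, 41))$p, 0.05^41)
})

test_that("group effect-size test is a one-sided Welch comparison", {
  assoc <- make_assoc(c("mA", "mA", "mB", "mB", "mB"),
                      paste0("g", 1:5),
                      beta = c(-5, -6, -1, -1.1, -0.9), p = 1e-4)
  res <- group_effectsize_test(assoc, "mA")
  ref <- oracle_welch_greater(c(5, 6), c(1, 1.1, 0.9))
  expect_equal(res$t, ref$t, tolerance = 1e-12)
  expect_equal(res$df, ref$df, tolerance = 1e-12)
  expect_equal(res$p, ref$p, tolerance = 1e-12)
  # under-sized group -> undefined with message
  expect_message(res1 <- group_effectsize_test(assoc, "zz"), "fewer")
  expect_true(is.na(res1$p))
  # identical groups give p near 0.5 on average
  set.seed(11)
  ps <- replicate(200, {
    a <- make_assoc(c(rep("mA", 20), rep("mB", 20)), paste0("g", 1:40),
                    beta = -abs(rnorm(40)), p = 1e-4)
    group_effectsize_test(a, "mA")$p
  })
  expect_lt(abs(mean(ps) - 0.5), 0.1)
  # planted |beta| shift detected
  power <- replicate(100, {
    a <- make_assoc(c(rep("mA", 50), rep("mB", 50)), paste0("g", 1:100),
                    beta = c(-abs(rnorm(50, 2, 1)), -abs(rnorm(50, 1, 1))),
                    p = 1e-4)
    group_effectsize_test(a, "mA")$p < 0.05
  })
  expect_gte(mean(power), 0.9)
})

test_that("sign-balance test matches exact binomial arithmetic", {
  expect_equal(sign_balance_test(c(rep(1, 5), rep(-1, 5))), 1)
  expect_equal(sign_balance_test(rep(1, 10)), 2 * 0.5^10, tolerance = 1e-12)
  expect_equal(sign_balance_test(1), 1)
  expect_equal(sign_balance_test(c(1, -1, 0, 0)), 1)  # zeros excluded
  expect_error(sign_balance_test(c(0, 0)), "non-zero")
})

test_that("enlarging a planted overlap never weakens median enrichment", {
  pool <- make_pool(2000, seed = 5)
  target <- pool$snp_id[1:200]
  med_p <- vapply(c(0, 0.2, 0.4), function(frac) {
    ps <- vapply(1:20, function(r) {
      set.seed(1000 + r)
      n_in <- round(50 * frac)
      query <- c(sample(target, n_in),
                 sample(setdiff(pool$snp_id, target), 50 - n_in))
      nulls <- maf_matched_null_sets(query, pool, B = 100, seed = r)
      overlap_enrichment(query, target, nulls)$empirical_p
    }, numeric(1))
    median(ps)
  }, numeric(1))
  expect_true(all(diff(med_p) <= 0))
})
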