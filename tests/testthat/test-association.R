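test_that("linear_assoc reproduces the hand-worked example and closed-form OLS", {
  r <- linear_assoc(c(0, 0, 1, 1, 2, 2), c(0, 0.2, 1, 1.2, 2, 2.2))
  # SSE = 0.06 on 4 df, Sxx = 4 -> se = sqrt(0.015/4)
  expect_equal(r$beta, 1.0, tolerance = 1e-12)
  expect_equal(r$se, sqrt(0.00375), tolerance = 1e-12)
  expect_equal(r$n, 6L)
  set.seed(10)
  for (i in 1:200) {
    n <- sample(5:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    mine <- linear_assoc(x, y)
    ref <- oracle_ols(x, y)
    expect_equal(mine$beta, ref$beta, tolerance = 1e-10)
    expect_equal(mine$se, ref$se, tolerance = 1e-10)
    expect_equal(mine$p, ref$p, tolerance = 1e-10)
  }
})

test_that("linear_assoc handles perfect fits, constant x, and covariates", {
  x <- c(0, 1, 2, 0, 1, 2)
  r <- linear_assoc(x, x)
  expect_equal(r$beta, 1)
  expect_gt(r$p, 0)
  expect_lte(r$p, 1e-300)
  rc <- linear_assoc(rep(1, 6), rnorm(6))
  expect_true(is.na(rc$beta) && is.na(rc$p))
  # covariate-adjusted slope equals lm()
  set.seed(3)
  n <- 50
  z <- rnorm(n); x2 <- rnorm(n) + z; y2 <- 0.5 * x2 + z + rnorm(n)
  ct <- covariate_table(paste0("S", 1:n), z = z)
  mine <- linear_assoc(x2, y2, ct)
  ref <- summary(stats::lm(y2 ~ x2 + z))$coefficients["x2", ]
  expect_equal(mine$beta, unname(ref["Estimate"]), tolerance = 1e-10)
  expect_equal(mine$se, unname(ref["Std. Error"]), tolerance = 1e-10)
  expect_equal(mine$p, unname(ref["Pr(>|t|)"]), tolerance = 1e-10)
  # missing x handled per complete cases
  x3 <- x2; x3[1:5] <- NA
  mine3 <- linear_assoc(x3, y2, ct)
  ref3 <- summary(stats::lm(y2 ~ x3 + z))$coefficients["x3", ]
  expect_equal(mine3$beta, unname(ref3["Estimate"]), tolerance = 1e-10)
  expect_equal(mine3$se, unname(ref3["Std. Error"]), tolerance = 1e-10)
  expect_equal(mine3$n, n - 5L)
})

test_that("bh_fdr reproduces the step-up recursion and validates input", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(c(1, 1)), c(1, 1))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  set.seed(5)
  for (i in 1:50) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("pair scan agrees with per-pair regression under missingness", {
  co <- small_cohort(seed = 19)
  tab <- mirna_mrna_scan(co$mirna, co$mrna)
  expect_equal(nrow(tab), 30 * 100)
  set.seed(1)
  pick <- sample(nrow(tab), 40)
  for (i in pick) {
    x <- co$mirna$values[tab$x_id[i], ]
    y <- co$mrna$values[tab$y_id[i], ]
    ref <- linear_assoc(x, y)
    expect_equal(tab$beta[i], ref$beta, tolerance = 1e-10)
    expect_equal(tab$p[i], ref$p, tolerance = 1e-10)
    expect_equal(tab$n[i], ref$n)
  }
  # q-values live only on the negative partition; positive slopes never enter
  sig <- significant_negative(tab)
  expect_true(all(sig$beta < 0))
  expect_true(all(is.na(tab$q[!is.na(tab$beta) & tab$beta >= 0])))
  # family-wide scope fills every defined record
  tab_all <- mirna_mrna_scan(co$mirna, co$mrna, fdr_scope = "all")
  expect_false(anyNA(tab_all$q[!is.na(tab_all$p)]))
})

test_that("planted strongly negative pairs are recovered by the scan", {
  hits <- logical(10)
  for (r in seq_len(10)) {
    cfg <- sim_config(n_samples = 79, n_snps = 10, n_mirnas = 20, n_mrnas = 50,
                      n_planted_eqtls = 0, n_planted_regulations = 5,
                      regulation_beta_sampler = function(n) rep(-2, n),
                      n_hidden_factors = 0, noise_sd = 0.5,
                      missingness_rate = 0, n_catalog = 0, seed = 300 + r)
    g <- simulate_genotypes(cfg)
    mi <- simulate_mirnas(g, cfg)
    mr <- simulate_mrnas(mi$expr, cfg)
    tab <- mirna_mrna_scan(mi$expr, mr$expr)
    sig <- significant_negative(tab)
    pl <- mr$truth$planted_regulations
    hits[r] <- all(paste(pl$mirna_id, pl$mrna_id) %in%
                     paste(sig$x_id, sig$y_id))
  }
  expect_true(all(hits))
})

test_that("eqtl_scan equals linear_assoc pairwise, bitwise", {
  co <- small_cohort(seed = 23)
  suppressMessages(gf <- filter_snps(co$genotypes))
  es <- eqtl_scan(co$mirna, gf)
  set.seed(2)
  for (i in sample(nrow(es), 25)) {
    ref <- linear_assoc(gf$dosage[, es$x_id[i]],
                        co$mirna$values[es$y_id[i], ])
    expect_identical(es$beta[i], ref$beta)
    expect_identical(es$se[i], ref$se)
    expect_identical(es$p[i], ref$p)
  }
})

test_that("covariate screening includes real covariates and excludes null ones", {
  set.seed(9)
  n <- 120
  age <- rnorm(n, 50, 10)
  junk <- rnorm(n)
  vals <- matrix(rnorm(60 * n), 60, n,
                 dimnames = list(sprintf("m%02d", 1:60), paste0("S", 1:n)))
  vals <- sweep(vals, 2, 0.08 * age, "+")  # age affects every miRNA
  e <- expression_matrix(vals, "miRNA")
  dos <- matrix(rbinom(n * 30, 2, 0.3), n, 30)
  snps <- data.frame(snp_id = paste0("s", 1:30), chrom = "chr1", pos = 1:30,
                     ref_allele = "A", alt_allele = "G",
                     stringsAsFactors = FALSE)
  g <- compute_maf(genotype_matrix(dos, snps,
                                   sample_ids = paste0("S", 1:n)))
  ct <- covariate_table(paste0("S", 1:n), age = age, junk = junk)
  es <- eqtl_scan(e, g, ct)
  used <- attr(es, "covariates_used")
  age_rate <- mean(vapply(used, function(u) "age" %in% u, logical(1)))
  junk_rate <- mean(vapply(used, function(u) "junk" %in% u, logical(1)))
  expect_gt(age_rate, 0.9)
  expect_lt(junk_rate, 0.2)  # ~5% expected under the null screen
  # adjusted slope matches lm with the selected covariate
  mir <- names(used)[vapply(used, function(u) identical(u, "age"), logical(1))][1]
  expect_false(is.na(mir))  # the fixed seed yields age-only selections
  row <- es[es$y_id == mir & es$x_id == "s1", ]
  ref <- summary(stats::lm(e$values[mir, ] ~ dos[, 1] + age))$coefficients[2, ]
  expect_equal(row$beta, unname(ref["Estimate"]), tolerance = 1e-10)
  expect_equal(row$p, unname(ref["Pr(>|t|)"]), tolerance = 1e-10)
})

test_that("permuting sample labels destroys planted eQTL associations", {
  cfg <- sim_config(n_samples = 150, n_snps = 100, n_mirnas = 10,
                    n_planted_eqtls = 5,
                    eqtl_beta_sampler = function(n) rep(1.5, n),
                    maf_spectrum = function(n) runif(n, 0.2, 0.5),
                    n_hidden_factors = 0, missingness_rate = 0,
                    n_mrnas = 1, n_planted_regulations = 0, n_catalog = 0,
                    seed = 31)
  g <- simulate_genotypes(cfg)
  m <- simulate_mirnas(g, cfg)
  es <- eqtl_scan(m$expr, g)
  key <- paste(es$x_id, es$y_id)
  planted_key <- paste(m$truth$planted_eqtls$snp_id,
                       m$truth$planted_eqtls$mirna_id)
  p_planted <- es$p[match(planted_key, key)]
  expect_lt(max(p_planted), 1e-8)
  set.seed(99)
  perm <- m$expr
  perm$values <- perm$values[, sample(ncol(perm$values))]
  colnames(perm$values) <- m$expr$sample_ids
  perm <- expression_matrix(perm$values, "miRNA")
  esp <- eqtl_scan(perm, g)
  p_perm <- esp$p[match(planted_key, paste(esp$x_id, esp$y_id))]
  expect_gt(min(p_perm), 1e-4)  # back in the null range for 100x10 tests
})

test_that("bonferroni threshold arithmetic and validation", {
  expect_equal(bonferroni_threshold(0.05, 1000, 10), 5e-6)
  expect_equal(bonferroni_threshold(0.05, 1, 1), 0.05)
  expect_error(bonferroni_threshold(0.05, 0, 10), ">= 1")
})

test_that("effect-size summary restricts by q and sign", {
  rec <- make_assoc(paste0("m", 1:4), paste0("g", 1:4),
                    beta = c(-1, -2, -3, 2), p = rep(0.001, 4),
                    q = c(0.01, 0.01, 0.01, 0.01))
  s <- effect_size_summary(rec)
  expect_equal(s$mean, -2)
  expect_equal(s$sd, 1)
  expect_equal(s$n, 3L)
  s_all <- effect_size_summary(rec, sign = "all")
  expect_equal(s_all$n, 4L)
  s_none <- effect_size_summary(rec, q_max = 0.001)
  expect_equal(s_none$n, 0L)
  expect_true(is.na(s_none$mean))
})

test_that("recovered effect distribution matches truncated-normal moments", {
  means <- numeric(10)
  for (r in seq_len(10)) {
    cfg <- sim_config(n_samples = 79, n_snps = 10, n_mirnas = 30, n_mrnas = 150,
                      n_planted_eqtls = 0, n_planted_regulations = 100,
                      n_hidden_factors = 0, noise_sd = 1,
                      missingness_rate = 0, n_catalog = 0, seed = 500 + r)
    g <- simulate_genotypes(cfg)
    mi <- simulate_mirnas(g, cfg)
    # low mRNA noise so even weak planted slopes reach significance
    mr <- simulate_mrnas(mi$expr, cfg, noise_sd = 0.1)
    tab <- mirna_mrna_scan(mi$expr, mr$expr)
    means[r] <- effect_size_summary(tab)$mean
  }
  expect_lt(abs(mean(means) - truncnorm_neg_mean(-1.21, 1.05)), 0.15)
})
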