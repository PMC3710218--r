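#' Simulation configuration for a synthetic liver-style cohort
#'
#' Defaults emulate the study conditions the pipeline targets: 79 samples,
#' a few hundred expressed miRNAs with modest missingness, a scaled-down
#' mRNA panel, biallelic SNPs with a uniform minor-allele-frequency
#' spectrum, planted trans-eQTLs, planted negative miRNA-to-mRNA
#' regulation with effects drawn from a negative-truncated
#' Normal(-1.21, 1.05^2), and 4 hidden expression factors.
#'
#' @param n_samples number of samples (default 79).
#' @param n_snps number of biallelic SNPs (default 5000).
#' @param maf_spectrum function of `n` returning allele frequencies in
#'   `(0.05, 0.5)`; default uniform.
#' @param n_mirnas number of miRNA features (default 300).
#' @param n_mrnas number of mRNA features (default 2000).
#' @param n_planted_eqtls number of planted SNP-to-miRNA effects.
#' @param eqtl_beta_sampler function of `n` returning eQTL effect sizes per
#'   alt-allele copy; default constant 1.
#' @param n_planted_regulations number of planted miRNA-to-mRNA effects.
#' @param regulation_beta_sampler function of `n` returning strictly
#'   negative regulation slopes; default Normal(-1.21, 1.05^2) truncated to
#'   negative values.
#' @param regulation_targets optional character vector of mRNA ids to
#'   receive the planted regulations (recycled order; default random).
#' @param n_hidden_factors number of latent expression factors (default 4).
#' @param factor_sd standard deviation of factor scores (default 0.3,
#'   which with unit-variance loadings and noise leaves most per-feature
#'   variance untouched by factor removal, the regime liver expression
#'   cohorts show).
#' @param noise_sd residual noise standard deviation (default 1).
#' @param missingness_rate per-cell missingness probability for the miRNA
#'   matrix, in `[0, 1)` (default 0.05).
#' @param n_hwe_violating_snps SNPs simulated with a heterozygote deficit.
#' @param hwe_het_factor multiplier on the Hardy-Weinberg heterozygote
#'   probability for violating SNPs (default 0.1, renormalized).
#' @param n_catalog number of annotation-catalog entries (default 100).
#' @param catalog_fraction_overlapping fraction of catalog entries that are
#'   planted-eQTL SNPs (default 0.3).
#' @param seed integer seed controlling all generators.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_samples = 79, n_snps = 5000,
                       maf_spectrum = function(n) stats::runif(n, 0.05, 0.5),
                       n_mirnas = 300, n_mrnas = 2000,
                       n_planted_eqtls = 30,
                       eqtl_beta_sampler = function(n) rep(1, n),
                       n_planted_regulations = 300,
                       regulation_beta_sampler = function(n)
                         rtruncnorm_neg(n, mean = -1.21, sd = 1.05),
                       regulation_targets = NULL,
                       n_hidden_factors = 4, factor_sd = 0.3, noise_sd = 1,
                       missingness_rate = 0.05,
                       n_hwe_violating_snps = 0, hwe_het_factor = 0.1,
                       n_catalog = 100, catalog_fraction_overlapping = 0.3,
                       seed = 1L) {
  cfg <- list(n_samples = n_samples, n_snps = n_snps,
              maf_spectrum = maf_spectrum, n_mirnas = n_mirnas,
              n_mrnas = n_mrnas, n_planted_eqtls = n_planted_eqtls,
              eqtl_beta_sampler = eqtl_beta_sampler,
              n_planted_regulations = n_planted_regulations,
              regulation_beta_sampler = regulation_beta_sampler,
              regulation_targets = regulation_targets,
              n_hidden_factors = n_hidden_factors, factor_sd = factor_sd,
              noise_sd = noise_sd, missingness_rate = missingness_rate,
              n_hwe_violating_snps = n_hwe_violating_snps,
              hwe_het_factor = hwe_het_factor, n_catalog = n_catalog,
              catalog_fraction_overlapping = catalog_fraction_overlapping,
              seed = as.integer(seed))
  counts <- c("n_samples", "n_snps", "n_mirnas", "n_mrnas",
              "n_planted_eqtls", "n_planted_regulations", "n_hidden_factors",
              "n_hwe_violating_snps", "n_catalog")
  for (nm in counts)
    if (cfg[[nm]] < 0) stop(nm, " must be >= 0")
  if (missingness_rate < 0 || missingness_rate >= 1)
    stop("missingness_rate must lie in [0, 1)")
  if (n_planted_eqtls > n_snps * n_mirnas)
    stop("n_planted_eqtls exceeds the SNP x miRNA grid")
  if (n_planted_regulations > n_mirnas * n_mrnas)
    stop("n_planted_regulations exceeds the miRNA x mRNA grid")
  class(cfg) <- "sim_config"
  cfg
}

#' Draw from a normal distribution truncated to negative values
#' @param n number of draws.
#' @param mean,sd parameters of the untruncated normal.
#' @return numeric vector of strictly negative values.
#' @export
rtruncnorm_neg <- function(n, mean = -1.21, sd = 1.05) {
  # inverse-CDF sampling on the negative half
  u <- stats::runif(n, 0, stats::pnorm(0, mean, sd))
  q <- stats::qnorm(u, mean, sd)
  pmin(q, -.Machine$double.eps)
}

#' Mean of a normal truncated to negative values
#' @param mean,sd parameters of the untruncated normal.
#' @return the truncated-distribution mean.
#' @export
truncnorm_neg_mean <- function(mean = -1.21, sd = 1.05) {
  beta <- (0 - mean) / sd
  mean - sd * stats::dnorm(beta) / stats::pnorm(beta)
}

# stage-specific seeds derived from the master seed (kept below 2^31)
.stage_seed <- function(cfg, offset) (cfg$seed + offset * 7919L) %% 2147483647L

#' Simulate a genotype matrix under Hardy-Weinberg proportions
#'
#' For each SNP an allele frequency `f` is drawn from the configured MAF
#' spectrum and hard-call genotypes are sampled from `((1-f)^2, 2f(1-f),
#' f^2)`. A configurable number of SNPs are instead drawn with a
#' heterozygote deficit (het probability multiplied by `hwe_het_factor` and
#' renormalized), emulating genotyping artifacts that an exact
#' Hardy-Weinberg test should flag.
#'
#' @param cfg a [sim_config()].
#' @return a [genotype_matrix()] with observed `maf` filled in. The true
#'   simulated allele frequencies are kept in `g$snps$true_f`, and the HWE
#'   violators flagged in `g$snps$hwe_violator`.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_samples < 2) stop("n_samples must be >= 2")
  set.seed(.stage_seed(cfg, 1L))
  n <- cfg$n_samples; S <- cfg$n_snps
  f <- cfg$maf_spectrum(S)
  viol <- rep(FALSE, S)
  if (cfg$n_hwe_violating_snps > 0)
    viol[sample.int(S, min(cfg$n_hwe_violating_snps, S))] <- TRUE
  p_het <- 2 * f * (1 - f)
  p_het[viol] <- p_het[viol] * cfg$hwe_het_factor
  p0 <- (1 - f)^2; p2 <- f^2
  tot <- p0 + p_het + p2
  p0 <- p0 / tot; p_het <- p_het / tot
  u <- matrix(stats::runif(n * S), n, S)
  dos <- matrix(0, n, S)
  dos[u >= rep(p0, each = n)] <- 1
  dos[u >= rep(p0 + p_het, each = n)] <- 2
  chrom <- paste0("chr", 1 + (seq_len(S) - 1) %% 22)
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, S, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), character(1))
  snps <- data.frame(snp_id = sprintf("rs%06d", seq_len(S)), chrom = chrom,
                     pos = 1e4L + 137L * seq_len(S), ref_allele = ref,
                     alt_allele = unname(alt), stringsAsFactors = FALSE)
  g <- genotype_matrix(dos, snps,
                       sample_ids = sprintf("S%03d", seq_len(n)))
  g <- compute_maf(g)
  g$snps$true_f <- f
  g$snps$hwe_violator <- viol
  g
}

#' Simulate miRNA expression with planted trans-eQTLs and hidden factors
#'
#' Each miRNA is a linear combination of its planted eQTL dosages, latent
#' factor scores, and Gaussian noise, on top of a feature-specific baseline:
#' `mirna_j(s) = mu_j + sum_k beta_jk dosage_sk + sum_f lambda_jf F_sf +
#' eps`, with `F` columns independent Normal(0, factor_sd^2) and loadings
#' Normal(0, 1). Missingness is then applied completely at random at the
#' configured rate; the complete pre-missingness matrix is retained as
#' attribute `"signal"` so downstream generators are unaffected by
#' measurement dropout.
#'
#' @param g a [genotype_matrix()] from [simulate_genotypes()].
#' @param cfg a [sim_config()].
#' @return list with `expr` (an [expression_matrix()], kind `"miRNA"`) and
#'   `truth` (planted eQTLs, factor loadings/scores, seed).
#' @export
simulate_mirnas <- function(g, cfg) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(cfg, "sim_config"))
  set.seed(.stage_seed(cfg, 2L))
  n <- nrow(g$dosage); M <- cfg$n_mirnas
  if (cfg$n_planted_eqtls > ncol(g$dosage) * M)
    stop("n_planted_eqtls exceeds the SNP x miRNA grid")
  mirna_ids <- sprintf("miR_%03d", seq_len(M))
  # planted pairs: distinct SNPs and miRNAs when the grid allows, so each
  # planted signal has an unambiguous top hit
  k <- cfg$n_planted_eqtls
  if (k > 0) {
    if (k <= min(ncol(g$dosage), M)) {
      snp_idx <- sample.int(ncol(g$dosage), k)
      mir_idx <- sample.int(M, k)
    } else {
      cells <- sample.int(ncol(g$dosage) * M, k)
      snp_idx <- (cells - 1L) %% ncol(g$dosage) + 1L
      mir_idx <- (cells - 1L) %/% ncol(g$dosage) + 1L
    }
    betas <- cfg$eqtl_beta_sampler(k)
    planted <- data.frame(snp_id = g$snps$snp_id[snp_idx],
                          mirna_id = mirna_ids[mir_idx], beta = betas,
                          stringsAsFactors = FALSE)
  } else {
    planted <- data.frame(snp_id = character(0), mirna_id = character(0),
                          beta = numeric(0), stringsAsFactors = FALSE)
    snp_idx <- mir_idx <- integer(0); betas <- numeric(0)
  }
  baseline <- stats::rnorm(M, mean = 8, sd = 1.5)
  signal <- matrix(rep(baseline, each = n), n, M)
  if (k > 0)
    for (i in seq_len(k))
      signal[, mir_idx[i]] <- signal[, mir_idx[i]] +
        betas[i] * g$dosage[, snp_idx[i]]
  kF <- cfg$n_hidden_factors
  if (kF > 0) {
    scores <- matrix(stats::rnorm(n * kF, sd = cfg$factor_sd), n, kF)
    loadings <- matrix(stats::rnorm(M * kF), M, kF)
    signal <- signal + scores %*% t(loadings)
  } else {
    scores <- matrix(numeric(0), n, 0)
    loadings <- matrix(numeric(0), M, 0)
  }
  signal <- signal + matrix(stats::rnorm(n * M, sd = cfg$noise_sd), n, M)
  values <- t(signal)
  dimnames(values) <- list(mirna_ids, g$sample_ids)
  complete <- values
  if (cfg$missingness_rate > 0)
    values[matrix(stats::runif(length(values)) < cfg$missingness_rate,
                  nrow(values), ncol(values))] <- NA_real_
  expr <- expression_matrix(values, "miRNA")
  attr(expr, "signal") <- complete
  rownames(scores) <- g$sample_ids
  rownames(loadings) <- mirna_ids
  truth <- list(planted_eqtls = planted, factor_loadings = loadings,
                factor_scores = scores, seed = cfg$seed)
  list(expr = expr, truth = truth)
}

#' Simulate mRNA expression with planted negative miRNA regulation
#'
#' Each regulated mRNA is a negative linear function of its regulator
#' miRNA's (complete, pre-missingness) expression plus Gaussian noise:
#' `mrna_i(s) = mu_i + gamma_ij mirna_j(s) + eta`, `gamma_ij < 0`.
#' Unregulated mRNAs are baseline plus noise.
#'
#' @param mirna the miRNA [expression_matrix()] from [simulate_mirnas()].
#' @param cfg a [sim_config()].
#' @param noise_sd residual noise for the mRNA layer; defaults to
#'   `cfg$noise_sd`.
#' @return list with `expr` (kind `"mRNA"`, fully observed) and `truth`
#'   (`planted_regulations` with columns `mirna_id`, `mrna_id`, `beta`).
#' @export
simulate_mrnas <- function(mirna, cfg, noise_sd = cfg$noise_sd) {
  stopifnot(inherits(mirna, "expression_matrix"), inherits(cfg, "sim_config"))
  set.seed(.stage_seed(cfg, 3L))
  sig <- attr(mirna, "signal")
  if (!is.null(sig)) {
    sig <- t(sig)  # stored features x samples; work samples x miRNAs
  } else {
    sig <- mirna$values
    if (anyNA(sig)) {
      # fall back to feature-mean fill if only the observed matrix is given
      mu <- rowMeans(sig, na.rm = TRUE)
      idx <- which(is.na(sig), arr.ind = TRUE)
      sig[idx] <- mu[idx[, 1]]
    }
    sig <- t(sig)
  }
  n <- nrow(sig); M <- ncol(sig); Q <- cfg$n_mrnas
  mrna_ids <- sprintf("gene_%04d", seq_len(Q))
  k <- cfg$n_planted_regulations
  if (k > 0) {
    if (!is.null(cfg$regulation_targets)) {
      tgt_idx <- match(rep_len(cfg$regulation_targets, k), mrna_ids)
      if (anyNA(tgt_idx)) stop("regulation_targets contains unknown mRNA id")
    } else {
      tgt_idx <- sample.int(Q, k, replace = k > Q)
    }
    reg_idx <- sample.int(M, k, replace = TRUE)
    gam <- cfg$regulation_beta_sampler(k)
    if (any(gam >= 0)) stop("regulation betas must be strictly negative")
    planted <- data.frame(mirna_id = colnames(sig)[reg_idx],
                          mrna_id = mrna_ids[tgt_idx], beta = gam,
                          stringsAsFactors = FALSE)
    if (anyNA(planted$mirna_id)) stop("planted pair references unknown miRNA")
  } else {
    planted <- data.frame(mirna_id = character(0), mrna_id = character(0),
                          beta = numeric(0), stringsAsFactors = FALSE)
    tgt_idx <- reg_idx <- integer(0); gam <- numeric(0)
  }
  baseline <- stats::rnorm(Q, mean = 8, sd = 1.5)
  vals <- matrix(rep(baseline, each = n), n, Q)
  if (k > 0)
    for (i in seq_len(k))
      vals[, tgt_idx[i]] <- vals[, tgt_idx[i]] + gam[i] * sig[, reg_idx[i]]
  vals <- vals + matrix(stats::rnorm(n * Q, sd = noise_sd), n, Q)
  values <- t(vals)
  dimnames(values) <- list(mrna_ids, rownames(sig))
  expr <- expression_matrix(values, "mRNA")
  truth <- list(planted_regulations = planted, seed = cfg$seed)
  list(expr = expr, truth = truth)
}

#' Simulate an annotation catalog overlapping planted eQTLs
#'
#' A configured fraction of entries are planted-eQTL SNPs (their
#' `risk_allele` set to the alternate allele); the remainder are drawn
#' uniformly from non-planted SNPs. Evidence levels are uniform on
#' \{1, 2, 3\} and annotations are drawn from a small trait/drug lexicon.
#'
#' @param g a [genotype_matrix()].
#' @param truth the truth list from [simulate_mirnas()] (uses
#'   `planted_eqtls`).
#' @param cfg a [sim_config()].
#' @return a `catalog_table`.
#' @export
simulate_catalog <- function(g, truth, cfg) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(cfg, "sim_config"))
  set.seed(.stage_seed(cfg, 4L))
  n_cat <- cfg$n_catalog
  n_over <- round(cfg$catalog_fraction_overlapping * n_cat)
  planted_snps <- unique(truth$planted_eqtls$snp_id)
  if (n_over > length(planted_snps))
    stop("requested catalog overlap (", n_over,
         ") exceeds the number of planted eQTL SNPs (",
         length(planted_snps), ")")
  over_ids <- if (n_over > 0) sample(planted_snps, n_over) else character(0)
  rest_pool <- setdiff(g$snps$snp_id, planted_snps)
  rest_ids <- sample(rest_pool, n_cat - n_over)
  ids <- c(over_ids, rest_ids)
  lexicon <- c("warfarin response", "serum urate", "QT interval",
               "Crohn's disease", "height", "clopidogrel response",
               "ulcerative colitis", "cisplatin toxicity", "lipid levels",
               "asthma treatment")
  alt <- g$snps$alt_allele[match(ids, g$snps$snp_id)]
  risk <- c(alt[seq_len(n_over)], rep(NA_character_, n_cat - n_over))
  catalog_table(data.frame(
    snp_id = ids,
    annotation = sample(lexicon, n_cat, replace = TRUE),
    risk_allele = risk,
    evidence_level = sample(1:3, n_cat, replace = TRUE),
    source = "synthetic",
    stringsAsFactors = FALSE))
}

#' Simulate a complete cohort
#'
#' Runs the four generators in order and bundles their outputs with the
#' full ground truth.
#'
#' @param cfg a [sim_config()].
#' @return list with `genotypes`, `mirna`, `mrna`, `catalog`, `truth`.
#' @export
simulate_cohort <- function(cfg) {
  g <- simulate_genotypes(cfg)
  mir <- simulate_mirnas(g, cfg)
  mr <- simulate_mrnas(mir$expr, cfg)
  catalog <- if (cfg$n_catalog > 0) simulate_catalog(g, mir$truth, cfg) else NULL
  truth <- c(mir$truth, mr$truth["planted_regulations"])
  list(genotypes = g, mirna = mir$expr, mrna = mr$expr, catalog = catalog,
       truth = truth)
}
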