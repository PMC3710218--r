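#' Pipeline run configuration
#'
#' Bundles every threshold of the full analysis with the input locations.
#' Inputs may be file paths (TSV/VCF, read with the package readers) or
#' in-memory objects from the simulators.
#'
#' @param genotypes path or [genotype_matrix()].
#' @param mirna path or miRNA [expression_matrix()].
#' @param mrna path or mRNA [expression_matrix()].
#' @param catalog optional path or `catalog_table`.
#' @param out_dir output directory (created if absent).
#' @param expressed_frac expressed-call non-missing fraction (default 0.75).
#' @param maf_min MAF filter, strict (default 0.15).
#' @param hwe_alpha HWE exact-test cut (default 0.001).
#' @param n_pcs genotype principal components offered as covariates
#'   (default 3).
#' @param n_factors hidden factors removed before the eQTL scan (default 4).
#' @param fdr_alpha pair-scan FDR level (default 0.05).
#' @param bonferroni_alpha family-wise level for the strict eQTL tier
#'   (default 0.05).
#' @param suggestive_p fixed suggestive eQTL tier (default 1e-8).
#' @param catalog_p_max catalog join threshold (default 1e-4).
#' @param enrichment_B number of matched null sets (default 1000).
#' @param bin_width MAF matching bin width (default 0.05).
#' @param quantile_normalize_mrna quantile-normalize the mRNA matrix before
#'   the pair scan (default TRUE; requires a fully observed matrix).
#' @param seed integer seed recorded in every output.
#' @return a `run_config` list.
#' @export
run_config <- function(genotypes, mirna, mrna, catalog = NULL,
                       out_dir = tempfile("mireqtl_run_"),
                       expressed_frac = 0.75, maf_min = 0.15,
                       hwe_alpha = 0.001, n_pcs = 3, n_factors = 4,
                       fdr_alpha = 0.05, bonferroni_alpha = 0.05,
                       suggestive_p = 1e-8, catalog_p_max = 1e-4,
                       enrichment_B = 1000, bin_width = 0.05,
                       quantile_normalize_mrna = TRUE, seed = 1L) {
  stopifnot(expressed_frac > 0, expressed_frac <= 1,
            maf_min >= 0, maf_min < 0.5,
            hwe_alpha > 0, hwe_alpha < 1,
            n_pcs >= 0, n_factors >= 0,
            fdr_alpha > 0, fdr_alpha < 1,
            enrichment_B >= 1, bin_width > 0, bin_width <= 0.5)
  structure(list(genotypes = genotypes, mirna = mirna, mrna = mrna,
                 catalog = catalog, out_dir = out_dir,
                 expressed_frac = expressed_frac, maf_min = maf_min,
                 hwe_alpha = hwe_alpha, n_pcs = n_pcs,
                 n_factors = n_factors, fdr_alpha = fdr_alpha,
                 bonferroni_alpha = bonferroni_alpha,
                 suggestive_p = suggestive_p,
                 catalog_p_max = catalog_p_max,
                 enrichment_B = enrichment_B, bin_width = bin_width,
                 quantile_normalize_mrna = quantile_normalize_mrna,
                 seed = as.integer(seed)),
            class = "run_config")
}

.resolve_input <- function(x, reader, what) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) {
    if (!file.exists(x)) stop("input path for ", what, " not found: ", x)
    reader(x)
  } else x
}

#' Run the full analysis pipeline
#'
#' Sequences preprocessing (expressed call, optional mRNA quantile
#' normalization, SNP filters, genotype PCs, hidden-factor
#' residualization), the miRNA-mRNA pair scan, the miR-eQTL scan,
#' catalog annotation with MAF-matched overlap enrichment and the
#' risk-allele sign-balance test, then writes every intermediate table, a
#' machine-readable summary, and a run log under `cfg$out_dir`. A failing
#' stage aborts with its name; completed outputs are preserved. The
#' summary's threshold-tier counts are recomputed from the emitted TSVs as
#' an internal consistency check.
#'
#' @param cfg a [run_config()].
#' @return (invisibly) a list with the summary, the result tables, and the
#'   output directory.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  g <- .resolve_input(cfg$genotypes, read_genotypes, "genotypes")
  mirna <- .resolve_input(cfg$mirna,
                          function(p) read_expression(p, "miRNA"), "mirna")
  mrna <- .resolve_input(cfg$mrna,
                         function(p) read_expression(p, "mRNA"), "mrna")
  catalog <- .resolve_input(cfg$catalog, read_catalog, "catalog")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run.log")
  logf <- function(...) cat(sprintf("[%s] %s\n", format(Sys.time()),
                                    sprintf(...)),
                            file = log_path, append = TRUE)
  logf("seed %d | mireqtl %s | R %s", cfg$seed,
       as.character(utils::packageVersion("mireqtl")),
       paste(R.version$major, R.version$minor, sep = "."))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    logf("stage %-12s %.2fs", name, proc.time()[["elapsed"]] - t0)
    out
  }
  resolved <- cfg[!(names(cfg) %in% c("genotypes", "mirna", "mrna", "catalog"))]
  writeLines(paste(names(resolved),
                   vapply(resolved, function(v) paste(format(v), collapse = ","),
                          character(1)), sep = " = "),
             file.path(cfg$out_dir, "resolved_config.txt"))

  pre <- stage("preprocess", {
    mirna_e <- call_expressed(mirna, cfg$expressed_frac)
    mrna_q <- if (cfg$quantile_normalize_mrna) quantile_normalize(mrna) else mrna
    gf <- filter_snps(compute_maf(g), cfg$maf_min, cfg$hwe_alpha)
    pcs <- if (cfg$n_pcs > 0) genotype_pcs(gf, cfg$n_pcs) else NULL
    adj <- remove_hidden_factors(mirna_e, cfg$n_factors)
    list(mirna = mirna_e, mirna_resid = adj$expr, adjustment = adj$adjustment,
         mrna = mrna_q, g = gf, pcs = pcs)
  })
  write_expression(pre$mirna_resid,
                   file.path(cfg$out_dir, "mirna_residualized.tsv"))

  pairs <- stage("pair_scan", mirna_mrna_scan(pre$mirna, pre$mrna,
                                              fdr_alpha = cfg$fdr_alpha))
  write_association_table(pairs, file.path(cfg$out_dir, "pair_scan.tsv"))
  sig_pairs <- significant_negative(pairs, cfg$fdr_alpha)
  write_association_table(sig_pairs,
                          file.path(cfg$out_dir, "pair_scan_significant.tsv"))

  eqtls <- stage("eqtl_scan", eqtl_scan(pre$mirna_resid, pre$g, pre$pcs))
  write_association_table(eqtls, file.path(cfg$out_dir, "eqtl_scan.tsv"))
  bonf <- bonferroni_threshold(cfg$bonferroni_alpha, ncol(pre$g$dosage),
                               nrow(pre$mirna_resid$values))
  ok_p <- !is.na(eqtls$p)
  n_bonf <- sum(ok_p & eqtls$p < bonf)
  n_sugg <- sum(ok_p & eqtls$p < cfg$suggestive_p)

  ann <- NULL; enr <- NULL; sign_p <- NA_real_
  if (!is.null(catalog)) {
    ann <- stage("annotate", annotate_eqtls(eqtls, catalog, pre$g$snps,
                                            cfg$catalog_p_max))
    utils::write.table(ann, file.path(cfg$out_dir, "annotated_eqtls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    enr <- stage("enrichment", {
      query <- unique(catalog$snp_id[catalog$snp_id %in% pre$g$snps$snp_id])
      target <- unique(eqtls$x_id[ok_p & eqtls$p < cfg$catalog_p_max])
      nulls <- maf_matched_null_sets(query, pre$g$snps, B = cfg$enrichment_B,
                                     bin_width = cfg$bin_width,
                                     seed = cfg$seed)
      overlap_enrichment(query, target, nulls)
    })
    dirs <- ann$direction_risk[!is.na(ann$direction_risk)]
    if (length(dirs) > 0) sign_p <- sign_balance_test(dirs)
  }

  ess <- effect_size_summary(pairs, q_max = cfg$fdr_alpha)
  summary <- list(
    seed = cfg$seed,
    n_samples = length(pre$mirna$sample_ids),
    n_expressed_mirnas = nrow(pre$mirna$values),
    n_snps_tested = ncol(pre$g$dosage),
    n_pairs_tested = sum(!is.na(pairs$p)),
    n_significant_negative_pairs = nrow(sig_pairs),
    n_mirnas_with_negative_target = length(unique(sig_pairs$x_id)),
    effect_mean = ess$mean, effect_sd = ess$sd,
    bonferroni_threshold = bonf,
    n_bonferroni_eqtls = n_bonf,
    n_suggestive_eqtls = n_sugg,
    n_annotated_eqtls = if (is.null(ann)) NA_integer_ else nrow(ann),
    catalog_enrichment_p = if (is.null(enr)) NA_real_ else enr$empirical_p,
    risk_direction_sign_p = sign_p)
  # consistency check: tier counts recomputed from the emitted TSV
  back <- read_association_table(file.path(cfg$out_dir, "eqtl_scan.tsv"))
  ok_b <- !is.na(back$p)
  stopifnot(sum(ok_b & back$p < bonf) == n_bonf,
            sum(ok_b & back$p < cfg$suggestive_p) == n_sugg)
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  logf("done: %d significant negative pairs, %d Bonferroni eQTLs",
       nrow(sig_pairs), n_bonf)
  invisible(list(summary = summary, pairs = pairs, eqtls = eqtls,
                 annotated = ann, enrichment = enr,
                 adjustment = pre$adjustment, out_dir = cfg$out_dir))
}
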