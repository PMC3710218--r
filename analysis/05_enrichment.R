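#!/usr/bin/env Rscript
# Stage 5: resampling-based enrichment analyses over MAF-matched null SNP
# sets, and the gene-set regulation test on a focal pharmacogene-style set.
#  - overlap of miRNA-associated SNPs (p < 1e-4) with the catalog SNPs
#  - multi-miRNA targeting of catalog SNPs versus matched SNPs
#  - QQ curve of all catalog-SNP association p-values
#  - regulation of a 41-gene focal set versus random same-size gene sets

suppressPackageStartupMessages(library(mireqtl))

out <- "results/enrichment"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 42L
B <- 1000

g <- read_genotypes("results/preprocess/genotypes_filtered.tsv")
eqtls <- read_association_table("results/eqtl_scan/eqtls_all.tsv")
pairs <- read_association_table("results/pair_scan/pairs_all.tsv")
catalog <- read_catalog("results/data/catalog.tsv")

query <- unique(catalog$snp_id[catalog$snp_id %in% g$snps$snp_id])
target <- unique(eqtls$x_id[!is.na(eqtls$p) & eqtls$p < 1e-4])
nulls <- maf_matched_null_sets(query, g$snps, B = B, seed = seed)

ov <- overlap_enrichment(query, target, nulls)
message(sprintf(
  "catalog SNPs vs miRNA-associated SNPs (p < 1e-4): overlap %d, null mean %.1f, empirical p %s",
  ov$observed, mean(ov$null_values), ov$reported))

mt <- multi_target_enrichment(query, eqtls, p_max = 1e-3, nulls = nulls)
message(sprintf(
  "catalog SNPs associated with >= 2 miRNAs (p < 1e-3): %d, null mean %.1f, empirical p %s",
  mt$observed, mean(mt$null_values), mt$reported))

cat_p <- eqtls$p[eqtls$x_id %in% query & !is.na(eqtls$p)]
qq <- qq_curve(cat_p)
write.table(qq, file.path(out, "catalog_qq.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
top <- qq[order(qq$expected, decreasing = TRUE)[1:max(1, nrow(qq) %/% 100)], ]
message(sprintf("catalog QQ: top-1%% mean observed %.2f vs expected %.2f (-log10)",
                mean(top$observed), mean(top$expected)))

# gene-set regulation: focal = the 41 most-regulated planted targets
truth <- read.delim("results/data/truth_regulations.tsv")
focal <- unique(truth$mrna_id[order(truth$beta)])[1:41]
gs <- geneset_regulation_test(pairs, focal, unique(pairs$y_id), B = B,
                              seed = seed)
message(sprintf(
  "gene-set regulation: focal median best-p %.2e vs null median range [%.2e, %.2e], empirical p %s",
  gs$observed_median, min(gs$null_medians), max(gs$null_medians),
  gs$reported))
write.table(gs$qq_pairs, file.path(out, "geneset_qq.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# large-effect tail of the focal genes
sig <- significant_negative(pairs)
sig_f <- sig[sig$y_id %in% focal, ]
best_beta <- tapply(sig_f$beta, sig_f$y_id, min)
tp <- tail_proportion_test(best_beta, beta_cut = -4, background_prop = 0.05)
message(sprintf(
  "focal genes with best beta < -4: %d of %d (%.0f%%), exact binomial p vs 5%%: %.2e",
  tp$n_below, tp$n, 100 * tp$proportion, tp$p))

enr <- data.frame(
  test = c("catalog_overlap", "multi_target", "geneset_regulation",
           "tail_proportion"),
  observed = c(ov$observed, mt$observed, gs$observed_median, tp$proportion),
  empirical_p = c(ov$empirical_p, mt$empirical_p, gs$empirical_p, tp$p))
write.table(enr, file.path(out, "enrichment_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(vapply(list(ov$null_values, mt$null_values, gs$null_medians),
                  function(v) paste(signif(v, 6), collapse = "\t"),
                  character(1)),
           file.path(out, "null_distributions.tsv"))
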