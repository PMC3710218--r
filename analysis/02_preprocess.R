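#!/usr/bin/env Rscript
# Stage 2: expression QC and genotype filtering. Calls expressed miRNAs
# (>= 75% non-missing), quantile-normalizes the mRNA matrix, filters SNPs
# on MAF > 15% and the Hardy-Weinberg exact test at p < 0.001, computes 3
# genotype PCs as candidate covariates, and removes 4 hidden factors from
# the miRNA matrix before eQTL mapping.

suppressPackageStartupMessages(library(mireqtl))

dat <- "results/data"
out <- "results/preprocess"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

g <- read_genotypes(file.path(dat, "genotypes.tsv"))
mirna <- read_expression(file.path(dat, "mirna_raw.tsv"), "miRNA")
mrna <- read_expression(file.path(dat, "mrna_raw.tsv"), "mRNA")

mirna_expr <- call_expressed(mirna, 0.75)
mrna_qn <- quantile_normalize(mrna)
gf <- filter_snps(g, maf_min = 0.15, hwe_alpha = 0.001)

truth <- read.delim(file.path(dat, "truth_eqtls.tsv"))
n_viol_dropped <- sum(!(unique(truth$snp_id) %in% gf$snps$snp_id))
message(sprintf("%d of %d planted eQTL SNPs survive the filters",
                length(unique(truth$snp_id)) - n_viol_dropped,
                length(unique(truth$snp_id))))

pcs <- genotype_pcs(gf, k = 3)
adj <- remove_hidden_factors(mirna_expr, k = 4)
message(sprintf(
  "hidden-factor adjustment: median pre/post correlation %.3f (min %.3f, max %.3f)",
  median(adj$adjustment$per_feature_correlation, na.rm = TRUE),
  min(adj$adjustment$per_feature_correlation, na.rm = TRUE),
  max(adj$adjustment$per_feature_correlation, na.rm = TRUE)))

write_expression(mirna_expr, file.path(out, "mirna_expressed.tsv"))
write_expression(adj$expr, file.path(out, "mirna_residualized.tsv"))
write_expression(mrna_qn, file.path(out, "mrna_qnorm.tsv"))
write_genotypes(gf, file.path(out, "genotypes_filtered.tsv"))
write.table(pcs, file.path(out, "genotype_pcs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
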