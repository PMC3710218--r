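#!/usr/bin/env Rscript
# Stage 1: generate the synthetic liver-style cohort the downstream stages
# analyse, and write its matrices, catalog and ground truth under
# results/data/. The configuration mirrors the study conditions the
# pipeline targets: 79 samples, 300 probed miRNAs with 5% random dropout,
# a 2,000-gene mRNA panel, 5,000 biallelic SNPs, 30 planted trans-eQTLs,
# 300 planted negative regulations with slopes from a negative-truncated
# Normal(-1.21, 1.05^2), 4 hidden expression factors, and an annotation
# catalog of 100 SNPs of which 30% are planted eQTL SNPs.

suppressPackageStartupMessages(library(mireqtl))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 42L

cfg <- sim_config(n_samples = 79, n_snps = 5000, n_mirnas = 300,
                  n_mrnas = 2000, n_planted_eqtls = 30,
                  # signed effects: the alt allele raises or lowers
                  # expression with equal probability
                  eqtl_beta_sampler = function(n)
                    sample(c(-1, 1), n, replace = TRUE) * rnorm(n, 1.2, 0.2),
                  n_planted_regulations = 300, n_hidden_factors = 4,
                  factor_sd = 0.3, noise_sd = 1, missingness_rate = 0.05,
                  n_hwe_violating_snps = 25, n_catalog = 100,
                  catalog_fraction_overlapping = 0.3, seed = seed)
co <- simulate_cohort(cfg)

write_genotypes(co$genotypes, file.path(out, "genotypes.tsv"))
write_expression(co$mirna, file.path(out, "mirna_raw.tsv"))
write_expression(co$mrna, file.path(out, "mrna_raw.tsv"))
write_catalog(co$catalog, file.path(out, "catalog.tsv"))
write.table(co$truth$planted_eqtls, file.path(out, "truth_eqtls.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(co$truth$planted_regulations,
            file.path(out, "truth_regulations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf(
  "cohort written: %d samples, %d SNPs (%d HWE-violating), %d miRNAs (%.1f%% missing), %d mRNAs",
  cfg$n_samples, cfg$n_snps, cfg$n_hwe_violating_snps, cfg$n_mirnas,
  100 * mean(is.na(co$mirna$values)), cfg$n_mrnas))
message(sprintf("planted: %d trans-eQTLs, %d negative regulations (mean beta %.2f)",
                nrow(co$truth$planted_eqtls),
                nrow(co$truth$planted_regulations),
                mean(co$truth$planted_regulations$beta)))
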