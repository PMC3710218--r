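#!/usr/bin/env Rscript
# Stage 3: miRNA-mRNA negative-association scan. Regresses every mRNA on
# every expressed miRNA, controls the FDR within the negative-slope
# partition at 0.05, and summarizes the effect-size distribution of the
# significant negative associations.

suppressPackageStartupMessages(library(mireqtl))

pre <- "results/preprocess"
out <- "results/pair_scan"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

mirna <- read_expression(file.path(pre, "mirna_expressed.tsv"), "miRNA")
mrna <- read_expression(file.path(pre, "mrna_qnorm.tsv"), "mRNA")

pairs <- mirna_mrna_scan(mirna, mrna, fdr_alpha = 0.05)
sig <- significant_negative(pairs)
write_association_table(pairs, file.path(out, "pairs_all.tsv"))
write_association_table(sig, file.path(out, "pairs_significant.tsv"))

ess <- effect_size_summary(pairs, q_max = 0.05, sign = "negative")
message(sprintf(
  "%d of %d tested pairs significant (negative, FDR < 0.05); %d of %d miRNAs have >= 1 target",
  nrow(sig), sum(!is.na(pairs$p)), length(unique(sig$x_id)),
  nrow(mirna$values)))
message(sprintf(
  "effect sizes among significant negative associations: mean %.2f, sd %.2f (n = %d)",
  ess$mean, ess$sd, ess$n))

# recovery of planted regulations
truth <- read.delim("results/data/truth_regulations.tsv")
found <- paste(truth$mirna_id, truth$mrna_id) %in% paste(sig$x_id, sig$y_id)
message(sprintf("planted regulation recovery: %d of %d pairs significant",
                sum(found), nrow(truth)))
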