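# mireqtl

Integrative microRNA analysis for a genotyped expression cohort: which
mRNAs do the expressed miRNAs repress, which genetic variants control
miRNA abundance (miR-eQTLs), and are those variants enriched in external
SNP catalogs and focal gene sets beyond what allele-frequency-matched
chance allows?

The package implements, as tested library code:

* **miRNA–mRNA negative-association scan** — OLS of every mRNA on every
  miRNA over pairwise-complete cases; Benjamini–Hochberg FDR within the
  negative-slope partition (repression is the direction of interest);
  effect-size summaries of the significant set.
* **miR-eQTL mapping** — each miRNA regressed on every SNP dosage, after
  SNP filters (MAF strictly > 15%, Levene–Haldane exact Hardy–Weinberg
  test at p ≥ 0.001), per-miRNA conditional covariate screening (genotype
  PCs, age, sex; included when marginally associated at p < 0.05), and
  hidden-factor residualization (top-4 expression PCs removed); Bonferroni
  `alpha / (n_SNPs × n_miRNAs)` and suggestive (p < 1e-8) tiers.
* **Resampling enrichment** — null SNP sets matched exactly on the
  query's minor-allele-frequency bin profile (bin width 0.05, B = 1000);
  empirical p = fraction of null statistics that match or exceed the
  observed (reported "< 1/B" at zero count). Built on this: catalog
  overlap enrichment, multi-miRNA targeting, a gene-set regulation test
  (median per-gene best negative p vs random same-size gene sets, with
  exhaustive enumeration on small universes), QQ curves, an exact
  binomial tail-proportion test (β < −4 vs 5% background), a one-sided
  Welch comparison of |β| between miRNA groups, and a sign-balance test
  of risk-allele effect directions.
* **Synthetic cohorts** — a generator with planted trans-eQTLs, planted
  negative regulation (slopes from a Normal(−1.21, 1.05²) truncated to
  negatives), hidden factors, Hardy–Weinberg violators, MCAR missingness
  and an overlapping annotation catalog, with full ground truth recorded
  for recovery/calibration/power testing.

Input formats: VCF (GT or DS) or dosage TSV for genotypes; feature × sample
TSV for expression; TSV catalogs (`snp_id`, `annotation`, optional
`risk_allele`, `evidence_level` ∈ {1,2,3}). All outputs are TSV/JSON.

## Worked example

The numbered scripts under `analysis/` run the full workflow on a
simulated 79-sample cohort (5,000 SNPs, 300 miRNAs, 2,000 mRNAs, 30
planted trans-eQTLs with signed effects, 300 planted negative
regulations, 4 hidden factors, 5% miRNA dropout, a 100-SNP catalog with
30% planted overlap):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_pair_scan.R
Rscript analysis/04_eqtl_scan.R
Rscript analysis/05_enrichment.R
Rscript analysis/06_annotate_report.R
```

Output of a run (~80 s total; tables land under `results/`):

```
filter_snps: 3859 of 5000 retained (1126 failed maf > 0.15, 15 failed HWE p >= 0.001)
hidden-factor adjustment: median pre/post correlation 0.862 (min 0.563, max 0.994)
380 of 600000 tested pairs significant (negative, FDR < 0.05); 198 of 300 miRNAs have >= 1 target
effect sizes among significant negative associations: mean -1.50, sd 0.78 (n = 380)
Bonferroni threshold 4.32e-08: 12 associations
suggestive tier (p < 1e-8): 8 associations over 8 miRNAs
catalog SNPs vs miRNA-associated SNPs (p < 1e-4): overlap 22, null mean 2.3, empirical p < 0.001
catalog SNPs associated with >= 2 miRNAs (p < 1e-3): 8, null mean 2.2, empirical p < 0.001
gene-set regulation: focal median best-p 3.96e-35 ... empirical p < 0.001
risk-allele direction: 9 up, 12 down; sign-balance p = 0.664
```

Reading it: the SNP filters drop rare and HWE-violating variants;
residualizing 4 factors perturbs each miRNA only mildly (median pre/post
correlation 0.86); the pair scan finds the planted repression (the mean
significant slope, −1.50, matches the negative-truncated Normal(−1.21,
1.05²) mean of −1.46); the eQTL tiers recover planted variants; catalog
SNPs — 30% of which are planted eQTL SNPs — overlap miRNA-associated SNPs
far beyond matched-null expectation, and target multiple miRNAs more often
than matched SNPs; risk-allele directions show no tendency, as the signed
planting implies.

In code, the same machinery:

```r
library(mireqtl)
co <- simulate_cohort(sim_config(seed = 42))
gf <- filter_snps(compute_maf(co$genotypes))        # MAF > 0.15, HWE >= 1e-3
adj <- remove_hidden_factors(call_expressed(co$mirna), k = 4)
eqtls <- eqtl_scan(adj$expr, gf, genotype_pcs(gf, 3))
pairs <- mirna_mrna_scan(co$mirna, co$mrna)
effect_size_summary(pairs)                           # mean/sd of significant betas
```

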