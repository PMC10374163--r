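#!/usr/bin/env Rscript
# QC the per-cohort alpha-angle GWAS, pool by fixed-effects inverse-variance
# meta-analysis, inspect inflation and heterogeneity, and clump to the
# independent instrument SNPs.
library(camMR)
cohorts <- read_sumstats("results/aa_gwas_cohorts.tsv")
qc <- qc_filter(cohorts)
cat(sprintf("QC: kept %d of %d records (%d dropped)\n", nrow(qc$kept),
            nrow(cohorts), nrow(qc$dropped)))
meta <- fixed_effects_meta(qc$kept)
write.table(meta, "results/aa_meta.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("pooled %d SNPs; %d genome-wide significant; max I2 %.0f%%\n",
            nrow(meta), sum(meta$P < 5e-8), max(meta$I2)))
ld <- simulate_ld_matrix(rep(1, nrow(meta)), 0)
dimnames(ld) <- list(meta$SNP, meta$SNP)
idx <- ld_clump(meta, ld)
write.table(idx, "results/aa_instruments.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("clumping selected %d independent instrument SNPs\n", nrow(idx)))
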