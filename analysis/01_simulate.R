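#!/usr/bin/env Rscript
# Generate the synthetic study inputs: a population of hip outlines with
# known ground-truth alpha angles, an observational phenotype table, and
# two-sample GWAS summary statistics for both MR directions.
library(camMR)
seed <- 20260930L %% 1000000L
dir.create("results", showWarnings = FALSE)
dir.create("scratch/outlines", showWarnings = FALSE)

aa <- aa_population(200, seed = seed)
cat(sprintf("simulated %d alpha angles: mean %.1f deg, skewness %.2f\n",
            length(aa), mean(aa), camMR:::sample_skewness(aa)))
for (i in seq_along(aa)) {
  sp <- shape_spec(cam_onset_angle = min(max(aa[i], 35), 140),
                   cam_amplitude = 0.15, noise_sd = 0.005, seed = seed + i)
  write_outline(generate_hip_outline(sp, sprintf("subj_%04d", i)),
                sprintf("scratch/outlines/subj_%04d.tsv", i))
}

pheno <- simulate_phenotype_table(20000, seed = seed + 500)
write.table(pheno, "scratch/phenotypes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("phenotype table: %d subjects, %.1f%% cam (alpha >= 60)\n",
            nrow(pheno), 100 * mean(pheno$alpha_deg >= 60)))

fwd <- simulate_summary_stats(gwas_sim_spec(causal_beta = 0.1,
                                            seed = seed + 600))
rev <- simulate_summary_stats(gwas_sim_spec(
  n_snps = 34, causal_beta = 0.09, n_exposure = 323948, n_outcome = 44214,
  outcome_type = "quantitative", seed = seed + 601))
write_sumstats(fwd$exposure, "results/aa_gwas_cohorts.tsv")
write_sumstats(fwd$outcome, "results/hoa_gwas_outcome.tsv")
write_sumstats(rev$exposure, "results/hoa_gwas_cohorts.tsv")
write_sumstats(rev$outcome, "results/aa_gwas_outcome.tsv")
cat("wrote per-cohort summary statistics for both MR directions\n")
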