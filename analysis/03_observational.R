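#!/usr/bin/env Rscript
# Observational stage: odds ratios for hip-OA outcomes and the hazard ratio
# for total hip replacement per SD of alpha angle, unadjusted and adjusted.
library(camMR)
pheno <- read.delim("scratch/phenotypes.tsv")
tab <- observational_table(pheno)
write.table(tab, "results/observational_associations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
fmt <- sprintf("%-30s %-3s %s %5.2f (%.2f, %.2f)  P=%.2g", tab$outcome,
               tab$measure, ifelse(tab$adjusted, "adj  ", "unadj"),
               tab$estimate, tab$ci_low, tab$ci_high, tab$p)
cat(fmt, sep = "\n")
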