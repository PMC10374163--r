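#!/usr/bin/env Rscript
# Colocalization of a simulated shared-causal-variant locus pair and a
# negative control with a null second trait.
library(camMR)
shared <- simulate_locus_pair(n_variants = 100, z1 = 8, z2 = 8,
                              shared = TRUE, seed = 930)
null2 <- simulate_locus_pair(n_variants = 100, z1 = 8, z2 = 0, seed = 931)
rows <- lapply(list(shared = shared, null_trait2 = null2), function(lp) {
  r <- coloc_pp(lp$trait1, lp$trait2)
  data.frame(t(r$pp), n_variants = r$n_variants, call = r$call)
})
tab <- cbind(locus = names(rows), do.call(rbind, rows))
write.table(tab, "results/coloc_results.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(tab, row.names = FALSE)
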