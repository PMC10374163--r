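#!/usr/bin/env Rscript
# Measure alpha angles on the simulated outlines and compare with the
# construction ground truth.
library(camMR)
paths <- list.files("scratch/outlines", full.names = TRUE)
res <- batch_alpha(paths)
write.table(res, "results/alpha_angles.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("measured %d/%d outlines; %d flagged failures\n",
            sum(!is.na(res$alpha_deg)), nrow(res), sum(!is.na(res$error))))
cat(sprintf("mean alpha %.1f deg; cam prevalence %.1f%%\n",
            mean(res$alpha_deg, na.rm = TRUE),
            100 * mean(res$is_cam, na.rm = TRUE)))
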