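#!/usr/bin/env Rscript
# Stage 6: 2^-ddCt relative quantification of the assayed miRNAs with
# U6-style reference normalization, ANOVA + Tukey compact letters, and the
# concordance check against the sequencing fold-changes.
suppressPackageStartupMessages(library(dtxmir))

study <- readRDS("scratch/study.rds")
de <- readRDS("scratch/de.rds")

dd <- delta_delta_ct(study$ct_table, calibrator = study$config$library_names[1])
gs <- group_stats(dd$records)
write.table(gs, "results/qpcr_rq.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

conc <- NULL
for (m in unique(gs$target)) {
  for (cmp in names(de$comparisons)) {
    seq_fc <- de$comparisons[[cmp]]$log2fc[de$comparisons[[cmp]]$mirna == m]
    rq <- dd$summary$mean_rq[dd$summary$target == m & dd$summary$group == cmp]
    if (length(seq_fc) && length(rq))
      conc <- c(conc, sign(seq_fc) == sign(log2(rq)))
  }
}
cat("qPCR targets:", length(unique(gs$target)), "\n")
cat(sprintf("Sequencing/qPCR sign concordance: %.0f%% (%d comparisons)\n",
            100 * mean(conc), length(conc)))
print(head(gs, 8), row.names = FALSE)
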