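#!/usr/bin/env Rscript
# Stage 5: predict binding sites for the differentially expressed miRNAs on
# the 3'-UTR set with the three predictors (seed scan, position-weighted
# alignment, duplex energy), keep all-three consensus spots, and run
# hypergeometric term enrichment of the consensus target genes.
suppressPackageStartupMessages(library(dtxmir))

study <- readRDS("scratch/study.rds")
de <- readRDS("scratch/de.rds")
cfg <- study$config

de_mirnas <- sort(unique(unlist(lapply(de$comparisons, function(d)
  d$mirna[d$regulation != "ns"]))))
seqs <- setNames(study$catalog$sequence, study$catalog$name)
tg <- predict_targets(seqs[de_mirnas], study$utrs,
                      gene_map = study$truth$gene_map)

write.table(tg$sites, "results/target_sites.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(set = names(tg$venn), spots = as.integer(tg$venn)),
            "results/venn_counts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

bg <- unique(study$truth$gene_map$gene)
enr <- correct_terms(hypergeom_enrich(tg$genes, bg, study$term_map))
write.table(enr, "results/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
go_tab <- classification_table(tg$genes,
                               study$term_map[study$term_map$category != "pathway", ])
write.table(go_tab, "results/classification_go.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
saveRDS(list(targets = tg, enrichment = enr), "scratch/targets.rds")

cat("DE miRNAs scanned:", length(de_mirnas), "against", length(study$utrs),
    "UTRs\n")
print(tg$venn)
cat("Consensus spots:", sum(tg$sites$consensus), "on",
    length(tg$genes), "target genes\n")
sig <- enr[enr$significant, ]
cat("Significant terms (corrected p <= 0.05):", nrow(sig), "\n")
print(sig[, c("term_id", "term_name", "k", "K", "p_corrected")],
      row.names = FALSE)
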