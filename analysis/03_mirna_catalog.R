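#!/usr/bin/env Rscript
# Stage 3: quantify known miRNAs (5'-anchored isomiR matching, low-count
# filter) and discover novel miRNA candidates from unannotated tags by
# hairpin folding with the dinucleotide-shuffle randomization test.
suppressPackageStartupMessages(library(dtxmir))

study <- readRDS("scratch/study.rds")
p <- readRDS("scratch/processed.rds")
cfg <- study$config

mk <- match_known(p$tags, study$catalog)
retained <- filter_low_count(mk$records)
cand <- discover_novel(p$tags, p$classes, p$hits, study$genome,
                       seed = derive_seed(cfg$seed, "novel"))
novel <- filter_novel(cand)

write.table(mk$records, "results/known_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cand[setdiff(colnames(cand), "structure")],
            "results/novel_candidates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
writeLines(paste0(">", novel$tag, "\n", novel$sequence),
           "results/novel_accepted.fa")
saveRDS(list(known = mk, retained = retained, cand = cand, novel = novel),
        "scratch/mirna.rds")

cat("Known miRNAs with reads:",
    sum(rowSums(as.matrix(mk$records[cfg$library_names])) > 0), "of",
    nrow(study$catalog), "\n")
cat("Retained after the <10-in-all-libraries filter:", nrow(retained), "\n")
cat("Novel candidates:", nrow(cand), "| accepted (score > 1, p < 0.05,",
    "MFE < -19):", nrow(novel), "\n")
truth_novel <- study$truth$mirna_truth$mature[study$truth$mirna_truth$is_novel]
cat("Planted novel miRNAs recovered:", sum(truth_novel %in% novel$tag),
    "of", length(truth_novel), "\n")
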