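#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study -- genome with embedded sRNA loci,
# miRNA catalog, four raw read libraries (control, 2 h, 4 h, 6 h after
# toxin injection), 3'-UTR set with planted target sites, term maps and a
# qPCR Ct table -- together with the ground-truth ledger that every later
# stage is judged against.
suppressPackageStartupMessages(library(dtxmir))

seed <- 20180208L
cfg <- sim_config(seed = seed)
study <- simulate_study(cfg)

# full input set (FASTQ/FASTA/GFF3/TSV/JSON ledger) is several MB; it goes
# under scratch/, with the study object cached for the later stages
dir.create("scratch/sim", showWarnings = FALSE, recursive = TRUE)
write_study(study, "scratch/sim")
saveRDS(study, "scratch/study.rds")

tr <- study$truth
cat("Simulated", cfg$n_libraries, "libraries x", cfg$reads_per_library,
    "reads on a", cfg$genome_length, "nt genome\n")
cat("Catalog:", sum(!tr$mirna_truth$is_novel), "known miRNAs;",
    sum(tr$mirna_truth$is_novel), "unannotated (novel) miRNA loci\n")
cat("Planted DE miRNAs:", length(tr$de_names),
    "(|log2FC| = 2 in every treatment)\n")
cat("Planted failure reads per library:",
    paste(names(tr$filter_truth), unlist(tr$filter_truth[1, ]),
          collapse = ", "), "\n")
cat("Inputs written to scratch/sim/, ledger in ground_truth.json\n")
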