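# The generator is itself first-class code: its ledger is the acceptance
# surface for every downstream stage, so its own invariants get tested.

test_that("generated genome has the configured features and is deterministic", {
  cfg <- small_cfg()
  g1 <- generate_genome(cfg)
  expect_equal(sum(Biostrings::width(g1$genome)), cfg$genome_length)
  expect_equal(sum(g1$annotation$type == "pre_miRNA"), cfg$n_known_mirnas)
  # precursor loci carry the planted hairpin sequence
  mt <- g1$truth$mirna_truth
  gs <- as.character(g1$genome[[1]])
  for (i in c(1L, nrow(mt)))
    expect_equal(substr(gs, mt$start[i] + 1L, mt$end[i]), mt$precursor[i])
  # novel precursors are deliberately absent from the annotation
  expect_false(any(mt$name[mt$is_novel] %in% g1$annotation$ID))
  g2 <- generate_genome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$truth$mirna_truth, g2$truth$mirna_truth)
})

test_that("infeasible feature placement fails loudly", {
  expect_error(generate_genome(small_cfg(genome_length = 30000L)),
               "placement failure")
})

test_that("planted cleaning failures and class counts conserve reads", {
  study <- get_small_study()
  cfg <- study$config
  ft <- study$truth$filter_truth
  expect_equal(unname(unlist(ft["control", ])),
               c(round(cfg$frac_quality_fail * cfg$reads_per_library),
                 round(cfg$frac_5contaminant * cfg$reads_per_library),
                 round(cfg$frac_no3adapter * cfg$reads_per_library),
                 round(cfg$frac_short * cfg$reads_per_library)))
  for (lib in cfg$library_names) {
    expect_equal(sum(study$truth$counts[, lib]) + sum(ft[lib, ]),
                 cfg$reads_per_library)
    expect_equal(nrow(study$reads[[lib]]), cfg$reads_per_library)
  }
  # every read is attributable to exactly one ground-truth class
  cls <- table(study$reads$control$class)
  expect_equal(sum(cls), cfg$reads_per_library)
})

test_that("planted fold-changes shape the expected counts", {
  study <- get_small_study()
  tr <- study$truth
  for (m in tr$de_names) {
    ratio <- tr$expected_counts[m, -1] / tr$expected_counts[m, "control"]
    expect_equal(unname(log2(ratio)), unname(tr$de_log2fc[m, ]),
                 tolerance = 1e-10)
  }
})

test_that("clean insert lengths are bimodal at 22 and 28 nt", {
  p <- get_small_processed()
  ld <- length_distribution(p$tags)
  for (lib in unique(ld$library)) {
    f <- ld$freq[ld$library == lib]
    len <- ld$length[ld$library == lib]
    is_mode <- function(L) {
      i <- match(L, len)
      f[i] > f[i - 1] && f[i] > f[i + 1]
    }
    expect_true(is_mode(22L))
    expect_true(is_mode(28L))
    expect_equal(sum(f), 1)
  }
})

test_that("planted target sites sit inside their UTRs with 8mer anatomy", {
  study <- get_small_study()
  st <- study$truth$site_truth
  strong <- st[st$site_class == "strong", ]
  expect_equal(nrow(strong),
               study$config$n_de_mirnas * study$config$planted_sites_per_de_mirna)
  mt <- study$truth$mirna_truth
  for (r in seq_len(nrow(strong))) {
    utr <- as.character(study$utrs[[strong$transcript[r]]])
    expect_gte(strong$start[r], 0L)
    expect_lte(strong$end[r], nchar(utr))
    mseq <- mt$mature[mt$name == strong$mirna[r]]
    site <- substr(utr, strong$start[r] + 1L, strong$end[r])
    # ends with the reverse complement of seed 2-8 followed by A
    seed_rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(mseq, 2, 8))))
    expect_equal(substr(site, nchar(site) - 7L, nchar(site)),
                 paste0(seed_rc, "A"))
  }
})

test_that("noise-free qPCR tables encode the planted relative quantities", {
  cfg <- small_cfg()
  gen <- generate_genome(cfg)
  qp <- generate_qpcr_table(cfg, gen, noise_sd = 0)
  dd <- delta_delta_ct(qp$ct_table, calibrator = "control")
  merged <- merge(dd$summary, qp$qpcr_truth, by = c("target", "group"))
  expect_equal(merged$mean_rq, merged$true_rq, tolerance = 1e-12)
  ctrl <- dd$summary[dd$summary$group == "control", ]
  expect_equal(ctrl$mean_rq, rep(1, nrow(ctrl)), tolerance = 1e-12)
})

test_that("noisy qPCR recovery stays within sampling error", {
  cfg <- small_cfg()
  gen <- generate_genome(cfg)
  qp <- generate_qpcr_table(cfg, gen, noise_sd = 0.1)
  dd <- delta_delta_ct(qp$ct_table, calibrator = "control")
  merged <- merge(dd$summary, qp$qpcr_truth, by = c("target", "group"))
  # log2 RQ is a difference of Ct terms with sd ~ 0.1*sqrt(2)/sqrt(3)
  off <- abs(log2(merged$mean_rq) - log2(merged$true_rq))
  expect_true(all(off < 3 * 0.1 * sqrt(2) * (1 + 1 / sqrt(3))))
})

test_that("configs validate and round-trip through YAML", {
  expect_error(sim_config(frac_quality_fail = 0.9, frac_len22_peak = 0.3),
               "sum to more than 1")
  expect_error(sim_config(n_de_mirnas = 5, de_log2fc = matrix(1, 2, 3)),
               "one fold-change per DE miRNA")
  expect_error(sim_config(reads_per_library = 10, frac_short = 0.95,
                          frac_len22_peak = 0.01, frac_len28_peak = 0.01),
               "failure total")
  cfg <- small_cfg()
  f <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, f)
  cfg2 <- read_sim_config(f)
  expect_equal(unclass(cfg)[sort(names(cfg))], unclass(cfg2)[sort(names(cfg2))],
               tolerance = 1e-12, ignore_attr = TRUE)
})
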