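#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic small-RNA study.
#' The defaults define the study conditions emulated throughout the package:
#' four libraries (one control plus 2 h, 4 h and 6 h post-injection
#' treatments, one library each, as in a time-course injection design), a
#' bimodal insert-length distribution with modes at 22 nt (miRNA) and 28 nt
#' (piRNA-like), planted cleaning failures at realistic low rates, a
#' log-uniform miRNA expression distribution, and a set of differentially
#' expressed miRNAs with planted log2 fold-changes of magnitude 2.
#'
#' @param seed integer RNG seed.
#' @param n_libraries number of libraries; the first is the control/calibrator.
#' @param library_names labels, control first.
#' @param reads_per_library raw reads simulated per library.
#' @param genome_length reference genome length (nt).
#' @param n_known_mirnas,n_novel_mirnas catalogued and uncatalogued
#'   (discoverable) miRNA loci planted in the genome.
#' @param n_de_mirnas number of known miRNAs given planted fold-changes.
#' @param de_log2fc matrix (`n_de_mirnas` x treatments) of true log2
#'   fold-changes, or `NULL` for the default (+/-2, alternating sign).
#' @param frac_len22_peak,frac_len28_peak proportions of clean reads allocated
#'   to the miRNA (22 nt) and piRNA-like (28 nt) length modes.
#' @param frac_quality_fail,frac_no3adapter,frac_5contaminant,frac_short
#'   planted failure proportions of raw reads, one per cleaning filter.
#' @param adapter3,adapter5 adapter sequences (DNA alphabet).
#' @param read_length raw read length after adapter ligation.
#' @param n_utrs number of 3'-UTR sequences in the synthetic transcriptome.
#' @param planted_sites_per_de_mirna strong (all-predictor) target sites
#'   planted per DE miRNA.
#' @param qpcr_noise_sd Gaussian Ct noise (cycles).
#' @param n_decoy_tags recurring unannotated background tags (novel-miRNA
#'   discovery decoys).
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_libraries = 4L,
                       library_names = c("control", "t2h", "t4h", "t6h"),
                       reads_per_library = 20000L,
                       genome_length = 200000L,
                       n_known_mirnas = 60L,
                       n_novel_mirnas = 8L,
                       n_de_mirnas = 12L,
                       de_log2fc = NULL,
                       frac_len22_peak = 0.30,
                       frac_len28_peak = 0.25,
                       frac_quality_fail = 0.010,
                       frac_no3adapter = 0.005,
                       frac_5contaminant = 0.003,
                       frac_short = 0.007,
                       adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                       adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                       read_length = 50L,
                       n_utrs = 80L,
                       planted_sites_per_de_mirna = 3L,
                       qpcr_noise_sd = 0.15,
                       n_decoy_tags = 30L) {
  if (length(library_names) != n_libraries)
    stopf("library_names must have length n_libraries (%d)", n_libraries)
  if (n_libraries < 2L) stopf("need a control plus at least one treatment")
  n_treat <- n_libraries - 1L
  if (is.null(de_log2fc)) {
    base <- rep(c(2, -2), length.out = n_de_mirnas)
    de_log2fc <- matrix(rep(base, n_treat), ncol = n_treat,
                        dimnames = list(NULL, library_names[-1]))
  }
  de_log2fc <- as.matrix(de_log2fc)
  if (n_de_mirnas > 0 &&
      (nrow(de_log2fc) != n_de_mirnas || ncol(de_log2fc) != n_treat))
    stopf("de_log2fc must be %d x %d (one fold-change per DE miRNA per treatment)",
          n_de_mirnas, n_treat)
  cfg <- list(
    seed = as.integer(seed), n_libraries = as.integer(n_libraries),
    library_names = library_names,
    reads_per_library = as.integer(reads_per_library),
    genome_length = as.integer(genome_length),
    n_known_mirnas = as.integer(n_known_mirnas),
    n_novel_mirnas = as.integer(n_novel_mirnas),
    n_de_mirnas = as.integer(n_de_mirnas),
    de_log2fc = de_log2fc,
    frac_len22_peak = frac_len22_peak, frac_len28_peak = frac_len28_peak,
    frac_quality_fail = frac_quality_fail, frac_no3adapter = frac_no3adapter,
    frac_5contaminant = frac_5contaminant, frac_short = frac_short,
    adapter3 = as_dna(adapter3), adapter5 = as_dna(adapter5),
    read_length = as.integer(read_length),
    n_utrs = as.integer(n_utrs),
    planted_sites_per_de_mirna = as.integer(planted_sites_per_de_mirna),
    qpcr_noise_sd = qpcr_noise_sd,
    n_decoy_tags = as.integer(n_decoy_tags))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  fr <- c(cfg$frac_quality_fail, cfg$frac_no3adapter, cfg$frac_5contaminant,
          cfg$frac_short)
  props <- c(fr, cfg$frac_len22_peak, cfg$frac_len28_peak)
  if (any(props < 0 | props > 1)) stopf("all proportions must lie in [0, 1]")
  if (sum(fr) + cfg$frac_len22_peak + cfg$frac_len28_peak > 1)
    stopf("proportions sum to more than 1")
  counts <- c(cfg$reads_per_library, cfg$genome_length, cfg$n_known_mirnas,
              cfg$read_length, cfg$n_utrs)
  if (any(counts <= 0)) stopf("all counts must be positive")
  if (cfg$n_de_mirnas > cfg$n_known_mirnas)
    stopf("n_de_mirnas cannot exceed n_known_mirnas")
  if (sum(round(fr * cfg$reads_per_library)) >= cfg$reads_per_library)
    stopf("reads_per_library smaller than the planted failure total")
  if (nchar(cfg$adapter3) < 6 || nchar(cfg$adapter5) < 8)
    stopf("adapters too short for the cleaning definitions")
  invisible(cfg)
}

#' Analysis thresholds
#'
#' Every printed threshold of the workflow in one place: minimum/maximum
#' insert length (18/30 nt), the known-miRNA raw-count floor (10 in at least
#' one library), the TPM zero substitution (0.01) and low-expression floor
#' (1 TPM), the novel-miRNA acceptance triple (score > 1, randomization
#' p < 0.05, MFE < -19 kcal/mol), differential-expression alpha (0.05 on the
#' Bonferroni-corrected p) and |log2 fold-change| >= 1, and the enrichment
#' alpha (corrected p <= 0.05).
#'
#' @param ... overrides of the defaults (logged on the returned object).
#' @return a `pipeline_params` list.
#' @export
pipeline_params <- function(...) {
  p <- list(
    min_insert_len = 18L, max_insert_len = 30L,
    quality_q = 20L, quality_max_frac = 0.2,
    adapter_min_match = 6L, adapter_max_mismatch = 1L,
    contaminant_prefix = 8L,
    known_min_count = 10L,
    tpm_zero_sub = 0.01, tpm_min = 1,
    novel_min_count = 10L, novel_score_min = 1,
    novel_randfold_alpha = 0.05, novel_mfe_max = -19,
    novel_flank = 70L, n_shuffles = 99L,
    de_alpha = 0.05, de_fc_min = 1, de_correction = "bonferroni",
    seed_site_min = "7mer", align_threshold = 80, duplex_energy_max = -20,
    enrich_alpha = 0.05, enrich_correction = "bonferroni")
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stopf("unknown parameter(s): %s", paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  attr(p, "overridden") <- names(ov)
  class(p) <- "pipeline_params"
  p
}

#' Write / read a simulation configuration (YAML)
#'
#' Configurations round-trip through serialization unchanged.
#' @param cfg a `sim_config`.
#' @param path file path.
#' @export
write_sim_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$de_log2fc <- as.list(as.data.frame(x$de_log2fc))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$de_log2fc <- as.matrix(as.data.frame(x$de_log2fc))
  do.call(sim_config, x[setdiff(names(x), character(0))])
}
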