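# End-to-end orchestration: simulate -> clean -> collapse -> map -> annotate
# -> quantify (known + novel) -> differential expression -> targets ->
# enrichment -> qPCR, with a run manifest and regenerable report tables.

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

#' Run the complete pipeline on a simulated study
#'
#' Executes all stages in order on inputs generated from `cfg` and returns
#' the full result bundle plus a manifest (seed, config hash, per-stage row
#' counts). Identical config and seed give identical bundles. Any stage
#' failure aborts with the stage name and cause.
#'
#' @param cfg a [sim_config()].
#' @param params a [pipeline_params()].
#' @return a result bundle (list); see the manifest element for stage
#'   accounting.
#' @export
run_pipeline <- function(cfg, params = pipeline_params()) {
  bundle <- list(config = cfg, params = params)
  stages <- character(0)
  run_stage <- function(name, expr) {
    r <- tryCatch(force(expr),
                  error = function(e) stopf("stage '%s' failed: %s", name,
                                            conditionMessage(e)))
    stages <<- c(stages, name)
    r
  }

  study <- run_stage("simulate", simulate_study(cfg))
  bundle$study <- study

  cleaned <- run_stage("clean", {
    lapply(study$reads, function(df)
      clean_reads(df[c("id", "sequence", "quality")],
                  cfg$adapter3, cfg$adapter5, params))
  })
  bundle$stats <- lapply(cleaned, `[[`, "stats")

  tags <- run_stage("collapse", {
    collapse_tags(lapply(cleaned, function(x) x$inserts$sequence))
  })
  bundle$tags <- tags
  bundle$length_dist <- length_distribution(
    tags, params$min_insert_len:params$max_insert_len)

  hits <- run_stage("map", map_tags(tags, study$genome))
  bundle$hits <- hits
  mapped <- tags$sequence %in% hits$sequence
  for (lib in names(bundle$stats))
    bundle$stats[[lib]]$mapped_total <- sum(tags[[lib]][mapped])

  classes <- run_stage("annotate", annotate_tags(tags, hits, study$annotation))
  bundle$classes <- classes

  quant <- run_stage("quantify", {
    mk <- match_known(tags, study$catalog)
    retained <- filter_low_count(mk$records, params$known_min_count)
    cand <- discover_novel(tags, classes, hits, study$genome, params,
                           seed = derive_seed(cfg$seed, "novel"))
    novel <- filter_novel(cand, params)
    list(known = mk, retained = retained, candidates = cand, novel = novel)
  })
  bundle$quant <- quant

  de <- run_stage("de", {
    clean_totals <- vapply(bundle$stats, `[[`, numeric(1), "clean_total")
    counts <- as.matrix(quant$retained[, cfg$library_names, drop = FALSE])
    rownames(counts) <- quant$retained$mirna
    tpm <- normalize_tpm(counts, clean_totals, params$tpm_zero_sub)
    keep <- rownames(filter_low_expression(tpm, params$tpm_min))
    counts <- counts[keep, , drop = FALSE]
    comparisons <- lapply(cfg$library_names[-1], function(tr) {
      res <- ac_test_table(counts, clean_totals, cfg$library_names[1], tr,
                           params$tpm_zero_sub)
      classify_de(res, m = nrow(res), alpha = params$de_alpha,
                  fc_threshold = params$de_fc_min)
    })
    names(comparisons) <- cfg$library_names[-1]
    list(clean_totals = clean_totals, tpm = tpm, counts = counts,
         comparisons = comparisons)
  })
  bundle$de <- de

  targets <- run_stage("targets", {
    de_mirnas <- sort(unique(unlist(lapply(de$comparisons, function(d)
      d$mirna[d$regulation != "ns"]))))
    seqs <- stats::setNames(study$catalog$sequence, study$catalog$name)
    predict_targets(seqs[de_mirnas], study$utrs, params,
                    gene_map = study$truth$gene_map)
  })
  bundle$targets <- targets

  enrich <- run_stage("enrich", {
    bg <- unique(study$truth$gene_map$gene)
    res <- hypergeom_enrich(targets$genes, bg, study$term_map)
    res <- correct_terms(res, params$enrich_correction, params$enrich_alpha)
    list(results = res,
         go_classes = classification_table(
           targets$genes,
           study$term_map[study$term_map$category != "pathway", ]),
         pathway_classes = classification_table(
           targets$genes,
           study$term_map[study$term_map$category == "pathway", ]))
  })
  bundle$enrich <- enrich

  qp <- run_stage("qpcr", {
    dd <- delta_delta_ct(study$ct_table, calibrator = cfg$library_names[1])
    list(records = dd$records, summary = dd$summary,
         stats = group_stats(dd$records))
  })
  bundle$qpcr <- qp

  bundle$manifest <- list(
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    stages = stages,
    n_stages = length(stages),
    rows = list(
      raw_reads = sum(vapply(bundle$stats, `[[`, numeric(1), "raw_total")),
      clean_reads = sum(vapply(bundle$stats, `[[`, numeric(1), "clean_total")),
      unique_tags = nrow(tags),
      known_matched = sum(rowSums(as.matrix(
        quant$known$records[cfg$library_names])) > 0),
      known_retained = nrow(quant$retained),
      novel_candidates = nrow(quant$candidates),
      novel_accepted = nrow(quant$novel),
      de_tested = nrow(de$counts),
      consensus_sites = sum(targets$sites$consensus),
      enriched_terms = sum(enrich$results$significant),
      qpcr_targets = length(unique(qp$summary$target))))
  bundle
}

write_tsv_report <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write the report tables for a pipeline bundle
#'
#' Library statistics, length histogram, the top-10 abundance table (ranked
#' by mean TPM across the libraries), per-comparison test and volcano
#' tables, target Venn counts and consensus sites, enrichment and
#' classification tables, and the qPCR RQ table; every table is regenerable
#' independently from the bundle and carries the config hash in a header
#' comment.
#'
#' @param bundle output of [run_pipeline()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_reports <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hash <- bundle$manifest$config_hash
  libs <- bundle$config$library_names

  stats_df <- do.call(rbind, lapply(names(bundle$stats), function(l) {
    s <- bundle$stats[[l]]
    data.frame(library = l, raw_total = s$raw_total,
               removed_low_quality = s$removed_low_quality,
               removed_5prime_contaminant = s$removed_5prime_contaminant,
               removed_no_3adapter_or_insert = s$removed_no_3adapter_or_insert,
               removed_short = s$removed_short,
               clean_total = s$clean_total, mapped_total = s$mapped_total,
               mapped_pct = round(100 * s$mapped_total / s$clean_total, 2))
  }))
  write_tsv_report(stats_df, file.path(dir, "library_stats.tsv"), hash)
  write_tsv_report(bundle$length_dist,
                   file.path(dir, "length_histogram.tsv"), hash)

  tpm <- bundle$de$tpm
  mean_tpm <- rowMeans(tpm)
  abundance <- data.frame(mirna = rownames(tpm), tpm,
                          mean_tpm = mean_tpm, check.names = FALSE)
  abundance <- abundance[order(-abundance$mean_tpm, abundance$mirna), ]
  rownames(abundance) <- NULL
  write_tsv_report(abundance, file.path(dir, "known_abundance.tsv"), hash)
  write_tsv_report(utils::head(abundance, 10L),
                   file.path(dir, "top10_abundance.tsv"), hash)

  for (tr in names(bundle$de$comparisons)) {
    d <- bundle$de$comparisons[[tr]]
    write_tsv_report(d, file.path(dir, sprintf("de_%s_vs_%s.tsv", tr,
                                               libs[1])), hash)
    write_tsv_report(d[c("mirna", "log2fc", "neg_log10_p", "regulation")],
                     file.path(dir, sprintf("volcano_%s_vs_%s.tsv", tr,
                                            libs[1])), hash)
  }

  write_tsv_report(bundle$quant$candidates[
    setdiff(colnames(bundle$quant$candidates), "structure")],
    file.path(dir, "novel_candidates.tsv"), hash)
  write_tsv_report(data.frame(set = names(bundle$targets$venn),
                              spots = as.integer(bundle$targets$venn)),
                   file.path(dir, "venn_counts.tsv"), hash)
  write_tsv_report(bundle$targets$sites,
                   file.path(dir, "target_sites.tsv"), hash)
  write_tsv_report(bundle$enrich$results,
                   file.path(dir, "enrichment.tsv"), hash)
  write_tsv_report(bundle$enrich$go_classes,
                   file.path(dir, "classification_go.tsv"), hash)
  write_tsv_report(bundle$enrich$pathway_classes,
                   file.path(dir, "classification_pathway.tsv"), hash)
  write_tsv_report(bundle$qpcr$stats, file.path(dir, "qpcr_rq.tsv"), hash)
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
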