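# Shared fixtures: one small simulated study for unit tests and one
# default-scale pipeline bundle for the acceptance checks, built once per
# suite run.

.fixtures <- new.env(parent = emptyenv())

small_cfg <- function(seed = 42L, ...) {
  args <- list(seed = seed, reads_per_library = 4000L,
               genome_length = 160000L, n_known_mirnas = 30L,
               n_novel_mirnas = 4L, n_de_mirnas = 6L, n_utrs = 40L,
               n_decoy_tags = 10L)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(sim_config, args)
}

get_small_study <- function() {
  if (is.null(.fixtures$small)) .fixtures$small <- simulate_study(small_cfg())
  .fixtures$small
}

get_small_processed <- function() {
  if (is.null(.fixtures$small_proc)) {
    study <- get_small_study()
    cfg <- study$config
    cleaned <- lapply(study$reads, function(df)
      clean_reads(df[c("id", "sequence", "quality")], cfg$adapter3,
                  cfg$adapter5))
    tags <- collapse_tags(lapply(cleaned, function(x) x$inserts$sequence))
    hits <- map_tags(tags, study$genome)
    classes <- annotate_tags(tags, hits, study$annotation)
    .fixtures$small_proc <- list(study = study, cleaned = cleaned,
                                 tags = tags, hits = hits, classes = classes)
  }
  .fixtures$small_proc
}

get_default_bundle <- function() {
  if (is.null(.fixtures$bundle))
    .fixtures$bundle <- run_pipeline(sim_config(seed = 20180208L))
  .fixtures$bundle
}
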