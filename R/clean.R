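# Read cleaning, tag collapsing, length distributions.

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ (Phred+33) file.
#' @param library library label attached to the reads.
#' @return data.frame with columns id, sequence, quality, library.
#' @export
read_fastq <- function(path, library = basename(path)) {
  x <- Biostrings::readQualityScaledDNAStringSet(path)
  data.frame(id = sub(" .*", "", names(x)),
             sequence = as.character(x),
             quality = as.character(Biostrings::quality(x)),
             library = library)
}

#' Clean raw small-RNA reads
#'
#' Applies the cleaning cascade in fixed order -- low quality, 5' primer
#' contaminant, missing 3' adapter or empty insert, insert length -- with
#' each removed read counted by the first filter it fails. Definitions:
#' low quality = more than 20% of bases below Q20; 5' contaminant = read
#' beginning with an exact 8-nt prefix of the 5' adapter; the 3' adapter is
#' located by the first prefix match of at least 6 nt with at most 1
#' mismatch scanning 5' to 3' (no such match, or an empty insert, counts as
#' missing); surviving inserts must be 18-30 nt. All cutoffs live in
#' [pipeline_params()].
#'
#' @param reads data.frame with columns id, sequence, quality (one library).
#' @param adapter3,adapter5 adapter sequences.
#' @param params a [pipeline_params()].
#' @return list with `inserts` (id, sequence) and `stats` (the per-library
#'   accounting; `raw_total = clean_total + sum(removed)`).
#' @export
clean_reads <- function(reads, adapter3, adapter5,
                        params = pipeline_params()) {
  adapter3 <- as_dna(adapter3); adapter5 <- as_dna(adapter5)
  bad_len <- nchar(reads$sequence) != nchar(reads$quality)
  if (any(bad_len))
    stopf("malformed FASTQ record (sequence/quality length mismatch): %s",
          paste(utils::head(reads$id[bad_len], 3), collapse = ", "))
  bad_chr <- !grepl("^[ACGTNacgtn]*$", reads$sequence)
  if (any(bad_chr))
    stopf("malformed FASTQ record (invalid characters): %s",
          paste(utils::head(reads$id[bad_chr], 3), collapse = ", "))
  seqs <- toupper(reads$sequence)
  n <- nrow(reads)
  state <- rep("clean", n)

  q_fail <- frac_below_q_cpp(reads$quality, params$quality_q) >
    params$quality_max_frac
  state[q_fail] <- "low_quality"

  live <- state == "clean"
  contam <- live & startsWith(seqs, substr(adapter5, 1L, params$contaminant_prefix))
  state[contam] <- "contaminant5"

  live <- state == "clean"
  pos <- rep(-1L, n)
  pos[live] <- adapter3_pos_cpp(seqs[live], adapter3,
                                params$adapter_min_match,
                                params$adapter_max_mismatch)
  no_ad <- live & (pos == -1L | pos == 0L)
  state[no_ad] <- "no_3adapter"

  live <- state == "clean"
  ins_len <- ifelse(live, pos, 0L)
  short <- live & (ins_len < params$min_insert_len |
                     ins_len > params$max_insert_len)
  state[short] <- "short"

  live <- state == "clean"
  inserts <- data.frame(id = reads$id[live],
                        sequence = substr(seqs[live], 1L, pos[live]))
  hist <- table(factor(nchar(inserts$sequence),
                       levels = params$min_insert_len:params$max_insert_len))
  stats <- list(raw_total = n,
                removed_low_quality = sum(state == "low_quality"),
                removed_5prime_contaminant = sum(state == "contaminant5"),
                removed_no_3adapter_or_insert = sum(state == "no_3adapter"),
                removed_short = sum(state == "short"),
                clean_total = sum(live),
                mapped_total = NA_integer_,
                length_histogram = stats::setNames(as.integer(hist),
                                                   names(hist)))
  list(inserts = inserts, stats = stats)
}

#' Collapse cleaned inserts to unique tags with per-library counts
#'
#' @param inserts named list: library label -> character vector of cleaned
#'   insert sequences.
#' @return data.frame with `sequence`, one count column per library and
#'   `total`, ordered by descending total count (ties broken
#'   lexicographically by sequence).
#' @export
collapse_tags <- function(inserts) {
  libs <- names(inserts)
  all_seq <- sort(unique(unlist(inserts, use.names = FALSE)))
  counts <- vapply(libs, function(l) {
    tab <- table(factor(inserts[[l]], levels = all_seq))
    as.integer(tab)
  }, integer(length(all_seq)))
  counts <- matrix(counts, nrow = length(all_seq),
                   dimnames = list(NULL, libs))
  total <- rowSums(counts)
  ord <- order(-total, all_seq)
  out <- data.frame(sequence = all_seq, counts, total = total,
                    check.names = FALSE)
  out[ord, , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Per-library insert-length distribution
#'
#' Read-weighted (not unique-tag) length histogram over the retained insert
#' range; per-library frequencies sum to 1 (empty libraries yield all-zero
#' counts and NA frequencies).
#'
#' @param tags output of [collapse_tags()].
#' @param lengths length range to tabulate.
#' @return long data.frame: length, library, count, freq.
#' @export
length_distribution <- function(tags, lengths = 18:30) {
  libs <- setdiff(colnames(tags), c("sequence", "total"))
  len <- nchar(tags$sequence)
  out <- do.call(rbind, lapply(libs, function(l) {
    cnt <- vapply(lengths, function(L) sum(tags[[l]][len == L]), numeric(1))
    tot <- sum(cnt)
    data.frame(length = lengths, library = l, count = cnt,
               freq = if (tot > 0) cnt / tot else rep(NA_real_, length(cnt)))
  }))
  rownames(out) <- NULL
  out
}
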